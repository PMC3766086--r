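# Seeded generators of synthetic protein families with planted conserved
# motifs, and of matched DNA templates, so mining, primer design and
# in-silico PCR can be exercised end to end without sequence downloads.
#
# All generators take an explicit integer seed and restore the caller's
# RNG state on exit: outputs are pure functions of their arguments.

.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.sampleResidue <- function(n) sample(.AA20, n, replace = TRUE)

.matchesPattern <- function(residues, pat) {
  all(mapply(function(r, s) r %in% s, residues, pat@positions))
}

#' Generate a synthetic protein family with planted conserved motifs
#'
#' Draws an ancestor uniformly over the 20 standard residues, plants each
#' motif at its stated position, and derives \code{nSequences} homologs by
#' i.i.d. substitution at \code{substitutionRate} per site outside motif
#' spans. Each motif is retained intact in exactly
#' \code{round(fraction * nSequences)} sequences (a seeded random subset);
#' in the remaining sequences the span is resampled until it no longer
#' matches the motif pattern. Motifs with alternative residue sets draw
#' one allowed residue per position independently in every retaining
#' sequence, so merged patterns arise naturally.
#'
#' @param nSequences Number of homologs.
#' @param length Sequence length in residues.
#' @param motifs List of motif descriptions, each a list with
#'   \code{pattern} (a \code{\link{PeptidePattern}} or string),
#'   \code{position} (1-based start in the sequence) and \code{fraction}
#'   (conservation fraction in [0, 1], default 1). Spans must not overlap.
#' @param substitutionRate Per-site substitution probability outside
#'   motifs.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return An \code{AAStringSet} named \code{seq01}, \code{seq02}, ...
#' @examples
#' fam <- generateFamily(5, 60, list(list(pattern = "YWDCCK",
#'                                        position = 20)), 0.3, seed = 1)
#' @export
generateFamily <- function(nSequences = 20L, length = 300L,
                           motifs = list(), substitutionRate = 0.3,
                           seed = 1L) {
  nSequences <- as.integer(nSequences); length <- as.integer(length)
  if (nSequences < 1L) stop("nSequences must be positive")
  if (substitutionRate < 0 || substitutionRate > 1)
    stop("substitutionRate must be in [0, 1]")
  motifs <- lapply(motifs, function(m) {
    m$pattern <- as.PeptidePattern(m$pattern)
    if (is.null(m$fraction)) m$fraction <- 1
    if (m$fraction < 0 || m$fraction > 1) stop("motif fraction outside [0, 1]")
    if (m$position < 1L || m$position + base::length(m$pattern) - 1L > length)
      stop("motif at position ", m$position, " does not fit in ", length,
           " residues")
    m
  })
  spans <- lapply(motifs, function(m)
    seq(m$position, m$position + length(m$pattern) - 1L))
  if (length(motifs) > 1L) {
    allpos <- unlist(spans)
    if (anyDuplicated(allpos)) stop("motif spans overlap")
  }
  inMotif <- rep(FALSE, length)
  for (sp in spans) inMotif[sp] <- TRUE

  .withSeed(seed, {
    ancestor <- .sampleResidue(length)
    retained <- lapply(motifs, function(m)
      sort(sample(nSequences, round(m$fraction * nSequences))))
    seqs <- vapply(seq_len(nSequences), function(i) {
      s <- ancestor
      # background divergence
      mut <- which(!inMotif & stats::runif(length) < substitutionRate)
      for (pos in mut) {
        s[pos] <- sample(setdiff(.AA20, s[pos]), 1L)
      }
      for (mi in seq_along(motifs)) {
        m <- motifs[[mi]]; sp <- spans[[mi]]
        if (i %in% retained[[mi]]) {
          s[sp] <- vapply(m$pattern@positions, function(alt)
            if (length(alt) == 1L) alt else sample(alt, 1L), character(1))
        } else {
          repeat {
            cand <- .sampleResidue(length(sp))
            if (!.matchesPattern(cand, m$pattern)) break
          }
          s[sp] <- cand
        }
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq%02d", seq_len(nSequences))
    Biostrings::AAStringSet(seqs)
  })
}

.backTranslate <- function(residues) {
  paste(vapply(residues, function(r) sample(.CODON_TABLE[[r]], 1L),
               character(1)), collapse = "")
}

.firstPatternHit <- function(seqChars, pat, from = 1L) {
  k <- length(pat@positions)
  n <- length(seqChars)
  for (start in seq(from, n - k + 1L)) {
    if (.matchesPattern(seqChars[start:(start + k - 1L)], pat)) return(start)
  }
  NA_integer_
}

#' Generate DNA templates with planted primer binding sites
#'
#' For each synthetic protein, back-translates the segment from the
#' sequence start through the forward motif and the segment from the
#' reverse motif through the sequence end, drawing codons uniformly from
#' each residue's full standard codon set (seeded), and joins them with a
#' random non-coding stretch sized so that the distance between the 3' end
#' of the forward core site and the 5' end of the reverse core site equals
#' the drawn spacer value. Each core therefore has one planted binding
#' site; templates acquiring a second zero-mismatch site by chance are
#' resampled (bounded). Because codons are drawn from the full code,
#' primer-template mismatches at Leu/Arg/Ser wobble positions can occur
#' naturally, matching the partial-coverage warnings of the encoder.
#'
#' Optional introns (\code{GT...AG} termini) are inserted at stated
#' template positions, shifting the expected product length by the
#' inserted total when they fall between the two sites.
#'
#' @param proteins An \code{AAStringSet} or named character vector; every
#'   sequence must contain the forward motif, and the reverse motif
#'   downstream of it.
#' @param fwdPeptide,revPeptide \code{PeptidePattern}s or strings.
#' @param spacer Integer range \code{c(min, max)} for the inter-core
#'   distance in nt (drawn uniformly per template; default fixed 200).
#' @param introns Optional list of \code{c(position, length)} pairs
#'   (0-based template position, length >= 4).
#' @param seed Integer seed.
#' @param maxResample Attempts per template before giving up on site
#'   uniqueness.
#' @return A list with \code{templates} (a \code{DNAStringSet}) and
#'   \code{truth}, a data.frame of planted coordinates: \code{template},
#'   \code{fwd_start}, \code{fwd_end}, \code{rev_start}, \code{rev_end}
#'   (0-based half-open), \code{spacer} and
#'   \code{expected_product_length}.
#' @export
generateTemplates <- function(proteins, fwdPeptide, revPeptide,
                              spacer = c(200L, 200L), introns = NULL,
                              seed = 1L, maxResample = 25L) {
  seqs <- .asProteinSet(proteins)
  fwdPeptide <- as.PeptidePattern(fwdPeptide)
  revPeptide <- as.PeptidePattern(revPeptide)
  spacer <- as.integer(spacer)
  if (length(spacer) == 1L) spacer <- c(spacer, spacer)
  if (any(spacer < 0L) || spacer[1L] > spacer[2L])
    stop("spacer must be a non-negative (min, max) range")
  if (!is.null(introns)) {
    for (iv in introns)
      if (length(iv) != 2L || iv[2L] < 4L)
        stop("introns must be (position, length) with length >= 4")
  }
  fwdCore <- trimWobble(as.character(encodeSense(fwdPeptide)))
  revCoreSense <- trimWobble(as.character(encodeSense(revPeptide)))
  lf <- nchar(fwdCore); lr <- nchar(revCoreSense)
  kF <- length(fwdPeptide); kR <- length(revPeptide)
  leftoverF <- 3L * kF - lf

  .withSeed(seed, {
    out <- vector("list", length(seqs))
    for (si in seq_along(seqs)) {
      id <- names(seqs)[si]
      chars <- .split1(seqs[[id]])
      p1 <- .firstPatternHit(chars, fwdPeptide)
      if (is.na(p1))
        stop("forward motif ", patternText(fwdPeptide),
             " not found in ", id)
      p2 <- .firstPatternHit(chars, revPeptide, from = p1 + kF)
      if (is.na(p2))
        stop("reverse motif ", patternText(revPeptide),
             " not found downstream of the forward motif in ", id)
      sRange <- seq(spacer[1L], spacer[2L])
      s <- sRange[sample.int(length(sRange), 1L)]
      nSpacerDNA <- s - leftoverF
      if (nSpacerDNA < 0L)
        stop("spacer ", s, " nt is shorter than the ", leftoverF,
             " nt of trimmed wobble bases after the forward core")
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        coding1 <- .backTranslate(chars[1:(p1 + kF - 1L)])
        coding2 <- .backTranslate(chars[p2:length(chars)])
        spacerDNA <- if (nSpacerDNA > 0L)
          paste(sample(c("A", "C", "G", "T"), nSpacerDNA, replace = TRUE),
                collapse = "") else ""
        tmpl <- paste0(coding1, spacerDNA, coding2)
        fStart <- 3L * (p1 - 1L)
        rStart <- nchar(coding1) + nSpacerDNA
        okF <- .plantedSiteUnique(fwdCore, tmpl, fStart, "+")
        okR <- .plantedSiteUnique(revCoreSense, tmpl, rStart, "+",
                                  asReverse = TRUE)
        if (okF && okR) break
        if (attempt >= maxResample)
          stop("could not generate a template with unique binding sites",
               " for ", id, " in ", maxResample, " attempts")
      }
      expectedLen <- lf + s + lr
      if (!is.null(introns)) {
        for (iv in rev(introns[order(vapply(introns, `[`, numeric(1), 1L))])) {
          pos <- as.integer(iv[1L]); ilen <- as.integer(iv[2L])
          if (pos < 0L || pos > nchar(tmpl))
            stop("intron position ", pos, " outside template ", id)
          body <- if (ilen > 4L)
            paste(sample(c("A", "C", "G", "T"), ilen - 4L, replace = TRUE),
                  collapse = "") else ""
          intron <- paste0("GT", body, "AG")
          tmpl <- paste0(substr(tmpl, 1L, pos), intron,
                         substr(tmpl, pos + 1L, nchar(tmpl)))
          if (pos >= fStart + lf && pos <= rStart) {
            expectedLen <- expectedLen + ilen
          }
          if (pos <= fStart) {
            fStart <- fStart + ilen; rStart <- rStart + ilen
          } else if (pos <= rStart) {
            rStart <- rStart + ilen
          }
        }
      }
      out[[si]] <- list(
        sequence = tmpl,
        truth = data.frame(template = id, fwd_start = fStart,
                           fwd_end = fStart + lf, rev_start = rStart,
                           rev_end = rStart + lr, spacer = s,
                           expected_product_length = expectedLen,
                           stringsAsFactors = FALSE))
    }
    templates <- Biostrings::DNAStringSet(
      stats::setNames(vapply(out, `[[`, character(1), "sequence"),
                      names(seqs)))
    truth <- .rbindList(lapply(out, `[[`, "truth"))
    list(templates = templates, truth = truth)
  })
}

# TRUE iff every zero-mismatch site of `core` (or its reverse orientation)
# on `tmpl` is the planted one at `start`. A mismatching planted site
# (L/R/S wobble outside core coverage) is tolerated; extra perfect sites
# are not.
.plantedSiteUnique <- function(senseCore, tmpl, start, strand,
                               asReverse = FALSE) {
  core <- if (asReverse) revComp(senseCore) else senseCore
  sites <- findBindingSites(core, tmpl, maxMismatches = 0L, anchorLen = 0L)
  extra <- sites[sites$start != start |
                 sites$strand != (if (asReverse) "-" else "+"), ,
                 drop = FALSE]
  nrow(extra) == 0L
}
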