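# Reverse translation into degenerate codons.
#
# Conventions for single residues:
#   * codon family sharing its first two bases: third position encoded as
#     the IUPAC code of the observed third bases, or inosine when all four
#     occur (four-fold box);
#   * Ile -> ATH (three-fold wobble kept as H, not widened to I);
#   * the three six-codon residues split across boxes: Leu -> CTI (CTN
#     family only), Arg -> MGI (CGN plus AGR, at the cost of also covering
#     AGY = Ser), Ser -> TCI (TCN family only; misses AGY, flagged).
# Alternative residue sets are merged position-wise by IUPAC union, which
# may widen coverage; the truly covered residue set is always reported.

.CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.SPECIAL_CODONS <- list(
  L = list(triplet = "CTI", partial = FALSE),
  R = list(triplet = "MGI", partial = FALSE),
  S = list(triplet = "TCI", partial = TRUE)
)

.AA20 <- sort(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*"))

# wobble = TRUE encodes a fully degenerate position as inosine (the
# third-codon-base convention); elsewhere the IUPAC union is N
.codeForBaseSet <- function(bases, wobble = FALSE) {
  bases <- sort(unique(bases))
  if (wobble && identical(bases, c("A", "C", "G", "T"))) return("I")
  key <- paste(bases, collapse = "")
  code <- .SET_TO_CODE[[key]]
  if (is.null(code)) stop("no IUPAC code for base set {",
                          paste(bases, collapse = ","), "}")
  code
}

.singleAaCodon <- local({
  cache <- new.env(parent = emptyenv())
  function(aa) {
    hit <- get0(aa, envir = cache)
    if (!is.null(hit)) return(hit)
    sp <- .SPECIAL_CODONS[[aa]]
    out <- if (!is.null(sp)) sp$triplet else {
      codons <- .CODON_TABLE[[aa]]
      mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
      paste(vapply(seq_len(3L), function(j)
        .codeForBaseSet(mat[, j], wobble = j == 3L), character(1)),
        collapse = "")
    }
    assign(aa, out, envir = cache)
    out
  }
})

# degenerate triplet for a residue alternative set, without the covered-set
# bookkeeping of codonFor(); used on mining's hot path
.tripletFor <- function(aaSet) {
  if (length(aaSet) == 1L) .singleAaCodon(aaSet)
  else .unionTriplet(vapply(aaSet, .singleAaCodon, character(1)))
}

.unionTriplet <- function(triplets) {
  mats <- strsplit(triplets, "", fixed = TRUE)
  paste(vapply(seq_len(3L), function(j) {
    bases <- unique(unlist(lapply(mats, function(m) .IUPAC_SETS[[m[[j]]]])))
    .codeForBaseSet(bases, wobble = j == 3L)
  }, character(1)), collapse = "")
}

.aaCovered <- function(triplet) {
  codons <- expandDegenerate(triplet, limit = 64L)
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  sort(unique(aas))
}

#' Canonical degenerate codon for a set of amino-acid alternatives
#'
#' Returns the degenerate codon used when reverse-translating peptides into
#' primers: third-position four-fold degeneracy becomes inosine, two- and
#' three-fold wobble the matching IUPAC code (Ile is \code{ATH}); the
#' six-codon residues use one codon family each (Leu \code{CTI}, Arg
#' \code{MGI}, Ser \code{TCI}); multi-residue sets are merged by
#' position-wise IUPAC union.
#'
#' Merged or family-restricted codons can cover more or fewer residues than
#' requested; \code{covered} reports the residues the codon truly encodes
#' and \code{partialCoverage} flags codons that miss codons of a requested
#' residue (Ser misses \code{AGY}).
#'
#' @param aaSet Character vector of 1-letter amino-acid codes (the
#'   alternatives at one peptide position).
#' @return A list with \code{triplet} (degenerate codon string),
#'   \code{covered} (residues every expansion translates into, as a sorted
#'   character vector), and \code{partialCoverage} (logical).
#' @examples
#' codonFor("D")$triplet            # "GAY"
#' codonFor(c("F", "Y"))$triplet    # "TWY"
#' @export
codonFor <- function(aaSet) {
  aaSet <- toupper(aaSet)
  if (length(aaSet) == 0L) stop("empty amino-acid set")
  if (any(aaSet == "*")) stop("cannot encode a stop codon")
  bad <- setdiff(aaSet, .AA20)
  if (length(bad))
    stop("unknown amino acid '", bad[1L], "' (standard 1-letter codes only)")
  aaSet <- sort(unique(aaSet))
  triplets <- vapply(aaSet, .singleAaCodon, character(1))
  triplet <- unname(if (length(triplets) == 1L) triplets
                    else .unionTriplet(triplets))
  partial <- any(vapply(aaSet, function(a) {
    sp <- .SPECIAL_CODONS[[a]]
    !is.null(sp) && sp$partial
  }, logical(1)))
  list(triplet = triplet, covered = .aaCovered(triplet),
       partialCoverage = partial)
}

#' Reverse-translate a peptide pattern into a degenerate sense-strand core
#'
#' Concatenates \code{\link{codonFor}} over the positions of a
#' \code{\link{PeptidePattern}} (or a plain peptide string, possibly with
#' bracketed alternatives such as \code{"WR[FY][DN]WF"}). The result is the
#' untrimmed sense-strand encoding, 3 nt per residue.
#'
#' @param p A \code{PeptidePattern} or a pattern string.
#' @return Degenerate DNA string of length \code{3 * length(p)}, with
#'   attributes \code{covered} (list of per-position covered residue sets)
#'   and \code{partialCoverage} (logical per position).
#' @examples
#' encodeSense("LPDRDC")  # "CTICCIGAYMGIGAYTGY"
#' @export
encodeSense <- function(p) {
  p <- as.PeptidePattern(p)
  codons <- lapply(seq_along(p@positions), function(i) {
    tryCatch(codonFor(p@positions[[i]]),
             error = function(e) stop("position ", i, " of peptide '",
                                      patternText(p), "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  out <- paste(vapply(codons, `[[`, character(1), "triplet"), collapse = "")
  attr(out, "covered") <- lapply(codons, `[[`, "covered")
  attr(out, "partialCoverage") <- vapply(codons, `[[`, logical(1),
                                         "partialCoverage")
  out
}

#' Translate a concrete DNA sequence in all six reading frames
#'
#' Standard genetic code, stops as \code{*}, trailing partial codons
#' dropped. Frames are named \code{+1 +2 +3 -1 -2 -3}; minus frames read
#' the reverse complement. Codons containing \code{N} translate to
#' \code{X}.
#'
#' @param t Concrete DNA string (A/C/G/T, N tolerated).
#' @return Named character vector of six peptide strings.
#' @examples
#' translateFrames("TGGGAC")[["+1"]]  # "WD"
#' @export
translateFrames <- function(t) {
  t <- .checkConcreteDNA(t, what = "sequence", allowN = TRUE)
  fwd <- Biostrings::DNAString(t)
  rev <- Biostrings::reverseComplement(fwd)
  oneFrame <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1L, off + n),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  c("+1" = oneFrame(fwd, 0L), "+2" = oneFrame(fwd, 1L), "+3" = oneFrame(fwd, 2L),
    "-1" = oneFrame(rev, 0L), "-2" = oneFrame(rev, 1L), "-3" = oneFrame(rev, 2L))
}
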