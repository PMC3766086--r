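# Virtual PCR: degenerate-core scanning of both template strands with a
# mismatch budget and a zero-mismatch 3' anchor, then pairing of forward
# and reverse sites into amplicons.
#
# Only the core binds; 5' tails are non-templated and never affect
# matching (gel sizes of tailed pairs run a constant 2 x tail length
# larger than the product lengths reported here).

.asTemplates <- function(templates) {
  if (is(templates, "DNAStringSet")) {
    seqs <- toupper(as.character(templates))
  } else if (is.character(templates)) {
    seqs <- toupper(templates)
  } else stop("expected a DNAStringSet or a named character vector")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("template", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate template identifier '",
         names(seqs)[anyDuplicated(names(seqs))], "'")
  for (id in names(seqs)) .checkConcreteDNA(seqs[[id]], what = id, allowN = TRUE)
  seqs
}

.coreOf <- function(primer) {
  if (is(primer, "PrimerRecord")) primerCore(primer) else degenerateSeq(primer)
}

.nameOf <- function(primer, fallback) {
  if (is(primer, "PrimerRecord")) primerName(primer) else fallback
}

# mismatch counts of `core` against every offset of `tmpl` (+ strand scan);
# returns list(total = vector over offsets, anchor = vector over offsets)
# where anchor counts mismatches within core positions [aFrom, aTo].
.scanMismatches <- function(core, tmpl, aFrom, aTo) {
  pc <- .split1(core)
  tc <- .split1(tmpl)
  m <- length(pc); L <- length(tc)
  nOff <- L - m + 1L
  if (nOff < 1L) return(list(total = integer(0), anchor = integer(0)))
  memb <- lapply(unique(pc), function(sym) !(tc %in% .IUPAC_SETS[[sym]]))
  names(memb) <- unique(pc)
  total <- integer(nOff); anchor <- integer(nOff)
  idx <- seq_len(nOff)
  for (j in seq_len(m)) {
    v <- memb[[pc[j]]][idx + j - 1L]
    total <- total + v
    if (j >= aFrom && j <= aTo) anchor <- anchor + v
  }
  list(total = total, anchor = anchor)
}

#' Find binding sites of a degenerate primer core on a template
#'
#' Scans both strands of the template with the primer core (the tail is
#' excluded: it is non-templated). A site is reported iff its total
#' mismatch count is at most \code{maxMismatches} and its 3'-terminal
#' \code{anchorLen} core bases match with zero mismatches. Template
#' \code{N} matches nothing. Coordinates are 0-based half-open on the +
#' strand.
#'
#' @param primer A \code{PrimerRecord} or a core string.
#' @param template A concrete DNA string.
#' @param maxMismatches Total mismatch tolerance (default 0).
#' @param anchorLen Length of the zero-mismatch 3' anchor (default 3).
#' @return A data.frame with columns \code{strand} ("+" if the core
#'   matches the + strand as written, "-" if it matches the reverse
#'   strand), \code{start}, \code{end}, \code{mismatches}, ordered by
#'   (start, strand).
#' @examples
#' findBindingSites("TGGGAY", "AATGGGACAA")
#' @export
findBindingSites <- function(primer, template, maxMismatches = 0L,
                             anchorLen = 3L) {
  core <- .coreOf(primer)
  tmpl <- .checkConcreteDNA(template, allowN = TRUE)
  m <- nchar(core)
  anchorLen <- as.integer(anchorLen)
  if (anchorLen < 0L || anchorLen > m)
    stop("anchorLen must be within 0..core length (", m, ")")
  res <- list()
  # + strand: core as written; 3' anchor is the last anchorLen positions
  sc <- .scanMismatches(core, tmpl, m - anchorLen + 1L, m)
  hit <- which(sc$total <= maxMismatches & sc$anchor == 0L)
  if (length(hit))
    res[[1L]] <- data.frame(strand = "+", start = hit - 1L,
                            end = hit - 1L + m,
                            mismatches = as.integer(sc$total[hit]),
                            stringsAsFactors = FALSE)
  # - strand: scan with the reverse complement; the core's 3' end maps to
  # the start of the matched + strand window
  sc <- .scanMismatches(revComp(core), tmpl, 1L, anchorLen)
  hit <- which(sc$total <= maxMismatches & sc$anchor == 0L)
  if (length(hit))
    res[[length(res) + 1L]] <- data.frame(strand = "-", start = hit - 1L,
                                          end = hit - 1L + m,
                                          mismatches = as.integer(sc$total[hit]),
                                          stringsAsFactors = FALSE)
  out <- .rbindList(res)
  if (is.null(out))
    out <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict amplicons of a primer pair against DNA templates
#'
#' Pairs every + strand site of the forward core with every downstream -
#' strand site of the reverse core (and symmetrically for products on the
#' - strand), keeping products whose length falls within
#' \code{[minLen, maxLen]}. Product length runs from the 5' end of the
#' forward binding site through the 5' end of the reverse binding site on
#' the template; tails are excluded. Zero hits is a valid outcome.
#'
#' @param fwd,rev \code{PrimerRecord}s (or core strings) for the forward
#'   and reverse primer.
#' @param templates A \code{DNAStringSet} or named character vector.
#' @param maxMismatches,anchorLen Passed to \code{\link{findBindingSites}}.
#' @param minLen,maxLen Product length bounds in nt.
#' @return A data.frame with one row per amplicon: \code{template},
#'   \code{fwd_name}, \code{fwd_start}, \code{fwd_end}, \code{rev_name},
#'   \code{rev_start}, \code{rev_end}, \code{strand} (of the product),
#'   \code{product_length}, \code{mismatches_forward},
#'   \code{mismatches_reverse}; ordered by (template, product start).
#' @export
predictAmplicons <- function(fwd, rev, templates, maxMismatches = 0L,
                             minLen = 0L, maxLen = 10000L, anchorLen = 3L) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  seqs <- .asTemplates(templates)
  fwdName <- .nameOf(fwd, "fwd"); revName <- .nameOf(rev, "rev")
  rows <- list()
  for (id in names(seqs)) {
    fs <- findBindingSites(fwd, seqs[[id]], maxMismatches, anchorLen)
    rs <- findBindingSites(rev, seqs[[id]], maxMismatches, anchorLen)
    pairUp <- function(f, r, strand) {
      # f binds first in product orientation; on "+" products f is the
      # forward + strand site and r the reverse - strand site downstream
      for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
        if (r$start[j] < f$end[i]) next
        len <- r$end[j] - f$start[i]
        if (len < minLen || len > maxLen) next
        rows[[length(rows) + 1L]] <<- data.frame(
          template = id,
          fwd_name = fwdName, fwd_start = f$start[i], fwd_end = f$end[i],
          rev_name = revName, rev_start = r$start[j], rev_end = r$end[j],
          strand = strand, product_length = len,
          mismatches_forward = f$mismatches[i],
          mismatches_reverse = r$mismatches[j],
          stringsAsFactors = FALSE)
      }
    }
    pairUp(fs[fs$strand == "+", , drop = FALSE],
           rs[rs$strand == "-", , drop = FALSE], "+")
    # product read off the - strand: rev core on +, fwd core on -, fwd site
    # downstream; swap roles so forward still precedes reverse in product
    # orientation
    fMinus <- fs[fs$strand == "-", , drop = FALSE]
    rPlus <- rs[rs$strand == "+", , drop = FALSE]
    for (j in seq_len(nrow(rPlus))) for (i in seq_len(nrow(fMinus))) {
      if (fMinus$start[i] < rPlus$end[j]) next
      len <- fMinus$end[i] - rPlus$start[j]
      if (len < minLen || len > maxLen) next
      rows[[length(rows) + 1L]] <- data.frame(
        template = id,
        fwd_name = fwdName, fwd_start = fMinus$start[i],
        fwd_end = fMinus$end[i],
        rev_name = revName, rev_start = rPlus$start[j],
        rev_end = rPlus$end[j],
        strand = "-", product_length = len,
        mismatches_forward = fMinus$mismatches[i],
        mismatches_reverse = rPlus$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- .rbindList(rows)
  if (is.null(out))
    out <- data.frame(template = character(0), fwd_name = character(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      rev_name = character(0), rev_start = integer(0),
                      rev_end = integer(0), strand = character(0),
                      product_length = integer(0),
                      mismatches_forward = integer(0),
                      mismatches_reverse = integer(0))
  pstart <- pmin(out$fwd_start, out$rev_start)
  out <- out[order(match(out$template, names(seqs)), pstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract predicted PCR products and their six-frame translations
#'
#' Returns each product in product orientation (forward core at the 5'
#' end): for "-" strand hits the returned sequence is the reverse
#' complement of the template slice.
#'
#' @param hits Output of \code{\link{predictAmplicons}}.
#' @param templates The templates the hits were predicted on.
#' @return A list with \code{products} (a \code{DNAStringSet}) and
#'   \code{translations} (a list of six-frame peptide vectors from
#'   \code{\link{translateFrames}}, one per product).
#' @export
extractProducts <- function(hits, templates) {
  seqs <- .asTemplates(templates)
  prods <- character(nrow(hits))
  nms <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    id <- hits$template[i]
    if (!id %in% names(seqs)) stop("hit references unknown template '", id, "'")
    lo <- min(hits$fwd_start[i], hits$rev_start[i])
    hi <- max(hits$fwd_end[i], hits$rev_end[i])
    if (lo < 0L || hi > nchar(seqs[[id]]))
      stop("hit on '", id, "' is out of template bounds")
    slice <- substr(seqs[[id]], lo + 1L, hi)
    if (hits$strand[i] == "-") slice <- revComp(slice)
    prods[i] <- slice
    nms[i] <- paste0(id, "|", hits$fwd_name[i], "|", hits$rev_name[i],
                     "|", lo, "-", hi, "|", hits$strand[i])
  }
  products <- Biostrings::DNAStringSet(prods)
  names(products) <- nms
  translations <- lapply(prods, translateFrames)
  names(translations) <- nms
  list(products = products, translations = translations)
}
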