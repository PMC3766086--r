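# Alignment-free conserved-peptide mining.
#
# Conservation is defined as the number of distinct sequences containing at
# least one occurrence (primers must work across species, so breadth beats
# repeat counts within one sequence). No multiple alignment is performed:
# the search is exact k-mer containment plus an optional greedy merge of
# near-identical k-mers into ambiguous patterns.

.asProteinSet <- function(p) {
  if (is(p, "AAStringSet")) {
    seqs <- toupper(as.character(p))
  } else if (is.character(p)) {
    seqs <- toupper(p)
  } else stop("expected an AAStringSet or a named character vector")
  if (length(seqs) == 0L) stop("empty protein set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  # FASTA headers: identifier is the first whitespace token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifier '",
         names(seqs)[anyDuplicated(names(seqs))], "'")
  if (any(nchar(seqs) == 0L)) stop("empty sequence in protein set")
  seqs
}

.kmerOccurrences <- function(seqs, k) {
  # returns data.frame(kmer, id, offset) of every k-window; X never matchable
  res <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", kmers)
    if (!any(ok)) return(NULL)
    data.frame(kmer = kmers[ok], id = id, offset = starts[ok],
               stringsAsFactors = FALSE)
  })
  .rbindList(res)
}

.patternDegeneracy <- function(patternText) {
  p <- as.PeptidePattern(patternText)
  core <- paste(vapply(p@positions, .tripletFor, character(1)), collapse = "")
  # heavily merged patterns can encode to an all-degenerate core that the
  # wobble trim would empty; rank those by the untrimmed mixture size
  trimmed <- tryCatch(trimWobble(core), error = function(e) core)
  degeneracy(trimmed)
}

.mergedPatternText <- function(members) {
  mat <- do.call(rbind, strsplit(members, "", fixed = TRUE))
  paste(apply(mat, 2L, function(col) {
    u <- sort(unique(col))
    if (length(u) == 1L) u else paste0("[", paste(u, collapse = ""), "]")
  }), collapse = "")
}

#' Mine the most conserved k-peptides from a set of homologous proteins
#'
#' Counts every exact k-mer by the number of distinct sequences containing
#' it, optionally merges k-mers that agree at all but
#' \code{maxVariablePositions} positions into ambiguous
#' \code{\link{PeptidePattern}}s (greedy, highest-support seed first,
#' variable positions carrying the union of observed residues), drops
#' patterns below \code{minSupportFraction}, and ranks the survivors by
#' support (descending), then encoded-core degeneracy (ascending), then
#' pattern text. Ranking is total and deterministic.
#'
#' @param proteins An \code{AAStringSet} or named character vector of
#'   amino-acid sequences (\code{X} tolerated, never matchable).
#' @param k Peptide length (default 6, hexapeptides; 4-10 supported).
#' @param minSupportFraction Minimum fraction of sequences a pattern must
#'   occur in.
#' @param maxVariablePositions Maximum Hamming distance to the seed k-mer
#'   when merging (0 = exact k-mers only; at most 2).
#' @param maxPatterns Number of top-ranked patterns to return.
#' @return A data.frame with columns \code{pattern}, \code{k},
#'   \code{support}, \code{support_fraction}, \code{degeneracy} (of the
#'   trimmed encoded core), \code{rank}, and a list-column
#'   \code{occurrences} of per-pattern data.frames (\code{id},
#'   \code{offset}).
#' @examples
#' seqs <- c(a = "AYWDCCKL", b = "GYWDCCKP", c = "YWDCCKAA")
#' mineConserved(seqs, k = 6, minSupportFraction = 1)$pattern
#' @export
mineConserved <- function(proteins, k = 6L, minSupportFraction = 0.5,
                          maxVariablePositions = 0L, maxPatterns = 20L) {
  seqs <- .asProteinSet(proteins)
  k <- as.integer(k)
  if (k < 4L || k > 10L) stop("k must be within 4-10")
  if (minSupportFraction <= 0 || minSupportFraction > 1)
    stop("minSupportFraction must be in (0, 1]")
  if (maxVariablePositions < 0L || maxVariablePositions > 2L)
    stop("maxVariablePositions must be 0, 1 or 2")
  if (min(nchar(seqs)) < k)
    stop("k = ", k, " exceeds the shortest sequence (",
         min(nchar(seqs)), " residues)")
  n <- length(seqs)

  occ <- .kmerOccurrences(seqs, k)
  if (is.null(occ) || nrow(occ) == 0L)
    stop("no valid ", k, "-mers found (sequences may be all-X)")

  # per-kmer support = distinct sequences
  supp <- tapply(occ$id, occ$kmer, function(ids) length(unique(ids)))
  kmers <- names(supp)
  supp <- as.integer(supp)

  # greedy merge into patterns, highest-support seed first (ties: lower
  # encoded degeneracy, then text). With no merging the seed order cannot
  # change the groups, so the degeneracy tie-break is skipped there.
  if (maxVariablePositions == 0L) {
    ord <- order(-supp, kmers)
  } else {
    deg <- vapply(kmers, .patternDegeneracy, numeric(1))
    ord <- order(-supp, deg, kmers)
  }
  kmers <- kmers[ord]; supp <- supp[ord]
  merged <- logical(length(kmers))
  groups <- list()
  if (maxVariablePositions == 0L) {
    groups <- as.list(kmers)
  } else {
    kmat <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
    for (i in seq_along(kmers)) {
      if (merged[i]) next
      dists <- colSums(t(kmat) != kmat[i, ])
      take <- which(!merged & dists <= maxVariablePositions)
      merged[take] <- TRUE
      groups[[length(groups) + 1L]] <- kmers[take]
    }
  }

  hits <- lapply(groups, function(members) {
    text <- .mergedPatternText(members)
    sub <- occ[occ$kmer %in% members, , drop = FALSE]
    sub <- sub[order(sub$id, sub$offset), c("id", "offset")]
    rownames(sub) <- NULL
    s <- length(unique(sub$id))
    list(pattern = text, support = s, occurrences = sub)
  })

  hits <- Filter(function(h) h$support / n >= minSupportFraction, hits)
  if (length(hits) == 0L) {
    out <- data.frame(pattern = character(0), k = integer(0),
                      support = integer(0), support_fraction = numeric(0),
                      degeneracy = numeric(0), rank = integer(0))
    out$occurrences <- list()
    return(out)
  }

  pat <- vapply(hits, `[[`, character(1), "pattern")
  s <- vapply(hits, `[[`, integer(1), "support")
  d <- vapply(pat, .patternDegeneracy, numeric(1))
  ord <- order(-s, d, pat)
  keep <- ord[seq_len(min(maxPatterns, length(ord)))]

  out <- data.frame(pattern = pat[keep], k = k, support = s[keep],
                    support_fraction = s[keep] / n, degeneracy = d[keep],
                    rank = seq_along(keep), stringsAsFactors = FALSE)
  out$occurrences <- lapply(hits[keep], `[[`, "occurrences")
  rownames(out) <- NULL
  out
}

.patternRegex <- function(p) {
  p <- as.PeptidePattern(p)
  paste(vapply(p@positions, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Score a peptide pattern against a protein set
#'
#' Computes support (distinct sequences with at least one match, by
#' per-position set membership) and the occurrence list for an arbitrary
#' pattern, e.g. to re-score a published peptide against new sequences.
#'
#' @inheritParams mineConserved
#' @param pattern A \code{PeptidePattern} or pattern string.
#' @return A one-row data.frame in the format of
#'   \code{\link{mineConserved}} (rank is \code{NA}).
#' @export
scorePattern <- function(proteins, pattern) {
  seqs <- .asProteinSet(proteins)
  p <- as.PeptidePattern(pattern)
  if (length(p) > min(nchar(seqs)))
    stop("pattern longer than the shortest sequence")
  rx <- paste0("(?=", .patternRegex(p), ")")  # lookahead: overlapping hits
  occ <- lapply(names(seqs), function(id) {
    m <- gregexpr(rx, seqs[[id]], perl = TRUE)[[1]]
    if (m[1L] == -1L) return(NULL)
    data.frame(id = id, offset = as.integer(m), stringsAsFactors = FALSE)
  })
  occ <- .rbindList(occ)
  if (is.null(occ)) occ <- data.frame(id = character(0), offset = integer(0))
  s <- length(unique(occ$id))
  out <- data.frame(pattern = patternText(p), k = length(p), support = s,
                    support_fraction = s / length(seqs),
                    degeneracy = .patternDegeneracy(patternText(p)),
                    rank = NA_integer_, stringsAsFactors = FALSE)
  out$occurrences <- list(occ)
  out
}

#' Write a mining report as TSV
#'
#' Occurrences are serialized as comma-separated \code{id:offset} pairs.
#'
#' @param hits Output of \code{\link{mineConserved}} or
#'   \code{\link{scorePattern}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeMiningTsv <- function(hits, path) {
  flat <- hits[, c("pattern", "k", "support", "support_fraction",
                   "degeneracy", "rank")]
  flat$occurrences <- vapply(hits$occurrences, function(o) {
    paste(paste0(o$id, ":", o$offset), collapse = ",")
  }, character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
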