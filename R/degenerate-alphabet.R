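#' @import methods
NULL

# IUPAC base sets. Inosine (I) is carried as a 16th symbol: it base-pairs
# with all four bases (so it matches {A,C,G,T}) but is a single physical
# nucleoside, so it contributes a factor of 1 to degeneracy and 4 to
# coverage fold.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

.DEGEN_ALPHABET <- names(.IUPAC_SETS)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", I = "I"
)

# reverse lookup: sorted concatenated base set -> IUPAC code (I excluded;
# a union of base sets is always expressible with the 15 standard codes)
.SET_TO_CODE <- local({
  codes <- setdiff(.DEGEN_ALPHABET, "I")
  keys <- vapply(codes, function(cd) paste(sort(.IUPAC_SETS[[cd]]), collapse = ""),
                 character(1))
  stats::setNames(codes, keys)
})

# per-symbol degeneracy weight (I counts 1) and coverage weight (I counts 4)
.DEGEN_WEIGHT <- vapply(.IUPAC_SETS, length, integer(1))
.DEGEN_WEIGHT[["I"]] <- 1L
.COVER_WEIGHT <- vapply(.IUPAC_SETS, length, integer(1))

.split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains
.rbindList <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Validate and canonicalize a degenerate DNA sequence
#'
#' Checks that a string contains only the 15 IUPAC DNA codes plus inosine
#' (\code{I}) and returns it uppercased. \code{U} is rejected: this is a
#' DNA-only toolkit.
#'
#' @param x A character string (case-insensitive).
#' @param what Label used in error messages.
#' @return The validated, uppercase string.
#' @examples
#' degenerateSeq("ctiCCigay")
#' @export
degenerateSeq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
  up <- toupper(x)
  if (nchar(up) == 0L) return(up)
  chars <- .split1(up)
  bad <- which(!chars %in% .DEGEN_ALPHABET)
  if (length(bad))
    stop("invalid symbol '", chars[bad[1L]], "' at position ", bad[1L],
         " in ", what, " (allowed: IUPAC DNA codes and inosine I)")
  up
}

.checkConcreteDNA <- function(t, what = "template", allowN = FALSE) {
  up <- toupper(t)
  allowed <- if (allowN) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- .split1(up)
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop("invalid symbol '", chars[bad[1L]], "' at position ", bad[1L],
         " in ", what, " (concrete DNA expected)")
  up
}

#' Complement a single degenerate base
#'
#' IUPAC complementation extended with \code{I -> I}: inosine pairs
#' indiscriminately, so a primer strand written against an inosine position
#' keeps the inosine.
#'
#' @param b One symbol from the degenerate DNA alphabet.
#' @return The complementary symbol.
#' @examples
#' complementBase("Y")  # "R"
#' complementBase("I")  # "I"
#' @export
complementBase <- function(b) {
  b <- degenerateSeq(b, what = "base")
  if (nchar(b) != 1L) stop("complementBase expects a single base")
  unname(.IUPAC_COMPLEMENT[b])
}

#' Reverse-complement a degenerate DNA sequence
#'
#' Per-base IUPAC complement (with \code{I -> I}) in reversed order.
#' An involution: applying it twice returns the input.
#'
#' @param s Degenerate DNA string.
#' @return The reverse complement as an uppercase string.
#' @examples
#' revComp("GAYMGI")  # "ICKRTC"
#' @export
revComp <- function(s) {
  s <- degenerateSeq(s)
  if (nchar(s) == 0L) return(s)
  paste(rev(unname(.IUPAC_COMPLEMENT[.split1(s)])), collapse = "")
}

#' Degeneracy and coverage fold of a degenerate sequence
#'
#' \code{degeneracy()} is the number of distinct oligonucleotide species in
#' the synthesized mixture: the product of per-position IUPAC set sizes with
#' inosine counted as 1 (it is a single physical base). \code{coverageFold()}
#' counts the concrete template sequences the primer can pair with, so
#' inosine counts as 4.
#'
#' @param s Degenerate DNA string.
#' @return A numeric count (may exceed integer range for long primers).
#' @examples
#' degeneracy("GGI")     # 1
#' coverageFold("GGI")   # 4
#' @export
degeneracy <- function(s) {
  s <- degenerateSeq(s)
  if (nchar(s) == 0L) return(1)
  prod(.DEGEN_WEIGHT[.split1(s)])
}

#' @rdname degeneracy
#' @export
coverageFold <- function(s) {
  s <- degenerateSeq(s)
  if (nchar(s) == 0L) return(1)
  prod(.COVER_WEIGHT[.split1(s)])
}

#' Match a degenerate pattern against concrete DNA of equal length
#'
#' Position \code{i} matches iff the template base is in the pattern
#' symbol's IUPAC base set; inosine matches any base. \code{N} in the
#' template matches nothing (it consumes mismatch budget).
#'
#' @param p Degenerate pattern string.
#' @param t Concrete DNA string (A/C/G/T, N tolerated), same length as
#'   \code{p}.
#' @param maxMismatches Mismatch tolerance.
#' @return A list with elements \code{match} (logical) and
#'   \code{mismatches} (integer count).
#' @examples
#' matchesTemplate("CAR", "CAA")              # match, 0 mismatches
#' matchesTemplate("CAR", "CAC")$mismatches   # 1
#' @export
matchesTemplate <- function(p, t, maxMismatches = 0L) {
  p <- degenerateSeq(p, what = "pattern")
  t <- .checkConcreteDNA(t, allowN = TRUE)
  if (nchar(p) != nchar(t))
    stop("pattern and template must have equal length (",
         nchar(p), " vs ", nchar(t), ")")
  pc <- .split1(p)
  tc <- .split1(t)
  mm <- sum(!mapply(function(pb, tb) tb %in% .IUPAC_SETS[[pb]], pc, tc))
  list(match = mm <= maxMismatches, mismatches = as.integer(mm))
}

#' Expand a degenerate sequence to its covered concrete sequences
#'
#' Enumerates every concrete A/C/G/T sequence the pattern can pair with,
#' treating inosine as a 4-fold wildcard. Refuses expansions larger than
#' \code{limit}.
#'
#' @param s Degenerate DNA string.
#' @param limit Maximum number of sequences to enumerate.
#' @return Character vector of concrete sequences (sorted).
#' @examples
#' expandDegenerate("GAY")  # "GAC" "GAT"
#' @export
expandDegenerate <- function(s, limit = 65536L) {
  s <- degenerateSeq(s)
  n <- coverageFold(s)
  if (n > limit)
    stop("expansion of '", s, "' needs ", format(n, scientific = FALSE),
         " sequences, above the limit of ", limit)
  if (nchar(s) == 0L) return("")
  sets <- .IUPAC_SETS[.split1(s)]
  grid <- do.call(expand.grid, c(rev(unname(sets)),
                                 list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}
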