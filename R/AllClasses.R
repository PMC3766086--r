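#' PeptidePattern: an ordered list of per-position residue alternatives
#'
#' A peptide motif in which each position carries one or more allowed
#' amino acids. The text form writes alternatives in brackets, e.g.
#' \code{"WR[FY][DN]WF"}; the slash form \code{"WR(F/Y)(D/N)WF"} is also
#' accepted on input.
#'
#' @slot positions list of character vectors, one per residue position;
#'   each a non-empty set of standard 1-letter codes.
#' @export
setClass("PeptidePattern", representation(positions = "list"))

setValidity("PeptidePattern", function(object) {
  pos <- object@positions
  if (length(pos) < 1L) return("pattern must have at least one position")
  for (i in seq_along(pos)) {
    p <- pos[[i]]
    if (!is.character(p) || length(p) < 1L)
      return(paste0("position ", i, " must be a non-empty character vector"))
    bad <- setdiff(p, .AA20)
    if (length(bad))
      return(paste0("position ", i, " contains non-standard residue '",
                    bad[1L], "'"))
    if (anyDuplicated(p)) return(paste0("position ", i, " has duplicates"))
  }
  TRUE
})

#' Construct or coerce to a PeptidePattern
#'
#' @param x A pattern string (\code{"YWDCCK"}, \code{"WR[FY][DN]WF"} or
#'   \code{"WR(F/Y)(D/N)WF"}), a list of per-position residue vectors, or a
#'   \code{PeptidePattern} (returned unchanged).
#' @return A \code{PeptidePattern}.
#' @examples
#' peptidePattern("WR[FY][DN]WF")
#' @export
peptidePattern <- function(x) {
  if (is(x, "PeptidePattern")) return(x)
  if (is.list(x)) {
    pos <- lapply(x, function(p) sort(unique(toupper(p))))
    return(new("PeptidePattern", positions = pos))
  }
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("peptide pattern must be a non-empty string, list, or PeptidePattern")
  s <- toupper(gsub("[[:space:]]", "", x))
  # normalize (F/Y) style groups to [FY]
  s <- gsub("\\(([A-Z/]+)\\)", "[\\1]", s)
  s <- gsub("/", "", s)
  pos <- list()
  i <- 1L
  chars <- .split1(s)
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        grp <- c(grp, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed '[' in pattern '", x, "'")
      if (length(grp) == 0L) stop("empty alternative set in pattern '", x, "'")
      pos[[length(pos) + 1L]] <- sort(unique(grp))
      i <- j + 1L
    } else if (ch == "]") {
      stop("unmatched ']' in pattern '", x, "'")
    } else {
      pos[[length(pos) + 1L]] <- ch
      i <- i + 1L
    }
  }
  new("PeptidePattern", positions = pos)
}

#' @rdname peptidePattern
#' @export
as.PeptidePattern <- peptidePattern

#' Text form of a PeptidePattern
#'
#' @param p A \code{PeptidePattern}.
#' @return A string with bracketed alternatives, e.g. \code{"WR[FY][DN]WF"}.
#' @export
patternText <- function(p) {
  p <- as.PeptidePattern(p)
  paste(vapply(p@positions, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @describeIn peptidePattern number of residue positions
#' @export
setMethod("length", "PeptidePattern", function(x) length(x@positions))

setMethod("show", "PeptidePattern", function(object) {
  cat("PeptidePattern: ", patternText(object),
      " (", length(object), " positions)\n", sep = "")
})

#' PCRProfile: thermal-cycling metadata attached to a primer
#'
#' Records the thermal profile a primer set is run with. The default
#' profile is an initial denaturation of 95 degrees C for 300 s, 30-40
#' cycles of 95 C/20 s denaturation, annealing for 30 s (temperature
#' optimized per primer set, NA until then) and 72 C/60 s extension, with a
#' final extension of 72 C for 300 s.
#'
#' @slot initialDenaturation numeric (temp C, seconds)
#' @slot cycles integer range (min, max), within 1-99
#' @slot denature,anneal,extend numeric (temp C, seconds); annealing
#'   temperature may be NA (to be optimized per primer set)
#' @slot finalExtension numeric (temp C, seconds)
#' @export
setClass("PCRProfile", representation(
  initialDenaturation = "numeric",
  cycles = "integer",
  denature = "numeric",
  anneal = "numeric",
  extend = "numeric",
  finalExtension = "numeric"
))

setValidity("PCRProfile", function(object) {
  chkStep <- function(x, nm, tempNAok = FALSE) {
    if (length(x) != 2L) return(paste0(nm, " must be (temp, seconds)"))
    if (!tempNAok && is.na(x[1L])) return(paste0(nm, " temperature missing"))
    if (!is.na(x[1L]) && (x[1L] < 0 || x[1L] > 100))
      return(paste0(nm, " temperature outside 0-100 C"))
    if (is.na(x[2L]) || x[2L] <= 0) return(paste0(nm, " duration invalid"))
    TRUE
  }
  for (nm in c("initialDenaturation", "denature", "extend", "finalExtension")) {
    r <- chkStep(slot(object, nm), nm)
    if (!isTRUE(r)) return(r)
  }
  r <- chkStep(object@anneal, "anneal", tempNAok = TRUE)
  if (!isTRUE(r)) return(r)
  cy <- object@cycles
  if (length(cy) != 2L || any(is.na(cy)) || cy[1L] > cy[2L] ||
      cy[1L] < 1L || cy[2L] > 99L)
    return("cycles must be an increasing range within 1-99")
  TRUE
})

#' @rdname PCRProfile-class
#' @param initialDenaturation,denature,anneal,extend,finalExtension numeric
#'   \code{c(temp_C, seconds)} pairs.
#' @param cycles integer \code{c(min, max)} cycle-count range.
#' @return A \code{PCRProfile}.
#' @examples
#' pcrProfile(anneal = c(52, 30), cycles = c(35, 35))
#' @export
pcrProfile <- function(initialDenaturation = c(95, 300),
                       cycles = c(30L, 40L),
                       denature = c(95, 20),
                       anneal = c(NA_real_, 30),
                       extend = c(72, 60),
                       finalExtension = c(72, 300)) {
  new("PCRProfile",
      initialDenaturation = as.numeric(initialDenaturation),
      cycles = as.integer(cycles),
      denature = as.numeric(denature),
      anneal = as.numeric(anneal),
      extend = as.numeric(extend),
      finalExtension = as.numeric(finalExtension))
}

setMethod("show", "PCRProfile", function(object) {
  fmt <- function(x) if (is.na(x[1L])) paste0("Ta/", x[2L], "s")
                     else paste0(x[1L], "C/", x[2L], "s")
  cat("PCRProfile: ", fmt(object@initialDenaturation), " | ",
      object@cycles[1L], "-", object@cycles[2L], " cycles of ",
      fmt(object@denature), ", ", fmt(object@anneal), ", ",
      fmt(object@extend), " | final ", fmt(object@finalExtension), "\n",
      sep = "")
})

#' PrimerRecord: a finished degenerate primer
#'
#' The product of \code{\link{buildPrimer}}: a constant 5' tail plus a
#' degenerate core derived from a peptide, with provenance and PCR
#' metadata. The 3'-terminal base of the core is always concrete (A/C/G/T).
#'
#' @slot name primer name
#' @slot family gene-family label (e.g. GH6/GH7/GH45); may be ""
#' @slot peptide the source \code{PeptidePattern}
#' @slot direction "forward" or "reverse"
#' @slot tail 5' constant extension (degenerate alphabet; concrete in
#'   practice; may be "")
#' @slot core template-binding portion
#' @slot fullSequence tail + core
#' @slot degeneracy number of oligo species in the mixture (inosine = 1)
#' @slot coverageFold number of concrete sequences matched (inosine = 4)
#' @slot partialCoverage TRUE if any codon misses codons of a requested
#'   residue (Ser encoded as TCI misses AGY)
#' @slot pcrMeta a \code{PCRProfile}
#' @export
setClass("PrimerRecord", representation(
  name = "character",
  family = "character",
  peptide = "PeptidePattern",
  direction = "character",
  tail = "character",
  core = "character",
  fullSequence = "character",
  degeneracy = "numeric",
  coverageFold = "numeric",
  partialCoverage = "logical",
  pcrMeta = "PCRProfile"
))

setValidity("PrimerRecord", function(object) {
  if (!object@direction %in% c("forward", "reverse"))
    return("direction must be 'forward' or 'reverse'")
  if (!identical(object@fullSequence, paste0(object@tail, object@core)))
    return("fullSequence must equal tail + core")
  if (nchar(object@core) == 0L) return("core must be non-empty")
  last <- substr(object@core, nchar(object@core), nchar(object@core))
  if (!last %in% c("A", "C", "G", "T"))
    return("3'-terminal base of the core must be concrete (A/C/G/T)")
  TRUE
})

#' Accessors for PrimerRecord
#'
#' @param x A \code{PrimerRecord}.
#' @return The corresponding slot value.
#' @name primer-accessors
NULL

#' @rdname primer-accessors
#' @export
primerName <- function(x) x@name
#' @rdname primer-accessors
#' @export
primerFamily <- function(x) x@family
#' @rdname primer-accessors
#' @export
primerPeptide <- function(x) x@peptide
#' @rdname primer-accessors
#' @export
primerDirection <- function(x) x@direction
#' @rdname primer-accessors
#' @export
primerTail <- function(x) x@tail
#' @rdname primer-accessors
#' @export
primerCore <- function(x) x@core
#' @rdname primer-accessors
#' @export
primerSequence <- function(x) x@fullSequence
#' @rdname primer-accessors
#' @export
primerProfile <- function(x) x@pcrMeta

setMethod("show", "PrimerRecord", function(object) {
  cat("PrimerRecord ", object@name,
      if (nzchar(object@family)) paste0(" [", object@family, "]") else "",
      " (", object@direction, ")\n", sep = "")
  cat("  peptide:  ", patternText(object@peptide), "\n", sep = "")
  cat("  sequence: ", object@fullSequence,
      " (tail ", if (nzchar(object@tail)) object@tail else "-",
      " + core ", object@core, ")\n", sep = "")
  cat("  length ", nchar(object@fullSequence), " nt; degeneracy ",
      object@degeneracy, "; coverage fold ", object@coverageFold,
      if (object@partialCoverage) "; PARTIAL residue coverage" else "",
      "\n", sep = "")
})
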