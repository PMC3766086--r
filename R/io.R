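# FASTA/TSV readers and writers, run configuration, and the command-line
# surface. Tables are tab-separated, unquoted, UTF-8, with a header row
# and a stable column order; FASTA is wrapped at 60 columns. Logging goes
# to standard error so result streams stay clean in pipelines.

.logMsg <- function(...) message("[hexaprimer] ", ...)

#' Read a protein FASTA file into an AAStringSet
#'
#' Multi-line records are joined, whitespace stripped, sequences
#' uppercased. Duplicate identifiers (first header token) and empty
#' records are rejected.
#'
#' @param path FASTA file.
#' @return An \code{AAStringSet}.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  seqs <- .asProteinSet(x)  # dup/empty checks + uppercase
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad))
    stop("record '", names(seqs)[which(bad)[1L]],
         "' contains non-amino-acid letters")
  Biostrings::AAStringSet(seqs)
}

#' Read a DNA template FASTA file into a DNAStringSet
#'
#' Rejects records containing anything but A/C/G/T/N (in particular,
#' amino-acid letters), so protein files cannot be passed by mistake.
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
readDnaFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(x)))
  if (is.null(names(seqs))) names(seqs) <- paste0("template", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate template identifier '",
         names(seqs)[anyDuplicated(names(seqs))], "' in ", path)
  if (any(nchar(seqs) == 0L))
    stop("empty record '", names(seqs)[which(nchar(seqs) == 0L)[1L]],
         "' in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record '", names(seqs)[which(bad)[1L]], "' in ", path,
         " contains letters outside {A,C,G,T,N}; not a DNA template file?")
  Biostrings::DNAStringSet(seqs)
}

#' Write primers as FASTA
#'
#' Inosine is emitted as plain uppercase \code{I}, a documented
#' non-standard FASTA extension (never lowercase).
#'
#' @param primers List of \code{PrimerRecord}s.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writePrimerFasta <- function(primers, path) {
  if (is(primers, "PrimerRecord")) primers <- list(primers)
  seqs <- Biostrings::BStringSet(
    stats::setNames(vapply(primers, primerSequence, character(1)),
                    vapply(primers, primerName, character(1))))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write a primer table as TSV
#'
#' @param primers List of \code{PrimerRecord}s (or a \code{primerTable}
#'   data.frame).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writePrimerTsv <- function(primers, path) {
  tab <- if (is.data.frame(primers)) primers else primerTable(primers)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer TSV back into PrimerRecord objects
#'
#' @param path A file written by \code{\link{writePrimerTsv}}.
#' @return A list of \code{PrimerRecord}s.
#' @export
readPrimerTsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(tab)), function(i) {
    buildPrimer(tab$peptide[i], tab$direction[i], tail = tab$tail[i],
                name = tab$name[i], family = tab$family[i])
  })
}

#' Write amplicon predictions as TSV
#'
#' @param hits Output of \code{\link{predictAmplicons}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeAmpliconTsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable parameters of the mine/design/pcr pipeline.
#' Serializes to plain-text YAML with full round-trip fidelity.
#'
#' @param k Peptide length for mining (default 6).
#' @param minSupportFraction Mining support threshold (default 0.5).
#' @param maxVariablePositions Merge radius for mining (default 0).
#' @param tail 5' tail sequence (default CTGGAC).
#' @param maxMismatches In-silico PCR mismatch budget (default 0).
#' @param anchorLen Zero-mismatch 3' anchor length (default 3).
#' @param minLen,maxLen Product length bounds (default 0, 10000).
#' @param seed Integer seed (default 1).
#' @param outputDir Output directory (default ".").
#' @return A named list of class \code{RunConfig}.
#' @export
runConfig <- function(k = 6L, minSupportFraction = 0.5,
                      maxVariablePositions = 0L, tail = "CTGGAC",
                      maxMismatches = 0L, anchorLen = 3L, minLen = 0L,
                      maxLen = 10000L, seed = 1L, outputDir = ".") {
  cfg <- list(k = as.integer(k),
              minSupportFraction = as.numeric(minSupportFraction),
              maxVariablePositions = as.integer(maxVariablePositions),
              tail = degenerateSeq(tail, what = "tail"),
              maxMismatches = as.integer(maxMismatches),
              anchorLen = as.integer(anchorLen),
              minLen = as.integer(minLen), maxLen = as.integer(maxLen),
              seed = as.integer(seed), outputDir = as.character(outputDir))
  if (cfg$minLen > cfg$maxLen) stop("minLen must not exceed maxLen")
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname runConfig
#' @param config A \code{RunConfig}.
#' @param path Config file (YAML).
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (nm in names(x)) cat("  ", nm, ": ", x[[nm]], "\n", sep = "")
  invisible(x)
}
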