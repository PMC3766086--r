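# Independent oracles for property tests. These re-derive IUPAC semantics
# from their own tables and naive algorithms, deliberately sharing no code
# with the package internals.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

# complement of a degenerate symbol = the symbol whose base set is the
# concrete complement of this symbol's base set; inosine maps to itself
oracleComplementBase <- function(b) {
  if (b == "I") return("I")
  comp <- chartr("ACGT", "TGCA", ORACLE_SETS[[b]])
  key <- paste(sort(comp), collapse = "")
  for (sym in setdiff(names(ORACLE_SETS), "I")) {
    if (paste(sort(ORACLE_SETS[[sym]]), collapse = "") == key) return(sym)
  }
  stop("no complement for ", b)
}

oracleRevComp <- function(s) {
  if (nchar(s) == 0L) return(s)
  chars <- rev(strsplit(s, "")[[1]])
  paste(vapply(chars, oracleComplementBase, character(1)), collapse = "")
}

oracleExpand <- function(s) {
  if (nchar(s) == 0L) return("")
  chars <- strsplit(s, "")[[1]]
  out <- ""
  for (ch in chars) out <- as.vector(outer(out, ORACLE_SETS[[ch]], paste0))
  sort(out)
}

# naive translation by straight genetic-code lookup
oracleTranslate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# naive binding-site scan: every offset, both strands, counting mismatches
# by direct set membership; anchor = 3'-terminal anchorLen core bases
oracleBindingSites <- function(core, tmpl, maxMM = 0L, anchorLen = 3L) {
  m <- nchar(core)
  L <- nchar(tmpl)
  rows <- list()
  scanOne <- function(pat, strand, anchorIdx) {
    pc <- strsplit(pat, "")[[1]]
    tc <- strsplit(tmpl, "")[[1]]
    for (o in 0:(L - m)) {
      mm <- 0L; amm <- 0L
      for (j in seq_len(m)) {
        ok <- tc[o + j] %in% ORACLE_SETS[[pc[j]]]
        if (!ok) {
          mm <- mm + 1L
          if (j %in% anchorIdx) amm <- amm + 1L
        }
      }
      if (mm <= maxMM && amm == 0L)
        rows[[length(rows) + 1L]] <<- data.frame(
          strand = strand, start = o, end = o + m, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (L >= m) {
    scanOne(core, "+", if (anchorLen > 0L) (m - anchorLen + 1L):m else integer(0))
    scanOne(oracleRevComp(core), "-",
            if (anchorLen > 0L) seq_len(anchorLen) else integer(0))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

randomDegenerateSeq <- function(len, alphabet = names(ORACLE_SETS)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

randomConcreteDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

AA_NO_LRS <- setdiff(strsplit("ACDEFGHIKMNPQTVWY", "")[[1]], character(0))
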