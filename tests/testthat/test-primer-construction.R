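test_that("3' wobble trimming stops at the first concrete base", {
  expect_identical(trimWobble("CTICCIGAYMGIGAYTGY"), "CTICCIGAYMGIGAYTG")
  expect_identical(trimWobble("GAYGCIAAYTGGMGITGG"), "GAYGCIAAYTGGMGITGG")
  expect_identical(trimWobble("TGG"), "TGG")
  expect_identical(trimWobble("TGGYI"), "TGG")  # loops past several wobbles
  expect_error(trimWobble("YRI"), "every base")
  expect_error(trimWobble(""), "empty")
})

test_that("buildPrimer reproduces published forward and reverse examples", {
  expect_identical(
    primerSequence(buildPrimer("LPDRDC", "forward", tail = "CAGGTC")),
    "CAGGTCCTICCIGAYMGIGAYTG")
  expect_identical(
    primerSequence(buildPrimer("VVTQF", "reverse", tail = "CTGGAC")),
    "CTGGACAAYTGIGTIACIAC")
  expect_identical(
    primerSequence(buildPrimer("YWDCCK", "forward", tail = "CAGGTC")),
    "CAGGTCTAYTGGGAYTGYTGYAA")
  expect_identical(
    primerSequence(buildPrimer("EMDIWEA", "reverse", tail = "CTGGAC")),
    "CTGGACGCYTCCCADATRTCCATYTC")
  expect_identical(primerSequence(buildPrimer("W", "forward", tail = "")),
                   "TGG")
})

test_that("PrimerRecord invariants hold for random peptides", {
  set.seed(5)
  for (i in 1:60) {
    k <- sample(4:7, 1)
    pep <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k,
                        replace = TRUE), collapse = "")
    fwd <- buildPrimer(pep, "forward")
    rev <- buildPrimer(pep, "reverse")
    # full = tail + core, concrete 3' terminus, core length within bounds
    for (p in list(fwd, rev)) {
      expect_identical(primerSequence(p),
                       paste0(primerTail(p), primerCore(p)))
      last <- substr(primerCore(p), nchar(primerCore(p)),
                     nchar(primerCore(p)))
      expect_true(last %in% c("A", "C", "G", "T"))
      expect_true(nchar(primerCore(p)) >= 3 * k - 2 &&
                  nchar(primerCore(p)) <= 3 * k)
      expect_identical(nchar(primerSequence(p)),
                       nchar(primerTail(p)) + nchar(primerCore(p)))
    }
    # reverse core is the reverse complement of the forward core, minus
    # any degenerate bases the complementation exposes at the new 3' end
    expect_identical(primerCore(rev), trimWobble(revComp(primerCore(fwd))))
  }
})

test_that("primer degeneracy and coverage are computed on the full sequence", {
  p <- buildPrimer("LPDRDC", "forward", tail = "CAGGTC")
  expect_equal(p@degeneracy, degeneracy("CAGGTCCTICCIGAYMGIGAYTG"))
  expect_equal(p@coverageFold, coverageFold("CAGGTCCTICCIGAYMGIGAYTG"))
  expect_false(p@partialCoverage)
  expect_true(buildPrimer("WSW", "forward")@partialCoverage)
})

test_that("the published primer table verifies as 18 exact and 2 deviant rows", {
  suite <- table2Suite()
  expect_equal(nrow(suite), 20)
  expect_setequal(unique(suite$tail), c("CAGGTC", "CTGGAC"))
  expect_equal(sum(suite$fidelity == "exact"), 18)
  expect_equal(table(suite$family)[["GH6"]], 8)
  expect_equal(table(suite$family)[["GH7"]], 6)
  expect_equal(table(suite$family)[["GH45"]], 6)

  rep <- verifyTable2()
  expect_identical(rep$match, rep$fidelity == "exact")
  # the two hand-edited rows deviate by exactly 1 and 2 bases
  dev <- rep[rep$fidelity == "deviant", ]
  expect_setequal(dev$peptide, c("GWLGWP", "WR[FY][DN]WF"))
  expect_equal(sort(dev$n_diff), c(1L, 2L))
})

test_that("primerTable has stable columns and one row per primer", {
  ps <- list(buildPrimer("LPDRDC", "forward", tail = "CAGGTC"),
             buildPrimer("VVTQF", "reverse"))
  tab <- primerTable(ps)
  expect_identical(names(tab),
                   c("name", "family", "peptide", "direction", "tail",
                     "core", "full_sequence", "length", "degeneracy",
                     "coverage_fold", "partial_coverage"))
  expect_equal(nrow(tab), 2)
  expect_identical(tab$full_sequence[1], "CAGGTCCTICCIGAYMGIGAYTG")
})

test_that("PCR profile validity catches out-of-range settings", {
  expect_s4_class(pcrProfile(), "PCRProfile")
  expect_error(pcrProfile(cycles = c(0L, 40L)), "cycles")
  expect_error(pcrProfile(denature = c(150, 20)), "temperature")
  p <- buildPrimer("YWDCCK", "forward",
                   pcrMeta = pcrProfile(anneal = c(48, 30)))
  expect_equal(primerProfile(p)@anneal, c(48, 30))
})
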