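test_that("binding sites are found on both strands with degenerate cores", {
  s <- findBindingSites("TGGGAY", "AATGGGACAAA")
  expect_equal(nrow(s), 1)
  expect_identical(s$strand, "+")
  expect_equal(s$start, 2L)
  expect_equal(s$end, 8L)
  # reverse-complement matching: GTCCCA on + strand is a - strand site
  s <- findBindingSites("TGGGAY", "AAGTCCCAAAA")
  expect_equal(nrow(s), 1)
  expect_identical(s$strand, "-")
  expect_equal(s$start, 2L)
})

test_that("the 3' anchor must match with zero mismatches", {
  # last 3 core bases YTG vs CTA mismatch at the final position
  expect_equal(nrow(findBindingSites("GAYTG", "GACTA", maxMismatches = 2,
                                     anchorLen = 3)), 0)
  # the same site is accepted once the anchor is relaxed
  expect_equal(nrow(findBindingSites("GAYTG", "GACTA", maxMismatches = 2,
                                     anchorLen = 0)), 1)
  # core longer than template: empty result, not an error
  expect_equal(nrow(findBindingSites("TGGGAYTGG", "ACGT")), 0)
})

test_that("scanning equals the brute-force oracle, mismatches included", {
  set.seed(12)
  for (rep in 1:25) {
    core <- randomDegenerateSeq(sample(8:15, 1))
    if (coverageFold(core) > 4096) next
    tmpl <- randomConcreteDNA(sample(100:300, 1))
    for (mm in 0:2) {
      got <- findBindingSites(core, tmpl, maxMismatches = mm, anchorLen = 3)
      want <- oracleBindingSites(core, tmpl, maxMM = mm, anchorLen = 3)
      rownames(got) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("tails never affect binding", {
  tmpl <- paste0(randomConcreteDNA(50), "TGGGACTATTGC", randomConcreteDNA(50))
  a <- buildPrimer("WDYC", "forward", tail = "CTGGAC")
  b <- buildPrimer("WDYC", "forward", tail = "")
  c <- buildPrimer("WDYC", "forward", tail = "AAAAAAAAAA")
  sa <- findBindingSites(a, tmpl)
  expect_identical(sa, findBindingSites(b, tmpl))
  expect_identical(sa, findBindingSites(c, tmpl))
})

test_that("amplicons are predicted from constructed templates", {
  fwd <- buildPrimer("YWDCCK", "forward")
  rev <- buildPrimer("EFTFDVD", "reverse")
  fCore <- primerCore(fwd)                 # sense
  rSense <- revComp(primerCore(rev))       # the + strand site of the rev core
  spacer <- randomConcreteDNA(200)
  tmpl <- c(t1 = paste0("ACGT", fCore, spacer, rSense, "ACGT"))
  tmpl <- gsub("Y", "C", tmpl); tmpl <- gsub("R", "A", tmpl)
  tmpl <- gsub("I", "G", tmpl); tmpl <- gsub("W", "A", tmpl)
  tmpl <- gsub("H", "C", tmpl); tmpl <- gsub("M", "A", tmpl)
  tmpl <- gsub("K", "G", tmpl); tmpl <- gsub("S", "C", tmpl)
  hits <- predictAmplicons(fwd, rev, tmpl)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$product_length,
               nchar(fCore) + 200 + nchar(primerCore(rev)))
  expect_identical(hits$strand, "+")
  expect_equal(hits$mismatches_forward + hits$mismatches_reverse, 0L)
  # a length filter above the construction removes the hit
  none <- predictAmplicons(fwd, rev, tmpl,
                           minLen = hits$product_length + 1)
  expect_equal(nrow(none), 0)
})

test_that("reverse-complementing the template mirrors every hit", {
  set.seed(77)
  fwd <- buildPrimer("YWDCCK", "forward")
  rev <- buildPrimer("WDCCKP", "reverse")
  gen <- generateTemplates(
    c(p1 = paste0(paste(rep("A", 10), collapse = ""), "YWDCCK",
                  paste(rep("G", 10), collapse = ""), "WDCCKP",
                  paste(rep("T", 5), collapse = ""))),
    "YWDCCK", "WDCCKP", spacer = c(60L, 60L), seed = 4)
  tmpl <- as.character(gen$templates)
  hits <- predictAmplicons(fwd, rev, tmpl)
  rcTmpl <- stats::setNames(revComp(tmpl[[1]]), names(tmpl))
  rcHits <- predictAmplicons(fwd, rev, rcTmpl)
  expect_equal(nrow(hits), nrow(rcHits))
  expect_equal(hits$product_length, rcHits$product_length)
  expect_equal(hits$mismatches_forward, rcHits$mismatches_forward)
  expect_equal(hits$mismatches_reverse, rcHits$mismatches_reverse)
  expect_identical(sort(c(hits$strand, rcHits$strand)), c("+", "-"))
})

test_that("products come out in product orientation with translations", {
  fwd <- buildPrimer("YWDCCK", "forward")
  rev <- buildPrimer("WDCCKP", "reverse")
  gen <- generateTemplates(
    c(p1 = paste0("MMMMM", "YWDCCK", "GGGGG", "WDCCKP", "HHHHH")),
    "YWDCCK", "WDCCKP", spacer = c(90L, 90L), seed = 9)
  hits <- predictAmplicons(fwd, rev, gen$templates)
  expect_equal(nrow(hits), 1)
  prod <- extractProducts(hits, gen$templates)
  expect_equal(length(prod$products), 1)
  expect_equal(nchar(as.character(prod$products[[1]])),
               hits$product_length)
  # product starts with a match to the forward core
  head <- substr(as.character(prod$products[[1]]), 1,
                 nchar(primerCore(fwd)))
  expect_true(matchesTemplate(primerCore(fwd), head)$match)
  # a - strand hit returns the reverse complement of the slice
  rcTmpl <- stats::setNames(revComp(as.character(gen$templates)[[1]]), "p1")
  rcHits <- predictAmplicons(fwd, rev, rcTmpl)
  rcProd <- extractProducts(rcHits, rcTmpl)
  expect_identical(as.character(rcProd$products[[1]]),
                   as.character(prod$products[[1]]))
  expect_identical(prod$translations[[1]],
                   translateFrames(as.character(prod$products[[1]])))
})

test_that("byte-identical output for identical inputs", {
  fwd <- buildPrimer("YWDCCK", "forward")
  rev <- buildPrimer("EFTFDVD", "reverse")
  set.seed(3); tmpls <- c(x = randomConcreteDNA(500), y = randomConcreteDNA(500))
  h1 <- predictAmplicons(fwd, rev, tmpls, maxMismatches = 2)
  h2 <- predictAmplicons(fwd, rev, tmpls, maxMismatches = 2)
  expect_identical(h1, h2)
})
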