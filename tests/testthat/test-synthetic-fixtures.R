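test_that("zero substitution rate with full conservation gives clones", {
  fam <- generateFamily(5, 40, list(list(pattern = "YWDCCK", position = 10,
                                         fraction = 1)),
                        substitutionRate = 0, seed = 2)
  seqs <- as.character(fam)
  expect_equal(length(unique(seqs)), 1)
  expect_identical(substr(seqs[[1]], 10, 15), "YWDCCK")
})

test_that("conservation fraction is honored exactly by the rounding rule", {
  fam <- generateFamily(10, 60, list(list(pattern = "YWDCCK", position = 20,
                                          fraction = 0.5)),
                        substitutionRate = 0.2, seed = 8)
  n <- sum(vapply(as.character(fam), function(s)
    grepl("YWDCCK", s, fixed = TRUE), logical(1)))
  expect_equal(n, 5)
})

test_that("generators are pure functions of their seeds", {
  f1 <- generateFamily(8, 100, list(list(pattern = "GTGYCD", position = 30)),
                       0.3, seed = 5)
  f2 <- generateFamily(8, 100, list(list(pattern = "GTGYCD", position = 30)),
                       0.3, seed = 5)
  f3 <- generateFamily(8, 100, list(list(pattern = "GTGYCD", position = 30)),
                       0.3, seed = 6)
  expect_identical(as.character(f1), as.character(f2))
  expect_false(identical(as.character(f1), as.character(f3)))
  # and the caller's RNG stream is untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generateFamily(3, 30, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("motifs with alternatives produce mergeable variants", {
  fam <- generateFamily(20, 80,
                        list(list(pattern = "WR[FY][DN]WF", position = 40)),
                        substitutionRate = 0.3, seed = 13)
  hits <- mineConserved(fam, k = 6, minSupportFraction = 0.9,
                        maxVariablePositions = 2)
  expect_equal(hits$pattern[1], "WR[FY][DN]WF")
  expect_equal(hits$support[1], 20L)
})

test_that("templates carry the planted sites at the recorded coordinates", {
  fam <- generateFamily(6, 90, list(list(pattern = "YWDCCK", position = 10),
                                    list(pattern = "EFTFDVD", position = 60)),
                        substitutionRate = 0.25, seed = 21)
  gen <- generateTemplates(fam, "YWDCCK", "EFTFDVD", spacer = c(150L, 150L),
                           seed = 22)
  fwd <- buildPrimer("YWDCCK", "forward")
  rev <- buildPrimer("EFTFDVD", "reverse")
  expect_equal(nrow(gen$truth), 6)
  expect_true(all(gen$truth$spacer == 150))
  for (i in seq_len(nrow(gen$truth))) {
    id <- gen$truth$template[i]
    tmpl <- as.character(gen$templates)[[id]]
    sitesF <- findBindingSites(fwd, tmpl)
    sitesR <- findBindingSites(rev, tmpl)
    expect_equal(sitesF$start, gen$truth$fwd_start[i])
    expect_equal(sitesF$strand, "+")
    expect_equal(sitesR$start, gen$truth$rev_start[i])
    expect_equal(sitesR$strand, "-")
    expect_equal(gen$truth$rev_start[i] - gen$truth$fwd_end[i], 150)
  }
})

test_that("translating the coding regions reproduces the protein segments", {
  fam <- generateFamily(4, 70, list(list(pattern = "YWDCCK", position = 15),
                                    list(pattern = "GTGYCD", position = 50)),
                        substitutionRate = 0.2, seed = 33)
  gen <- generateTemplates(fam, "YWDCCK", "GTGYCD", spacer = c(120L, 120L),
                           seed = 34)
  prots <- as.character(fam)
  for (id in names(prots)) {
    tmpl <- as.character(gen$templates)[[id]]
    p <- prots[[id]]
    # the 5' coding region runs through the end of the forward motif
    p1end <- 15 + 6 - 1
    lead <- substr(tmpl, 1, 3 * p1end)
    expect_identical(translateFrames(lead)[["+1"]], substr(p, 1, p1end))
    # the 3' coding region starts at the reverse motif
    tailLen <- 3 * (nchar(p) - 50 + 1)
    trail <- substr(tmpl, nchar(tmpl) - tailLen + 1, nchar(tmpl))
    expect_identical(translateFrames(trail)[["+1"]],
                     substr(p, 50, nchar(p)))
  }
})

test_that("an intron between the sites lengthens the product additively", {
  fam <- generateFamily(3, 60, list(list(pattern = "YWDCCK", position = 5),
                                    list(pattern = "WDCCKP", position = 40)),
                        substitutionRate = 0.1, seed = 44)
  plain <- generateTemplates(fam, "YWDCCK", "WDCCKP", spacer = c(100L, 100L),
                             seed = 45)
  # insert the intron in the middle of the spacer region of each template
  pos <- plain$truth$fwd_end[1] + 50
  spliced <- generateTemplates(fam, "YWDCCK", "WDCCKP",
                               spacer = c(100L, 100L),
                               introns = list(c(pos, 80)), seed = 45)
  expect_equal(spliced$truth$expected_product_length,
               plain$truth$expected_product_length + 80)
  fwd <- buildPrimer("YWDCCK", "forward")
  rev <- buildPrimer("WDCCKP", "reverse")
  h0 <- predictAmplicons(fwd, rev, plain$templates)
  h1 <- predictAmplicons(fwd, rev, spliced$templates)
  expect_equal(h1$product_length, h0$product_length + 80)
  # GT...AG termini
  tmpl <- as.character(spliced$templates)[[1]]
  expect_identical(substr(tmpl, pos + 1, pos + 2), "GT")
  expect_identical(substr(tmpl, pos + 79, pos + 80), "AG")
})

test_that("malformed generator arguments are caught", {
  expect_error(generateFamily(5, 10, list(list(pattern = "YWDCCKYWDCCK",
                                               position = 5))), "fit")
  expect_error(generateFamily(5, 30, list(
    list(pattern = "YWDCCK", position = 5),
    list(pattern = "GTGYCD", position = 8))), "overlap")
  fam <- generateFamily(3, 40, list(list(pattern = "YWDCCK", position = 10)),
                        0.1, seed = 1)
  expect_error(generateTemplates(fam, "YWDCCK", "EFTFDVD"), "not found")
})
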