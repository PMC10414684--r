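test_that("PSM tiers are a monotone step function with inclusive bounds", {
  expect_equal(psmTier(55.71), "high")
  expect_equal(psmTier(47.4), "high")
  expect_equal(psmTier(47.39), "medium")
  expect_equal(psmTier(20), "medium")
  expect_equal(psmTier(19.99), "low")
  expect_equal(psmTier(13), "low")
  expect_equal(psmTier(12.9), "rejected")
  # monotone: tier rank never improves as the score drops
  scores <- seq(60, 5, by = -0.7)
  ranks <- match(psmTier(scores), c("rejected", "low", "medium", "high"))
  expect_true(all(diff(ranks) <= 0))
})

test_that("b/y ladder values match hand-computed masses for GG", {
  l <- fragmentLadder(ModifiedPeptide("GG"))
  expect_equal(unname(l$b["b1"]), 58.0287, tolerance = 1e-3)
  expect_equal(unname(l$y["y1"]), 76.0393, tolerance = 1e-3)
  expect_length(l$b, 1L)
  expect_length(l$y, 1L)
})

test_that("b/y complementarity holds for every generated ladder", {
  set.seed(61)
  peps <- c(randomPeptides(15, c(5, 30)), "YGGVYSKT")
  for (s in peps) {
    p <- ModifiedPeptide(s)
    l <- fragmentLadder(p)
    n <- nchar(s)
    neutral <- monoisotopicMass(p)
    for (i in seq_len(n - 1))
      expect_equal(unname(l$b[i] + l$y[n - i]), neutral + 2 * 1.007276,
                   tolerance = 1e-3)
    # y-series maximum stays below the protonated neutral mass
    expect_lt(max(l$y), neutral + 1.007276)
  }
})

test_that("terminal and residue modifications travel with their fragment", {
  plain <- fragmentLadder(ModifiedPeptide("QGWG"))
  pyro <- fragmentLadder(ModifiedPeptide("QGWG", nTerm = "pyro_glu"))
  expect_equal(unname(pyro$b - plain$b), rep(-17.026549, 3),
               tolerance = 1e-5)
  expect_equal(unname(pyro$y), unname(plain$y), tolerance = 1e-9)
  amide <- fragmentLadder(ModifiedPeptide("QGWG", cTerm = "amide"))
  expect_equal(unname(amide$y - plain$y), rep(-0.984016, 3),
               tolerance = 1e-5)
  expect_equal(unname(amide$b), unname(plain$b), tolerance = 1e-9)
  ox <- fragmentLadder(ModifiedPeptide("GMGG",
                                       residueMods = c("2" = "oxidation")))
  plain2 <- fragmentLadder(ModifiedPeptide("GMGG"))
  expect_equal(unname(ox$b - plain2$b), c(0, rep(15.994915, 2)),
               tolerance = 1e-5)
})

test_that("consecutive-ion rule needs a k-run within one series", {
  expect_true(consecutiveIonCheck(c("b2", "b3", "b4")))
  expect_false(consecutiveIonCheck(c("b2", "b4", "y1", "y3")))
  expect_false(consecutiveIonCheck(c("b1", "b2", "y3")))
  expect_true(consecutiveIonCheck(c("y5", "y7", "y6")))
  expect_false(consecutiveIonCheck(character()))
  expect_error(consecutiveIonCheck("a3"), "malformed")
  # brute-force window oracle on random matched sets
  set.seed(62)
  for (rep in 1:50) {
    bidx <- sort(sample(1:12, sample(0:6, 1)))
    yidx <- sort(sample(1:12, sample(0:6, 1)))
    ions <- c(paste0("b", bidx, recycle0 = TRUE),
              paste0("y", yidx, recycle0 = TRUE))
    brute <- any(vapply(1:10, function(st)
      all(st:(st + 2) %in% bidx) || all(st:(st + 2) %in% yidx),
      logical(1)))
    expect_equal(consecutiveIonCheck(ions), brute,
                 info = paste(ions, collapse = ","))
  }
})

test_that("sequence coverage is the interval union at the chosen tier", {
  # one 8-mer PSM on a 27-residue mature region within a 68-aa precursor
  psms <- data.frame(start = 61L, end = 68L, tier = "high")
  expect_equal(sequenceCoverage(27L, data.frame(start = 10L, end = 17L,
                                                tier = "high"), "high"),
               30L)
  expect_equal(sequenceCoverage(100L, psms[0, ], "low"), 0L)
  # overlapping PSMs never double-count
  two <- data.frame(start = c(3L, 8L), end = c(10L, 12L),
                    tier = c("high", "high"))
  expect_equal(sequenceCoverage(20L, two, "high"), 50L)
})

test_that("coverage grows monotonically as the tier cutoff is relaxed", {
  set.seed(63)
  for (rep in 1:10) {
    n <- 80L
    psms <- data.frame(
      start = sample(1:70, 12, TRUE),
      score = runif(12, 5, 60))
    psms$end <- pmin(psms$start + sample(5:15, 12, TRUE), n)
    psms$tier <- psmTier(psms$score)
    cov <- vapply(c("high", "medium", "low"), function(t)
      sequenceCoverage(n, psms, t), integer(1))
    expect_true(all(diff(cov) >= 0))
  }
})

test_that("PSM tables read with derived tiers and validated coordinates", {
  tf <- tempfile()
  writeLines(c(
    "precursor_id\tsequence\tstart\tend\tscore\tmatched_ions",
    "prec1\tYGGVYSKT\t61\t68\t55.71\tb2;b3;b4;y5",
    "prec1\tPPPPP\t56\t60\t18.2\t"), tf)
  psms <- readPsmTable(tf)
  expect_equal(psms$tier, c("high", "low"))
  expect_equal(psms$matched_ions[[1]], c("b2", "b3", "b4", "y5"))
  expect_true(consecutiveIonCheck(psms$matched_ions[[1]]))
  writeLines(c("precursor_id\tsequence\tstart\tend\tscore",
               "prec1\tYGGVYSKT\t61\t67\t55.71"), tf)
  expect_error(readPsmTable(tf), "inconsistent")
})
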