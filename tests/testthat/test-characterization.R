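test_that("monoisotopic masses reproduce the detected-peptide values", {
  tol <- 0.001
  expect_equal(monoisotopicMass(ModifiedPeptide("YGGVYSKT")),
               873.4232, tolerance = tol)
  expect_equal(monoisotopicMass(
    ModifiedPeptide("QELAEDFSPDKRGMSS", nTerm = "pyro_glu")),
    1778.7781, tolerance = tol)
  expect_equal(monoisotopicMass(
    ModifiedPeptide("QELAEDFSPDKRGMSS", nTerm = "pyro_glu",
                    residueMods = c("14" = "oxidation"))),
    1794.7729, tolerance = tol)
  expect_equal(monoisotopicMass(ModifiedPeptide("PPPPPPPPPPP")),
               1085.5909, tolerance = tol)
  expect_equal(monoisotopicMass(ModifiedPeptide("PGPPGPPG")),
               674.3387, tolerance = tol)
  expect_equal(monoisotopicMass(ModifiedPeptide("VIDDIKEIRIFE")),
               1488.8187, tolerance = tol)
  expect_equal(monoisotopicMass(ModifiedPeptide("AVDEVTSTKDGATW")),
               1478.6888, tolerance = tol)
  expect_equal(monoisotopicMass(
    ModifiedPeptide("GTLVMSSQFMLQ", residueMods = c("10" = "oxidation"))),
    1356.6417, tolerance = tol)
  expect_equal(monoisotopicMass(
    ModifiedPeptide("QGWGEYGGNGGGR", nTerm = "pyro_glu")),
    1276.5221, tolerance = tol)
})

test_that("monoisotopic mass is additive up to one water", {
  set.seed(51)
  for (i in 1:10) {
    parts <- randomPeptides(2, c(5, 25))
    whole <- monoisotopicMass(ModifiedPeptide(paste0(parts[1], parts[2])))
    expect_equal(whole,
                 monoisotopicMass(ModifiedPeptide(parts[1])) +
                   monoisotopicMass(ModifiedPeptide(parts[2])) - 18.010565,
                 tolerance = 1e-3)
  }
})

test_that("modification deltas are exact", {
  base <- ModifiedPeptide("QELAEDFSPDKRGMSS", nTerm = "pyro_glu")
  ox <- ModifiedPeptide("QELAEDFSPDKRGMSS", nTerm = "pyro_glu",
                        residueMods = c("14" = "oxidation"))
  expect_equal(monoisotopicMass(ox) - monoisotopicMass(base),
               15.9949, tolerance = 2e-4)
  free <- ModifiedPeptide("AAKWAAK")
  amide <- ModifiedPeptide("AAKWAAK", cTerm = "amide")
  expect_equal(monoisotopicMass(free) - monoisotopicMass(amide),
               0.984, tolerance = 1e-3)
  expect_equal(averageMass(free) - averageMass(amide), 0.985,
               tolerance = 1e-3)
})

test_that("ModifiedPeptide validity catches impossible states", {
  expect_error(ModifiedPeptide("ALAEDFS", nTerm = "pyro_glu"), "Q or E")
  expect_error(ModifiedPeptide("AAK", residueMods = c("9" = "oxidation")),
               "outside")
  expect_error(ModifiedPeptide("ABZ"), "non-standard")
})

test_that("average mass matches an independent residue-table summation", {
  # independent hand-summed values
  expect_equal(averageMass(ModifiedPeptide("GG")), 132.12, tolerance = 0.01)
  p249 <- "GFGKWVKKKWGSVRKGASKLVKGVKKVFPKKGIPIIRYERRF"
  expect_equal(averageMass(ModifiedPeptide(p249)), 4889.0, tolerance = 0.1)
})

test_that("MIC conversions reproduce the published micromolar values", {
  p249 <- ModifiedPeptide("GFGKWVKKKWGSVRKGASKLVKGVKKVFPKKGIPIIRYERRF")
  expect_equal(micToMicromolar(c(8, 16, 128, 512), p249),
               c(2L, 3L, 26L, 105L))
  p298 <- ModifiedPeptide(
    "GAGRWRANRRANRRRFARRLRRNQRRAAQKRRAHARRHQRNLRRAARKIRRIQRR",
    cTerm = "amide")
  expect_equal(micToMicromolar(c(64, 32), p298), c(9L, 5L))
  p18 <- ModifiedPeptide("GTFWKAVGAGALIGGGAALLSKAFK", cTerm = "amide")
  expect_equal(micToMicromolar(64, p18), 27L)
  expect_error(micToMicromolar(0, p18))
})

test_that("net charge follows the simple counting model", {
  expect_equal(netCharge(ModifiedPeptide("KKDD")), 0)
  expect_equal(netCharge(ModifiedPeptide(strrep("R", 10), cTerm = "amide")),
               11)
  expect_equal(netCharge(ModifiedPeptide("HH")), 1)  # 2x0.5 + termini 0
  # pyro-glu suppresses the N-terminal positive charge
  expect_equal(netCharge(ModifiedPeptide("QKK", nTerm = "pyro_glu")), 1)
  # arginine-rich amidated peptide is strongly cationic
  p298 <- ModifiedPeptide(
    "GAGRWRANRRANRRRFARRLRRNQRRAAQKRRAHARRHQRNLRRAARKIRRIQRR",
    cTerm = "amide")
  expect_gt(netCharge(p298), 25)
  # Henderson-Hasselbalch model agrees in sign and rough magnitude
  expect_gt(netCharge(p298, model = "hh"), 25)
})

test_that("hydrophobic percentage counts the stated residue set", {
  expect_equal(hydrophobicFraction(strrep("L", 12)), 100L)
  expect_equal(hydrophobicFraction(strrep("K", 12)), 0L)
  s <- "GTFWKAVGAGALIGGGAALLSKAFK"
  res <- strsplit(s, "")[[1]]
  brute <- round(100 * sum(res %in% c("A","C","F","I","L","M","V","W")) /
                   length(res))
  expect_equal(hydrophobicFraction(s), as.integer(brute))
})

test_that("characterizePeptides assembles a coherent descriptor table", {
  tab <- characterizePeptides(c(a = "GTFWKAVGAGALIGGGAALLSKAFKG",
                                b = "ACKKAC"))
  expect_equal(tab$synthesis_sequence[1], "GTFWKAVGAGALIGGGAALLSKAFK")
  expect_true(tab$amidated[1])
  expect_false(tab$amidated[2])
  expect_equal(tab$cysteine_class, c("linear", "two_cysteine"))
  expect_equal(tab$length, c(26L, 6L))
})
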