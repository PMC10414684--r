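test_that("heuristic signal end finds hydrophobic h-regions only", {
  polyL <- paste0("M", strrep("L", 10), strrep("A", 30))
  expect_false(is.na(heuristicSignalEnd(polyL)))
  expect_true(is.na(heuristicSignalEnd(paste0("M", strrep("D", 40)))))
  # too short for the search range
  expect_true(is.na(heuristicSignalEnd("MLLLLLLLLL")))
  # predicted end is capped at 35
  late <- paste0("M", strrep("D", 21), strrep("L", 30))
  expect_lte(heuristicSignalEnd(late), 35L)
})

test_that("planted signal peptides are recovered within 3 residues", {
  b <- defaultFixture()
  prot <- fixtureProteome()
  truth <- b$truth
  pred <- vapply(as.character(prot)[truth$protein_id],
                 heuristicSignalEnd, integer(1))
  hits <- abs(pred - truth$signal_end) <= 3L
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("dibasic sites mark the second residue, overlaps included", {
  expect_equal(dibasicSites("AAKRAA"), 4L)
  expect_equal(dibasicSites("AKRRA"), c(3L, 4L))
  expect_equal(dibasicSites("AAAA"), integer())
  # brute-force scan oracle on a long random sequence
  set.seed(11)
  s <- paste(sample(c("A","R","N","D","K","G","S","T"), 1000, TRUE),
             collapse = "")
  res <- strsplit(s, "")[[1]]
  brute <- integer()
  for (i in 1:999)
    if (paste0(res[i], res[i + 1]) %in% c("KR", "RR", "KK", "RK"))
      brute <- c(brute, i + 1L)
  expect_equal(dibasicSites(s), brute)
})

test_that("all_pairs excision yields m(m-1)/2 peptides at correct slices", {
  x <- aaset(c(p1 = strrep("ANSPQT", 14)))  # 84 aa
  ann <- data.frame(protein_id = "p1", signal_end = 20L)
  ann$propeptide_sites <- list(c(35L, 50L))
  out <- enumeratePeptides(x, ann)
  expect_equal(nrow(out), 6L)  # B = {20, 35, 50, 84}, choose(4,2)
  expect_true(all(out$sequence ==
                    substring(as.character(x)[["p1"]], out$start, out$end)))
  expect_true(all(out$start > 20L))
  seg <- enumeratePeptides(x, ann, mode = "segments")
  expect_equal(nrow(seg), 3L)
  expect_true(all(seg$peptide_id %in% out$peptide_id))
  # no propeptide sites: single peptide from signal end to C-terminus
  ann2 <- data.frame(protein_id = "p1", signal_end = 20L)
  ann2$propeptide_sites <- list(integer())
  one <- enumeratePeptides(x, ann2)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(21L, 84L))
})

test_that("excision combinatorics hold across the fixture proteome", {
  prot <- fixtureProteome()
  ann <- heuristicAnnotations(prot)
  out <- enumeratePeptides(prot, ann)
  # per-precursor count is m(m-1)/2 with m boundaries
  for (i in seq_len(nrow(ann))) {
    L <- Biostrings::width(prot)[match(ann$protein_id[i], names(prot))]
    m <- length(unique(c(ann$signal_end[i], ann$propeptide_sites[[i]], L)))
    expect_equal(sum(out$protein_id == ann$protein_id[i]), m * (m - 1) / 2)
  }
  # every peptide equals its coordinate slice on the precursor
  prec <- as.character(prot)[out$protein_id]
  expect_true(all(out$sequence == substring(prec, out$start, out$end)))
})

test_that("length gate boundaries: 10..99 kept, 9 and 100 removed", {
  x <- aaset(c(p = strrep("A", 130)))
  make <- function(len) data.frame(
    peptide_id = "q", protein_id = "p", genome_id = "g1",
    start = 21L, end = 20L + len, length = len,
    sequence = strrep("A", len))
  expect_equal(nrow(lengthGate(make(9L))), 0L)
  expect_equal(nrow(lengthGate(make(10L))), 1L)
  expect_equal(nrow(lengthGate(make(99L))), 1L)
  expect_equal(nrow(lengthGate(make(100L))), 0L)
})

test_that("length gate matches a brute-force recount on the fixture", {
  prot <- fixtureProteome()
  cand <- enumeratePeptides(prot, heuristicAnnotations(prot))
  gated <- lengthGate(cand)
  expect_equal(nrow(gated), sum(cand$length >= 10 & cand$length <= 99))
  expect_equal(attr(gated, "n_removed"), nrow(cand) - nrow(gated))
})

test_that("synthesis form amidates in place of a terminal glycine", {
  p <- synthesisForm("AAKG")
  expect_equal(peptideSequence(p), "AAK")
  expect_equal(p@cTerm, "amide")
  q <- synthesisForm("GTLLKGLAGGAAAGLGAALLYKAFKKKN")
  expect_equal(peptideSequence(q), "GTLLKGLAGGAAAGLGAALLYKAFKKKN")
  expect_equal(q@cTerm, "free")
})
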