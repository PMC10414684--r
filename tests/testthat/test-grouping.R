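test_that("exclusion filter removes library matches and logs best hits", {
  lib <- c(cecropin = "SWLSKTAKKLENSAKKRISEGIAIAIQGGPR")
  peptides <- data.frame(
    peptide_id = c("hit", "miss"),
    sequence = c(unname(lib), "GGGGGGGGGGSSSSSSSSTT"),
    stringsAsFactors = FALSE)
  out <- exclusionFilter(peptides, lib)
  expect_equal(out$peptide_id, "miss")
  removed <- attr(out, "removed")
  expect_equal(removed$peptide_id, "hit")
  expect_equal(removed$best_hit, "cecropin")
  expect_gte(removed$bits, 50)
  # empty library is the identity
  out2 <- exclusionFilter(peptides, character())
  expect_equal(out2$peptide_id, peptides$peptide_id)
})

test_that("planted known-AMP copies are all removed by the exclusion screen", {
  b <- defaultFixture()
  known <- b$truth[b$truth$family_type == "known", ]
  others <- b$truth[b$truth$family_type == "amp", ]
  peptides <- data.frame(
    peptide_id = c(known$protein_id, others$protein_id),
    sequence = c(known$mature_sequence, others$mature_sequence),
    stringsAsFactors = FALSE)
  lib <- as.character(Biostrings::readAAStringSet(b$paths$exclusion))
  out <- exclusionFilter(peptides, lib)
  expect_equal(nrow(attr(out, "removed")), nrow(known))
  expect_true(all(known$protein_id %in% attr(out, "removed")$peptide_id))
  expect_true(all(others$protein_id %in% out$peptide_id))
})

.pepframe <- function(seqs, genomes) data.frame(
  peptide_id = names(seqs), genome_id = genomes,
  precursor_sequence = unname(seqs), stringsAsFactors = FALSE)

test_that("identical sequences from different genomes form one group", {
  s <- strrep("KLAGSDTE", 8)  # 64-mer, self-score comfortably over 248
  g <- buildGroups(.pepframe(c(a = s, b = s), c("g1", "g2")))
  expect_equal(nGroups(g), 1L)
  expect_equal(groupTable(g)$n_members, 2L)
  expect_equal(groupTable(g)$n_genomes, 2L)
})

test_that("singleton and single-genome components are discarded", {
  s <- strrep("KLAGSDTE", 8)
  other <- strrep("WNPYHQMC", 8)
  # singleton: unrelated second sequence
  g1 <- buildGroups(.pepframe(c(a = s, b = other), c("g1", "g2")))
  expect_equal(nGroups(g1), 0L)
  # both members from the same genome
  g2 <- buildGroups(.pepframe(c(a = s, b = s), c("g1", "g1")))
  expect_equal(nGroups(g2), 0L)
  # keepAll retains both kinds
  g3 <- buildGroups(.pepframe(c(a = s, b = s, c = other),
                              c("g1", "g1", "g2")), keepAll = TRUE)
  expect_equal(nGroups(g3), 2L)
})

test_that("components equal union-find over the thresholded edge matrix", {
  b <- defaultFixture()
  truth <- b$truth[b$truth$family_type %in% c("amp", "decoy_go"), ]
  prot <- fixtureProteome()
  seqs <- stats::setNames(as.character(prot)[truth$protein_id],
                          truth$protein_id)
  pep <- .pepframe(seqs, truth$genome_id)
  gs <- buildGroups(pep, keepAll = TRUE)
  # oracle: brute-force pairwise scores + union-find
  n <- length(seqs)
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bits <- bitScore(smithWaterman(seqs[i], seqs[j]))
    if (bits >= 100) edges <- rbind(edges, c(i, j))
  }
  comp <- unionFindComponents(n, edges)
  mem <- groupMembership(gs)
  got <- mem$group_id[match(names(seqs), mem$peptide_id)]
  # same partition: component labels must be a bijection
  expect_equal(length(unique(comp)), nGroups(gs))
  expect_true(all(tapply(got, comp, function(v) length(unique(v)) == 1L)))
  expect_true(all(tapply(comp, got, function(v) length(unique(v)) == 1L)))
})

test_that("planted families are recovered exactly at 5% mutation", {
  b <- defaultFixture()
  truth <- b$truth[b$truth$family_type == "amp", ]
  prot <- fixtureProteome()
  pep <- .pepframe(stats::setNames(as.character(prot)[truth$protein_id],
                                   truth$protein_id), truth$genome_id)
  gs <- buildGroups(pep)
  mem <- groupMembership(gs)
  fams <- unique(truth$family_id)
  recovered <- vapply(fams, function(f) {
    ids <- truth$protein_id[truth$family_id == f]
    gid <- unique(mem$group_id[mem$peptide_id %in% ids])
    length(gid) == 1L &&
      setequal(mem$peptide_id[mem$group_id == gid], ids)
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("grouping is invariant to input order with deterministic ids", {
  b <- defaultFixture()
  truth <- b$truth[b$truth$family_type == "amp", ]
  prot <- fixtureProteome()
  pep <- .pepframe(stats::setNames(as.character(prot)[truth$protein_id],
                                   truth$protein_id), truth$genome_id)
  g1 <- buildGroups(pep)
  g2 <- buildGroups(pep[rev(seq_len(nrow(pep))), ])
  expect_equal(groupTable(g1)[c("group_id", "n_members", "n_genomes")],
               groupTable(g2)[c("group_id", "n_members", "n_genomes")])
  expect_equal(groupMembership(g1), groupMembership(g2))
})

test_that("consensus is the column mode and ties break alphabetically", {
  cr <- consensusAndRepresentative(c(a = "AAKK", b = "AAKR", c = "AAKK"))
  expect_equal(cr$consensus, "AAKK")
  expect_equal(cr$representative, "a")  # identical top scorers: smallest id
  # identical members: consensus is the shared sequence
  cr2 <- consensusAndRepresentative(c(x = "KLAGSDTE", y = "KLAGSDTE"))
  expect_equal(cr2$consensus, "KLAGSDTE")
  expect_equal(cr2$representative, "x")
})

test_that("column modes denoise mutations back to the planted ancestor", {
  b <- defaultFixture()
  truth <- b$truth[b$truth$family_type == "amp", ]
  fams <- unique(truth$family_id)
  hamming <- function(a, b) {
    if (nchar(a) != nchar(b)) return(NA_integer_)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  exact <- vapply(fams, function(f) {
    rows <- truth[truth$family_id == f, ]
    cr <- consensusAndRepresentative(
      stats::setNames(rows$mature_sequence, rows$protein_id))
    # i.i.d. substitutions rarely coincide, so the per-column mode over
    # the copies recovers the planted ancestral mature peptide
    d <- hamming(cr$consensus, rows$ancestor_mature[1])
    !is.na(d) && d <= 1
  }, logical(1))
  expect_gte(mean(exact), 0.9)
})

test_that("the representative is the member closest to the consensus", {
  b <- defaultFixture()
  truth <- b$truth[b$truth$family_type == "amp", ]
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (f in unique(truth$family_id)) {
    rows <- truth[truth$family_id == f, ]
    seqs <- stats::setNames(rows$mature_sequence, rows$protein_id)
    cr <- consensusAndRepresentative(seqs)
    # gapless same-length copies: percent identity reduces to Hamming
    d <- vapply(seqs, hamming, integer(1), b = cr$consensus)
    expect_equal(unname(d[cr$representative]), min(d), label = f)
  }
})
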