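# Shared fixture bundle, generated once per test run (seed fixed so every
# run sees identical data).

.fixture_cache <- new.env(parent = emptyenv())

defaultFixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "helminthamp-fixture")
    .fixture_cache$bundle <- generateFixtures(fixtureSpec(seed = 17), dir)
    .fixture_cache$dir <- dir
  }
  .fixture_cache$bundle
}

fixtureProteome <- function() {
  b <- defaultFixture()
  gnames <- grep("^genome_", names(b$paths), value = TRUE)
  do.call(combineProteomes, lapply(gnames, function(g)
    readProteome(b$paths[[g]], genomeId = g)))
}

# hand-built SequelogGroupSet for curation-stage tests
.mkGroups <- function(members) {
  mem <- do.call(rbind, lapply(seq_along(members), function(i)
    data.frame(group_id = i, peptide_id = members[[i]],
               genome_id = paste0("g", seq_along(members[[i]])),
               stringsAsFactors = FALSE)))
  grp <- data.frame(group_id = seq_along(members),
                    n_members = lengths(members),
                    n_genomes = lengths(members),
                    representative = NA_character_,
                    consensus = NA_character_)
  new("SequelogGroupSet", groups = grp, membership = mem, minBits = 100)
}

# small AAStringSet constructor with genome provenance
aaset <- function(seqs, genome = "g1") {
  x <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    genome_id = rep(genome, length.out = length(x)),
    species = NA_character_)
  x
}
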