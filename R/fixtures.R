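# Seeded synthetic-proteome generator with ground truth, so the whole
# pipeline runs and is testable without any external downloads or tools.
#
# Each planted precursor follows the prepropeptide architecture the
# pipeline expects: Met + short n-region, an 8-residue hydrophobic
# h-region (heuristically detectable), a polar c-region ending the signal
# peptide at position 16, a neutral pro-region closed by a dibasic KR, the
# planted mature peptide closed by a second KR, and an acidic tail.
# Random substitutions never touch the h-region or the dibasic motifs, so
# the truth table stays valid after mutation.

.NEUTRAL_AA <- c("S", "T", "N", "Q", "G", "A", "D", "E", "P")
.HREGION_AA <- c("L", "V", "I", "F", "A")
.AMP_TEMPLATE <- strrep("KLAKLAK", 12L)

#' Specification for a synthetic fixture bundle
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 8 planted AMP families and 6 decoy families, each copied into 4
#' pseudo-genomes with 5\% per-residue substitution, plus 3 copies of a
#' known AMP for the exclusion screen.
#'
#' @param seed Integer RNG seed (reproducibility contract: same seed, same
#'   bundle, byte for byte).
#' @param nGenomes Number of pseudo-genomes (default 4).
#' @param nFamilies Planted AMP families (default 8).
#' @param copiesPerFamily Genomes each family appears in (default
#'   \code{nGenomes}; one copy per genome).
#' @param mutationRate Per-residue substitution probability (default 0.05).
#' @param nDecoys Decoy (non-AMP) families (default 6). Half are GO
#'   decoys: AMP-like sequences carrying a blocklisted GO term, which the
#'   GO curation stage must remove; the other half are neutral sequences
#'   the ensemble itself should reject.
#' @param plantedKnownAmps Copies of the known-AMP sequence planted for
#'   the exclusion filter (default 3).
#' @param nDuplicates Extra exact-duplicate proteins planted per bundle
#'   (default 0).
#' @param nInvalid Extra proteins containing X or * planted (default 0).
#' @param toolNoise Per-tool label-flip probability for the synthetic
#'   predictor call tables (default 0.08).
#' @return Validated list of class \code{"fixtureSpec"}.
#' @examples fixtureSpec(seed = 17)
#' @export
fixtureSpec <- function(seed, nGenomes = 4L, nFamilies = 8L,
                        copiesPerFamily = nGenomes, mutationRate = 0.05,
                        nDecoys = 6L, plantedKnownAmps = 3L,
                        nDuplicates = 0L, nInvalid = 0L, toolNoise = 0.08) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            nGenomes >= 1L, nFamilies >= 0L,
            copiesPerFamily >= 1L, copiesPerFamily <= nGenomes,
            mutationRate >= 0, mutationRate <= 1,
            nDecoys >= 0L, plantedKnownAmps >= 0L,
            toolNoise >= 0, toolNoise <= 1)
  structure(list(seed = as.integer(seed), nGenomes = as.integer(nGenomes),
                 nFamilies = as.integer(nFamilies),
                 copiesPerFamily = as.integer(copiesPerFamily),
                 mutationRate = mutationRate, nDecoys = as.integer(nDecoys),
                 plantedKnownAmps = as.integer(plantedKnownAmps),
                 nDuplicates = as.integer(nDuplicates),
                 nInvalid = as.integer(nInvalid), toolNoise = toolNoise),
            class = "fixtureSpec")
}

# the known AMP planted for the exclusion screen (porcine cecropin P1)
.KNOWN_AMP <- c(cecropin_P1 = "SWLSKTAKKLENSAKKRISEGIAIAIQGGPR")

.sampleSeq <- function(n, alphabet) paste(sample(alphabet, n, TRUE),
                                          collapse = "")

# ancestor prepropeptide for one family; returns sequence + truth coords
.makeAncestor <- function(type) {
  nreg <- .sampleSeq(2L, c("S", "N", "T"))
  hreg <- .sampleSeq(8L, .HREGION_AA)
  creg <- .sampleSeq(5L, c("S", "N", "A", "G", "T"))
  signal <- paste0("M", nreg, hreg, creg)          # 16 aa, signal_end 16
  spacer <- .sampleSeq(sample(12:20, 1L), .NEUTRAL_AA)
  core_len <- sample(25:40, 1L)
  core <- switch(type,
    decoy_go = ,
    amp = {
      off <- sample(0:6, 1L)
      s <- substr(.AMP_TEMPLATE, off + 1L, off + core_len)
      # family-specific divergence from the template (conservative)
      r <- .splitResidues(s)
      sub <- which(stats::runif(core_len) < 0.10)
      r[sub] <- vapply(r[sub], function(ch)
        if (ch == "K") sample(c("K", "R"), 1L)
        else sample(.HREGION_AA, 1L), character(1))
      paste(r, collapse = "")
    },
    known = substr(unname(.KNOWN_AMP), 1L, nchar(unname(.KNOWN_AMP))),
    decoy = .sampleSeq(core_len, .NEUTRAL_AA))
  tail <- .sampleSeq(sample(8:15, 1L), c("D", "E", "S", "G", "N", "Q", "A"))
  seq <- paste0(signal, spacer, "KR", core, "KR", tail)
  site1 <- 16L + nchar(spacer) + 2L
  site2 <- site1 + nchar(core) + 2L
  list(sequence = seq, signal_end = 16L, site1 = site1, site2 = site2,
       mature_start = site1 + 1L, mature_end = site2,
       frozen = c(4:11, site1 - 1L, site1, site2 - 1L, site2))
}

.mutateSeq <- function(sequence, rate, frozen) {
  r <- .splitResidues(sequence)
  idx <- setdiff(which(stats::runif(length(r)) < rate), frozen)
  r[idx] <- vapply(r[idx], function(ch)
    sample(setdiff(.AA20, ch), 1L), character(1))
  paste(r, collapse = "")
}

#' Generate a synthetic fixture bundle
#'
#' Writes per-genome proteome FASTAs, the known-AMP exclusion library,
#' ground-truth tables (precursor coordinates and family membership, GO
#' annotations with blocklisted terms on half the decoy families, TPM
#' values with expression for AMP families only) and an 11-tool predictor
#' call table derived from the built-in reference rules plus seeded label
#' noise. Fully reproducible from the spec seed.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written \code{paths} and the
#'   in-memory \code{truth} table, \code{go}, \code{tpm} and
#'   \code{tool_calls} data.frames.
#' @examples
#' b <- generateFixtures(fixtureSpec(seed = 1, nFamilies = 2, nDecoys = 1,
#'                                   plantedKnownAmps = 0), tempdir())
#' nrow(b$truth)
#' @export
generateFixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister")

  # half the decoy families are "GO decoys": AMP-like sequences carrying a
  # blocklisted GO term (the protease-inhibitor style false positive the
  # GO curation stage exists to remove); the rest are neutral sequences
  # that the ensemble itself should reject.
  n_go_decoys <- ceiling(spec$nDecoys / 2)
  fam_types <- c(rep("amp", spec$nFamilies),
                 rep("decoy_go", n_go_decoys),
                 rep("decoy", spec$nDecoys - n_go_decoys))
  fam_ids <- c(sprintf("ampfam%02d", seq_len(spec$nFamilies)),
               sprintf("decoyfam%02d", seq_len(spec$nDecoys)))
  rows <- list(); seqs_by_genome <- vector("list", spec$nGenomes)
  names(seqs_by_genome) <- sprintf("genome_%d", seq_len(spec$nGenomes))
  addProtein <- function(genome, pid, sequence) {
    seqs_by_genome[[genome]][[pid]] <<- sequence
  }
  for (f in seq_along(fam_ids)) {
    anc <- .makeAncestor(fam_types[f])
    genomes <- ((f - 1L + seq_len(spec$copiesPerFamily) - 1L) %%
                  spec$nGenomes) + 1L
    for (g in genomes) {
      gname <- names(seqs_by_genome)[g]
      pid <- sprintf("%s_%s", fam_ids[f], gname)
      s <- .mutateSeq(anc$sequence, spec$mutationRate, anc$frozen)
      addProtein(gname, pid, s)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, genome_id = gname, family_id = fam_ids[f],
        family_type = fam_types[f], signal_end = anc$signal_end,
        site1 = anc$site1, site2 = anc$site2,
        mature_start = anc$mature_start, mature_end = anc$mature_end,
        mature_sequence = substr(s, anc$mature_start, anc$mature_end),
        ancestor_mature = substr(anc$sequence, anc$mature_start,
                                 anc$mature_end),
        stringsAsFactors = FALSE)
    }
  }
  # planted copies of the known AMP (removed later by the exclusion screen)
  for (k in seq_len(spec$plantedKnownAmps)) {
    anc <- .makeAncestor("known")
    g <- ((k - 1L) %% spec$nGenomes) + 1L
    gname <- names(seqs_by_genome)[g]
    pid <- sprintf("knownamp%02d_%s", k, gname)
    addProtein(gname, pid, anc$sequence)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, genome_id = gname,
      family_id = sprintf("knownamp%02d", k), family_type = "known",
      signal_end = anc$signal_end, site1 = anc$site1, site2 = anc$site2,
      mature_start = anc$mature_start, mature_end = anc$mature_end,
      mature_sequence = substr(anc$sequence, anc$mature_start,
                               anc$mature_end),
      ancestor_mature = substr(anc$sequence, anc$mature_start,
                               anc$mature_end),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  # optional planted duplicates / invalid proteins (filter-stage fodder)
  extra <- character(0)
  if (spec$nDuplicates > 0L) {
    src <- truth[sample.int(nrow(truth), spec$nDuplicates, TRUE), ]
    for (i in seq_len(nrow(src))) {
      g <- src$genome_id[i]
      pid <- sprintf("dup%02d_%s", i, g)
      addProtein(g, pid, seqs_by_genome[[g]][[src$protein_id[i]]])
      extra <- c(extra, pid)
    }
  }
  if (spec$nInvalid > 0L) for (i in seq_len(spec$nInvalid)) {
    g <- names(seqs_by_genome)[((i - 1L) %% spec$nGenomes) + 1L]
    pid <- sprintf("invalid%02d_%s", i, g)
    addProtein(g, pid, paste0(.sampleSeq(30L, .AA20), "X",
                              .sampleSeq(20L, .AA20)))
    extra <- c(extra, pid)
  }

  paths <- list()
  for (g in names(seqs_by_genome)) {
    p <- file.path(dir, paste0(g, ".fasta"))
    writeFasta(unlist(seqs_by_genome[[g]]), p)
    paths[[g]] <- p
  }
  paths$exclusion <- file.path(dir, "known_amps.fasta")
  writeFasta(.KNOWN_AMP, paths$exclusion)

  # GO truth: blocklisted terms on half the decoy families, a benign term
  # on some AMP families, the rest unannotated
  bl <- defaultGoBlocklist()
  go_rows <- list()
  blocked <- fam_ids[fam_types == "decoy_go"]
  for (i in seq_len(nrow(truth))) {
    fid <- truth$family_id[i]
    if (fid %in% blocked)
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        gene_id = truth$protein_id[i], namespace = "biological_process",
        go_id = bl[(match(fid, blocked) - 1L) %% length(bl) + 1L])
    else if (truth$family_type[i] == "amp" &&
             match(fid, fam_ids) %% 2L == 0L)
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        gene_id = truth$protein_id[i], namespace = "biological_process",
        go_id = "GO:0050830")  # defense response to Gram-positive bacterium
  }
  go <- if (length(go_rows)) do.call(rbind, go_rows) else
    data.frame(gene_id = character(), namespace = character(),
               go_id = character())
  paths$go <- file.path(dir, "go_annotations.tsv")
  utils::write.table(go, paths$go, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # TPM truth: AMP families expressed in at least one life stage
  tpm <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    expressed <- truth$family_type[i] == "amp"
    data.frame(gene_id = truth$protein_id[i],
               sample = c("L3", "adult"),
               tpm = round(if (expressed) c(stats::runif(1, 0, 1.5),
                                            stats::runif(1, 5, 50))
                           else stats::runif(2, 0, 1.5), 3))
  }))
  paths$tpm <- file.path(dir, "tpm.tsv")
  utils::write.table(tpm, paths$tpm, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # synthetic 11-tool call table over the excised candidate peptides
  proteomes <- lapply(names(seqs_by_genome), function(g)
    readProteome(paths[[g]], genomeId = g))
  prot <- do.call(combineProteomes, proteomes)
  prot <- filterPrecursors(prot)$proteins
  ann <- heuristicAnnotations(prot)
  cand <- lengthGate(enumeratePeptides(prot, ann))
  base <- consensusProfile(referencePredictors(
    stats::setNames(cand$sequence, cand$peptide_id)))
  base_pos <- base$n_positive >= 2L
  tools <- c("camp_svm", "camp_rf", "camp_ann", "camp_da", "adam_svm",
             "adam_hmm", "dbaasp", "iamp2l", "iamppred", "aps", "ampep")
  tc <- do.call(rbind, lapply(tools, function(tl) {
    flip <- stats::runif(nrow(base)) < spec$toolNoise
    data.frame(peptide_id = base$peptide_id, tool_name = tl,
               call = xor(base_pos, flip), stringsAsFactors = FALSE)
  }))
  paths$tool_calls <- file.path(dir, "tool_calls.tsv")
  utils::write.table(tc, paths$tool_calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths$truth <- file.path(dir, "truth_precursors.tsv")
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(paths = paths, truth = truth, go = go, tpm = tpm,
                 tool_calls = tc, extra_ids = extra))
}
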