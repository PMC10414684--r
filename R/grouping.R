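# Sequelog grouping: threshold graph over pairwise bit scores, connected
# components, and the known-AMP exclusion screen that precedes it.

#' Remove peptides matching a known-AMP library
#'
#' Screens each candidate's grouping sequence against a library of
#' previously characterised AMPs; any candidate whose best local-alignment
#' bit score against the library reaches \code{minBits} is removed so that
#' only novel candidates continue through the pipeline. Removals are
#' reported via the \code{"removed"} attribute (peptide id and best hit).
#'
#' @param peptides data.frame with columns \code{peptide_id} and a sequence
#'   column named by \code{seqColumn}.
#' @param library Named character vector or \code{AAStringSet} of known
#'   AMPs; an empty library removes nothing.
#' @param minBits Bit-score threshold for exclusion (default 50).
#' @param params From \code{\link{alignmentParams}}.
#' @param seqColumn Column holding the sequence to screen
#'   (default \code{"sequence"}).
#' @return Filtered data.frame; attribute \code{"removed"} is a data.frame
#'   with \code{peptide_id}, \code{best_hit}, \code{bits}.
#' @export
exclusionFilter <- function(peptides, library, minBits = 50,
                            params = alignmentParams(),
                            seqColumn = "sequence") {
  if (!is.character(library)) library <- as.character(library)
  removed <- data.frame(peptide_id = character(), best_hit = character(),
                        bits = numeric())
  if (length(library) && nrow(peptides)) {
    best <- rep(-Inf, nrow(peptides))
    hit <- rep(NA_character_, nrow(peptides))
    for (nm in seq_along(library)) {
      bits <- bitScore(.localScores(peptides[[seqColumn]], library[nm],
                                    params), params)
      better <- bits > best
      best[better] <- bits[better]
      hit[better] <- if (!is.null(names(library))) names(library)[nm]
                     else as.character(nm)
    }
    drop <- best >= minBits
    removed <- data.frame(peptide_id = peptides$peptide_id[drop],
                          best_hit = hit[drop], bits = best[drop])
    peptides <- peptides[!drop, , drop = FALSE]
    rownames(peptides) <- NULL
  }
  attr(peptides, "removed") <- removed
  peptides
}

# Pairwise bit-score matrix (symmetric, diagonal NA) for a set of sequences.
.pairwiseBits <- function(seqs, params) {
  n <- length(seqs)
  bits <- matrix(NA_real_, n, n)
  if (n >= 2L) for (j in 2:n) {
    raw <- .localScores(seqs[seq_len(j - 1L)], seqs[j], params)
    b <- bitScore(raw, params)
    bits[seq_len(j - 1L), j] <- b
    bits[j, seq_len(j - 1L)] <- b
  }
  bits
}

#' Group AMP-like peptides into sequelog groups
#'
#' Builds an undirected graph with an edge wherever the pairwise
#' local-alignment bit score reaches \code{minBits} (self-hits excluded)
#' and takes connected components as sequelog groups. Components of size
#' one (no sequelog) and components whose members all originate from a
#' single genome assembly are discarded. Group ids are assigned
#' deterministically: descending size, ties broken by the
#' lexicographically smallest member id, so grouping is invariant to input
#' order.
#'
#' Grouping operates on the \code{groupingColumn} sequence — by default the
#' full precursor, since short mature peptides cannot reach 100 bits under
#' the default constants (a raw score of 248 exceeds the maximal self-score
#' of peptides shorter than about 45 residues); a mature-peptide mode with
#' a lower user-chosen threshold is available via
#' \code{groupingColumn = "sequence"}.
#'
#' @param peptides data.frame with \code{peptide_id}, \code{genome_id} and
#'   the grouping sequence column.
#' @param params From \code{\link{alignmentParams}}.
#' @param minBits Edge threshold in bits (default 100).
#' @param groupingColumn Column holding the grouping sequence (default
#'   \code{"precursor_sequence"}).
#' @param keepAll Keep singleton and single-genome components
#'   (default FALSE).
#' @return A \linkS4class{SequelogGroupSet}.
#' @export
buildGroups <- function(peptides, params = alignmentParams(),
                        minBits = 100, groupingColumn = "precursor_sequence",
                        keepAll = FALSE) {
  stopifnot(nrow(peptides) >= 1L,
            all(c("peptide_id", "genome_id", groupingColumn) %in%
                  names(peptides)))
  seqs <- peptides[[groupingColumn]]
  n <- length(seqs)
  # peptides sharing a grouping sequence (e.g. one precursor) need a
  # single alignment row: compute pairwise bits on unique sequences, with
  # self-scores on the diagonal so identical sequences connect
  useq <- unique(seqs)
  umap <- match(seqs, useq)
  ubits <- .pairwiseBits(useq, params)
  diag(ubits) <- vapply(useq, function(s)
    bitScore(.localScores(s, s, params), params), numeric(1))
  adj <- ubits[umap, umap, drop = FALSE] >= minBits
  diag(adj) <- FALSE  # self-hits excluded
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep_comp <- as.integer(names(which(
    tapply(seq_len(n), comp, function(ix) {
      keepAll || (length(ix) >= 2L &&
                    length(unique(peptides$genome_id[ix])) >= 2L)
    }))))
  kept <- which(comp %in% keep_comp)
  if (!length(kept))
    return(new("SequelogGroupSet",
               groups = data.frame(group_id = integer(),
                                   n_members = integer(),
                                   n_genomes = integer(),
                                   representative = character(),
                                   consensus = character()),
               membership = data.frame(group_id = integer(),
                                       peptide_id = character(),
                                       genome_id = character()),
               minBits = minBits))
  comps <- split(kept, comp[kept])
  size <- lengths(comps)
  minid <- vapply(comps, function(ix) min(peptides$peptide_id[ix]),
                  character(1))
  ord <- order(-size, minid)
  comps <- comps[ord]
  membership <- do.call(rbind, lapply(seq_along(comps), function(gi) {
    ix <- comps[[gi]][order(peptides$peptide_id[comps[[gi]]])]
    data.frame(group_id = gi, peptide_id = peptides$peptide_id[ix],
               genome_id = peptides$genome_id[ix], stringsAsFactors = FALSE)
  }))
  groups <- data.frame(
    group_id = seq_along(comps),
    n_members = as.integer(lengths(comps)),
    n_genomes = vapply(comps, function(ix)
      length(unique(peptides$genome_id[ix])), integer(1)),
    representative = NA_character_,
    consensus = NA_character_,
    row.names = NULL)
  new("SequelogGroupSet", groups = groups, membership = membership,
      minBits = minBits)
}

# Center-star multiple alignment: globally align every member to the center
# and merge on the center's coordinates (insertions relative to the center
# are padded across members).
.centerStarAlignment <- function(seqs, params) {
  n <- length(seqs)
  if (n == 1L) return(matrix(.splitResidues(seqs), nrow = 1L))
  total <- vapply(seq_len(n), function(i)
    sum(bitScore(.localScores(seqs[-i], seqs[i], params), params)),
    numeric(1))
  center <- which.max(total)
  aligned_c <- vector("list", n)
  aligned_m <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == center) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[center]),
      type = "global", substitutionMatrix = params$submat,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    aligned_m[[i]] <- .splitResidues(as.character(
      Biostrings::alignedPattern(pa)))
    aligned_c[[i]] <- .splitResidues(as.character(
      Biostrings::alignedSubject(pa)))
  }
  # column map: for every pairwise alignment, count insertions before each
  # center position; the master alignment allows the max insertion run
  Lc <- nchar(seqs[center])
  ins_before <- matrix(0L, n, Lc + 1L)  # insertions before center pos k
  for (i in seq_len(n)) {
    if (i == center) next
    cpos <- 0L; run <- 0L
    for (ch in aligned_c[[i]]) {
      if (ch == "-") run <- run + 1L
      else {
        cpos <- cpos + 1L
        ins_before[i, cpos] <- run
        run <- 0L
      }
    }
    ins_before[i, Lc + 1L] <- run
  }
  max_ins <- apply(ins_before, 2L, max)
  width <- Lc + sum(max_ins)
  msa <- matrix("-", n, width)
  # lay out the center row
  col_of_cpos <- integer(Lc)
  col <- 0L
  for (k in seq_len(Lc)) {
    col <- col + max_ins[k] + 1L
    col_of_cpos[k] <- col
  }
  msa[center, col_of_cpos] <- .splitResidues(seqs[center])
  for (i in seq_len(n)) {
    if (i == center) next
    cpos <- 0L; buf <- character()
    put <- function(chars, k) {
      # place run of member chars right-aligned before center pos k
      if (!length(chars)) return()
      start_col <- if (k <= Lc) col_of_cpos[k] - length(chars) else
        width - length(chars) + 1L
      msa[i, seq.int(start_col, length.out = length(chars))] <<- chars
    }
    for (t in seq_along(aligned_c[[i]])) {
      cc <- aligned_c[[i]][t]; mc <- aligned_m[[i]][t]
      if (cc == "-") { if (mc != "-") buf <- c(buf, mc) }
      else {
        cpos <- cpos + 1L
        put(buf, cpos); buf <- character()
        if (mc != "-") msa[i, col_of_cpos[cpos]] <- mc
      }
    }
    put(buf, Lc + 1L)
  }
  msa
}

#' Consensus sequence and representative member of a group
#'
#' Builds a center-star multiple alignment of the member sequences (center
#' = member maximising its summed pairwise bit score to the others). The
#' consensus takes the modal residue of each column (ties broken
#' alphabetically) and drops gap-majority columns, i.e. the consensus is
#' reported with gaps removed. The representative is the member with the
#' highest percent identity to the consensus; ties are broken by greater
#' length, then by lexicographically smallest id.
#'
#' @param memberSequences Named character vector (names = peptide ids).
#' @param params From \code{\link{alignmentParams}}.
#' @return list with \code{consensus} (character) and
#'   \code{representative} (peptide id).
#' @examples
#' consensusAndRepresentative(c(a = "AAKK", b = "AAKR", c = "AAKK"))
#' @export
consensusAndRepresentative <- function(memberSequences,
                                       params = alignmentParams()) {
  stopifnot(length(memberSequences) >= 2L, !is.null(names(memberSequences)))
  msa <- .centerStarAlignment(unname(memberSequences), params)
  cons_cols <- character()
  for (j in seq_len(ncol(msa))) {
    col <- msa[, j]
    if (sum(col == "-") > length(col) / 2) next  # gap-majority column
    res <- col[col != "-"]
    tab <- table(res)
    top <- names(tab)[tab == max(tab)]
    cons_cols <- c(cons_cols, sort(top)[1])
  }
  consensus <- paste(cons_cols, collapse = "")
  pid <- vapply(memberSequences, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(consensus),
      type = "global", substitutionMatrix = params$submat,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    Biostrings::pid(pa)
  }, numeric(1))
  len <- nchar(memberSequences)
  ids <- names(memberSequences)
  ord <- order(-pid, -len, ids)
  list(consensus = consensus, representative = ids[ord[1]])
}

#' Annotate groups with consensus and representative
#'
#' Runs \code{\link{consensusAndRepresentative}} on every group of a
#' \linkS4class{SequelogGroupSet}.
#'
#' @param groupSet A \linkS4class{SequelogGroupSet}.
#' @param sequences Named character vector mapping peptide_id to the
#'   sequence used for the consensus (typically the mature peptide).
#' @param params From \code{\link{alignmentParams}}.
#' @return The \linkS4class{SequelogGroupSet} with \code{representative}
#'   and \code{consensus} filled in.
#' @export
annotateGroups <- function(groupSet, sequences, params = alignmentParams()) {
  grp <- groupTable(groupSet)
  mem <- groupMembership(groupSet)
  for (i in seq_len(nrow(grp))) {
    ids <- mem$peptide_id[mem$group_id == grp$group_id[i]]
    cr <- consensusAndRepresentative(
      stats::setNames(sequences[ids], ids), params)
    grp$consensus[i] <- cr$consensus
    grp$representative[i] <- cr$representative
  }
  methods::initialize(groupSet, groups = grp)
}
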