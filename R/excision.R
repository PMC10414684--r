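#' Heuristic signal-peptide end position
#'
#' A deterministic hydropathy heuristic standing in for a neural-network
#' signal-peptide predictor so that fixtures run self-contained: the first
#' window of \code{window} residues starting within \code{searchRange}
#' whose mean Kyte-Doolittle hydropathy reaches \code{minKd} marks the
#' hydrophobic h-region; the predicted signal end is the window end plus a
#' fixed 5-residue c-region offset, capped at position 35. This is a
#' labelled heuristic, not a reproduction of any external predictor; real
#' annotations take precedence when supplied.
#'
#' @param sequence Amino-acid sequence.
#' @param window h-region window width (default 8).
#' @param minKd Mean hydropathy threshold (default 1.6).
#' @param searchRange Window start positions searched (default c(3, 30)).
#' @return Integer position of the last signal-peptide residue, or
#'   \code{NA_integer_} if no window qualifies or the sequence is shorter
#'   than the search range upper bound.
#' @examples
#' heuristicSignalEnd(paste0("M", strrep("L", 10), strrep("A", 30)))
#' heuristicSignalEnd(paste0("M", strrep("D", 40)))
#' @export
heuristicSignalEnd <- function(sequence, window = 8L, minKd = 1.6,
                               searchRange = c(3L, 30L)) {
  n <- nchar(sequence)
  if (n < searchRange[2]) return(NA_integer_)
  kd <- unname(.KD[.splitResidues(sequence)])
  kd[is.na(kd)] <- 0  # X and friends count as neutral
  starts <- seq.int(searchRange[1], min(searchRange[2], n - window + 1L))
  cs <- c(0, cumsum(kd))
  for (p in starts) {
    if ((cs[p + window] - cs[p]) / window >= minKd)
      return(min(p + window - 1L + 5L, 35L, n))
  }
  NA_integer_
}

#' Dibasic propeptide cleavage sites
#'
#' Deterministic stand-in for a pro-protein convertase site predictor:
#' reports the position of the second residue of every dibasic motif
#' occurrence (cleavage happens after the pair). Overlapping motifs are all
#' reported.
#'
#' @param sequence Amino-acid sequence.
#' @param motifs Character vector of 2-residue motifs
#'   (default KR, RR, KK, RK).
#' @return Sorted integer positions.
#' @examples
#' dibasicSites("AAKRAA")  # 4
#' dibasicSites("AKRRA")   # 3 4
#' @export
dibasicSites <- function(sequence, motifs = c("KR", "RR", "KK", "RK")) {
  res <- .splitResidues(sequence)
  if (length(res) < 2L) return(integer())
  pair <- paste0(res[-length(res)], res[-1L])
  sort(which(pair %in% motifs) + 1L)
}

#' Annotate precursors with the built-in cleavage heuristics
#'
#' Convenience wrapper running \code{\link{heuristicSignalEnd}} and
#' \code{\link{dibasicSites}} over a proteome; proteins without a heuristic
#' signal peptide are omitted (as with a negative predictor call).
#'
#' @param proteins \code{AAStringSet}.
#' @param ... Passed to \code{\link{heuristicSignalEnd}}.
#' @return Cleavage annotation data.frame (see
#'   \code{\link{readCleavageTsv}}).
#' @export
heuristicAnnotations <- function(proteins, ...) {
  seqs <- as.character(proteins)
  se <- vapply(seqs, heuristicSignalEnd, integer(1), ..., USE.NAMES = FALSE)
  keep <- !is.na(se)
  ann <- data.frame(protein_id = names(proteins)[keep],
                    signal_end = se[keep], stringsAsFactors = FALSE)
  kept_seqs <- seqs[keep]
  # sites within the signal peptide are void
  ann$propeptide_sites <- lapply(seq_len(nrow(ann)), function(i) {
    p <- dibasicSites(kept_seqs[i])
    p[p > ann$signal_end[i]]
  })
  .validateAnnotations(ann, proteins)
}

#' Enumerate candidate mature peptides from cleavage boundaries
#'
#' For each annotated precursor the boundary list is
#' \code{B = sort(unique(c(signal_end, propeptide_sites, length)))}. In the
#' default \code{"all_pairs"} mode one candidate is emitted per ordered
#' boundary pair \code{(b_i, b_j), i < j}, spanning residues
#' \code{b_i + 1 .. b_j} — every potential peptide is kept when multiple
#' cleavage sites are predicted, giving \code{m(m-1)/2} candidates for
#' \code{m} boundaries. \code{"segments"} mode emits only consecutive
#' pairs (a subset of all_pairs). Precursors missing from the annotation
#' table are skipped with a message.
#'
#' @param proteins \code{AAStringSet} with mcols \code{genome_id}.
#' @param annotations Cleavage annotation data.frame.
#' @param mode \code{"all_pairs"} (default) or \code{"segments"}.
#' @return data.frame of candidates: \code{peptide_id}, \code{protein_id},
#'   \code{genome_id}, \code{start}, \code{end}, \code{length},
#'   \code{sequence}, \code{boundary_from}, \code{boundary_to}.
#' @examples
#' x <- Biostrings::AAStringSet(c(p1 = strrep("A", 80)))
#' S4Vectors::mcols(x) <- S4Vectors::DataFrame(genome_id = "g1")
#' ann <- data.frame(protein_id = "p1", signal_end = 20L)
#' ann$propeptide_sites <- list(c(35L, 50L))
#' nrow(enumeratePeptides(x, ann))  # choose(4, 2) = 6
#' @export
enumeratePeptides <- function(proteins, annotations,
                              mode = c("all_pairs", "segments")) {
  mode <- match.arg(mode)
  gid <- S4Vectors::mcols(proteins)$genome_id
  seqs <- as.character(proteins)
  idx <- match(annotations$protein_id, names(proteins))
  missing <- is.na(idx)
  if (any(missing))
    message(sum(missing), " annotated protein(s) absent from proteome; skipped")
  rows <- vector("list", sum(!missing))
  k <- 0L
  for (i in which(!missing)) {
    pid <- annotations$protein_id[i]
    j <- idx[i]
    L <- nchar(seqs[j])
    B <- sort(unique(c(annotations$signal_end[i],
                       annotations$propeptide_sites[[i]], L)))
    m <- length(B)
    if (m < 2L) next
    pairs <- if (mode == "all_pairs") t(utils::combn(m, 2L))
             else cbind(seq_len(m - 1L), 2:m)
    st <- B[pairs[, 1L]] + 1L
    en <- B[pairs[, 2L]]
    k <- k + 1L
    rows[[k]] <- data.frame(
      protein_id = pid, genome_id = gid[j],
      start = st, end = en, length = en - st + 1L,
      sequence = substring(seqs[j], st, en),
      boundary_from = ifelse(B[pairs[, 1L]] == annotations$signal_end[i],
                             "signal_end", "propeptide_site"),
      boundary_to = ifelse(B[pairs[, 2L]] == L, "C-terminus",
                           "propeptide_site"),
      stringsAsFactors = FALSE)
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(protein_id = character(), genome_id = character(),
               start = integer(), end = integer(), length = integer(),
               sequence = character(), boundary_from = character(),
               boundary_to = character())
  if (nrow(out))
    out <- cbind(peptide_id = paste0(out$protein_id, ":", out$start, "-",
                                     out$end), out)
  else out <- cbind(peptide_id = character(), out)
  rownames(out) <- NULL
  out
}

#' Gate candidate peptides by length
#'
#' Retains candidates of 10 to 99 residues inclusive (the working range of
#' the AMP predictor ensemble): shorter than \code{minLen} or at/above
#' \code{maxLen + 1} are removed.
#'
#' @param peptides Candidate data.frame from \code{\link{enumeratePeptides}}.
#' @param minLen Minimum retained length (default 10).
#' @param maxLen Maximum retained length (default 99).
#' @return Filtered data.frame with attribute \code{"n_removed"}.
#' @export
lengthGate <- function(peptides, minLen = 10L, maxLen = 99L) {
  keep <- peptides$length >= minLen & peptides$length <= maxLen
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Synthesis form of a candidate peptide
#'
#' Peptides ending in glycine are synthesised with C-terminal amidation in
#' place of the glycine (the glycine is the biological amide donor); the
#' returned \linkS4class{ModifiedPeptide} drops the terminal G and carries
#' \code{cTerm = "amide"}. Other peptides are returned unchanged with free
#' termini.
#'
#' @param sequence Peptide sequence.
#' @return A \linkS4class{ModifiedPeptide}.
#' @examples
#' synthesisForm("AAKG")  # "AAK", amidated
#' @export
synthesisForm <- function(sequence) {
  sequence <- toupper(sequence)
  if (endsWith(sequence, "G"))
    ModifiedPeptide(substr(sequence, 1L, nchar(sequence) - 1L),
                    cTerm = "amide")
  else ModifiedPeptide(sequence)
}
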