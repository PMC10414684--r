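#' Remove exact duplicate sequences
#'
#' Removes exact-sequence duplicates, keeping the first occurrence in input
#' order. By default deduplication is scoped within each genome (duplicates
#' are common between assemblies of related species and are retained across
#' genomes); \code{scope = "global"} removes them across the whole set.
#'
#' @param proteins \code{AAStringSet} with mcols \code{genome_id}.
#' @param scope \code{"genome"} (default) or \code{"global"}.
#' @return Filtered \code{AAStringSet}; attribute \code{"n_removed"} holds
#'   the removal count.
#' @examples
#' x <- Biostrings::AAStringSet(c(a = "MKL", b = "MKL", c = "MKA"))
#' S4Vectors::mcols(x) <- S4Vectors::DataFrame(genome_id = rep("g1", 3))
#' deduplicate(x)
#' @export
deduplicate <- function(proteins, scope = c("genome", "global")) {
  scope <- match.arg(scope)
  seqs <- as.character(proteins)
  key <- if (scope == "genome")
    paste0(S4Vectors::mcols(proteins)$genome_id, "\r", seqs) else seqs
  keep <- !duplicated(key)
  out <- proteins[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove proteins with unknown residues or stop codons
#'
#' Drops any sequence containing \code{X} (unknown amino acid) or \code{*}
#' (stop codon).
#'
#' @param proteins \code{AAStringSet}.
#' @return Filtered \code{AAStringSet} with attribute \code{"n_removed"}.
#' @examples
#' x <- Biostrings::AAStringSet(c(a = "MKXL", b = "MKL"))
#' removeInvalid(x)
#' @export
removeInvalid <- function(proteins) {
  keep <- !grepl("[X*]", as.character(proteins), fixed = FALSE)
  out <- proteins[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove proteins longer than a maximum length
#'
#' Proteins strictly longer than \code{maxLen} residues are removed; a
#' protein of exactly \code{maxLen} residues is retained. The default of
#' 150 aa reflects the length range of known AMP precursors.
#'
#' @param proteins \code{AAStringSet}.
#' @param maxLen Maximum retained length (default 150).
#' @return Filtered \code{AAStringSet} with attribute \code{"n_removed"}.
#' @examples
#' x <- Biostrings::AAStringSet(c(a = strrep("A", 150), b = strrep("A", 151)))
#' lengthFilter(x)
#' @export
lengthFilter <- function(proteins, maxLen = 150L) {
  stopifnot(maxLen > 0)
  keep <- Biostrings::width(proteins) <= maxLen
  out <- proteins[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the precursor-level filter cascade
#'
#' Applies, in order: per-genome deduplication, removal of sequences with
#' unknown residues or stop codons, and the precursor length filter. Each
#' stage's input/removed/output counts are reported so a run can be laid
#' beside the pipeline's published accounting.
#'
#' @param proteins \code{AAStringSet} with mcols \code{genome_id}.
#' @param maxLen Length cutoff passed to \code{\link{lengthFilter}}.
#' @param dedupScope Passed to \code{\link{deduplicate}}.
#' @return list with \code{proteins} (survivors) and \code{report}
#'   (data.frame: stage, n_in, n_removed, n_out).
#' @examples
#' x <- Biostrings::AAStringSet(c(a = "MKL", b = "MKL", c = "MKX"))
#' S4Vectors::mcols(x) <- S4Vectors::DataFrame(genome_id = rep("g1", 3))
#' filterPrecursors(x)$report
#' @export
filterPrecursors <- function(proteins, maxLen = 150L,
                             dedupScope = c("genome", "global")) {
  stages <- list(
    deduplicate = function(p) deduplicate(p, scope = dedupScope),
    remove_invalid = removeInvalid,
    length_filter = function(p) lengthFilter(p, maxLen = maxLen))
  report <- data.frame(stage = character(), n_in = integer(),
                       n_removed = integer(), n_out = integer())
  cur <- proteins
  for (nm in names(stages)) {
    n_in <- length(cur)
    cur <- stages[[nm]](cur)
    report <- rbind(report, data.frame(
      stage = nm, n_in = n_in, n_removed = n_in - length(cur),
      n_out = length(cur)))
  }
  list(proteins = cur, report = report)
}
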