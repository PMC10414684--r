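# Curation stages applied to sequelog groups after grouping: GO blocklist,
# group length, cysteine-class triage, expression evidence.

#' Default GO blocklist
#'
#' GO Biological Process / Molecular Function accessions regarded as
#' established non-antimicrobial functions (signalling, protease
#' inhibition, hormone activity and similar); groups carrying them are
#' removed to reduce likely false positives.
#'
#' @return Character vector of GO accessions.
#' @examples defaultGoBlocklist()
#' @export
defaultGoBlocklist <- function() {
  c("GO:0007165",  # signal transduction
    "GO:0010951",  # negative regulation of endopeptidase activity
    "GO:0007218",  # neuropeptide signalling pathway
    "GO:0006644",  # phospholipid metabolic process
    "GO:0050482",  # arachidonic acid secretion
    "GO:0006508",  # proteolysis
    "GO:0004867",  # serine-type endopeptidase inhibitor activity
    "GO:0005179",  # hormone activity
    "GO:0004623",  # phospholipase A2 activity
    "GO:0008233")  # peptidase activity
}

#' Read a GO blocklist configuration file
#'
#' YAML file with a top-level \code{blocklist} sequence of GO accessions.
#'
#' @param path YAML path.
#' @return Character vector of accessions.
#' @export
readGoBlocklist <- function(path) {
  cfg <- yaml::read_yaml(path)
  bl <- unlist(cfg$blocklist)
  .checkGoIds(bl)
  bl
}

.checkGoIds <- function(ids) {
  bad <- !grepl("^GO:\\d{7}$", ids)
  if (any(bad))
    stop("malformed GO accession in blocklist: ", ids[bad][1], call. = FALSE)
  invisible(ids)
}

#' Remove groups carrying blocklisted GO terms
#'
#' A group is removed when a member's gene carries a blocklisted
#' BP/MF term (\code{mode = "any"}, the conservative default) or when all
#' annotated members do (\code{mode = "all"}). Groups whose members have no
#' GO annotations at all are retained.
#'
#' @param groupSet A \linkS4class{SequelogGroupSet}.
#' @param annotations data.frame with columns \code{gene_id},
#'   \code{go_id} (and optionally \code{namespace}).
#' @param geneOf Named character vector mapping peptide_id to gene_id
#'   (default: peptide ids are gene ids).
#' @param blocklist GO accessions (default
#'   \code{\link{defaultGoBlocklist}}).
#' @param mode \code{"any"} or \code{"all"}.
#' @return Filtered \linkS4class{SequelogGroupSet} with attribute
#'   \code{"removed_groups"}.
#' @export
goFilter <- function(groupSet, annotations, geneOf = NULL,
                     blocklist = defaultGoBlocklist(),
                     mode = c("any", "all")) {
  mode <- match.arg(mode)
  .checkGoIds(blocklist)
  mem <- groupMembership(groupSet)
  genes <- if (is.null(geneOf)) mem$peptide_id else
    unname(geneOf[mem$peptide_id])
  hit_gene <- unique(annotations$gene_id[annotations$go_id %in% blocklist])
  annotated_gene <- unique(annotations$gene_id)
  member_hit <- genes %in% hit_gene
  member_annotated <- genes %in% annotated_gene
  drop <- vapply(split(seq_len(nrow(mem)), mem$group_id), function(ix) {
    if (mode == "any") any(member_hit[ix])
    else any(member_annotated[ix]) &&
      all(member_hit[ix][member_annotated[ix]])
  }, logical(1))
  .subsetGroups(groupSet, !drop[as.character(groupTable(groupSet)$group_id)])
}

.subsetGroups <- function(groupSet, keep) {
  grp <- groupTable(groupSet)
  removed <- grp$group_id[!keep]
  grp2 <- grp[keep, , drop = FALSE]
  mem2 <- groupMembership(groupSet)
  mem2 <- mem2[mem2$group_id %in% grp2$group_id, , drop = FALSE]
  rownames(grp2) <- rownames(mem2) <- NULL
  out <- methods::initialize(groupSet, groups = grp2, membership = mem2)
  attr(out, "removed_groups") <- removed
  out
}

#' Remove groups dominated by long peptides
#'
#' A group is removed iff strictly more than half of its member peptides
#' are longer than \code{cutoff} residues; at exactly 50\% the group is
#' retained. Most characterised AMPs are under 60 residues, motivating the
#' default.
#'
#' @param groupSet A \linkS4class{SequelogGroupSet}.
#' @param lengths Named integer vector mapping peptide_id to peptide
#'   length.
#' @param cutoff Length above which a member counts as long (default 60).
#' @return Filtered \linkS4class{SequelogGroupSet} with attribute
#'   \code{"removed_groups"}.
#' @export
groupLengthFilter <- function(groupSet, lengths, cutoff = 60L) {
  mem <- groupMembership(groupSet)
  long <- unname(lengths[mem$peptide_id]) > cutoff
  drop <- vapply(split(long, mem$group_id),
                 function(v) mean(v) > 0.5, logical(1))
  .subsetGroups(groupSet, !drop[as.character(groupTable(groupSet)$group_id)])
}

#' Cysteine structural class of a peptide
#'
#' \code{"linear"} for at most one cysteine, \code{"two_cysteine"} for
#' exactly two (a single putative disulfide), \code{"cysteine_rich"} for
#' more than two. Linear peptides are the synthesis-friendly cohort; the
#' exactly-two class is kept separate because it is neither.
#'
#' @param sequence Peptide sequence(s).
#' @return Character vector of class labels.
#' @examples
#' cysteineClass(c("ACKKAC", "AKKA", "ACCACCA"))
#' @export
cysteineClass <- function(sequence) {
  nC <- vapply(strsplit(toupper(sequence), "", fixed = TRUE),
               function(r) sum(r == "C"), integer(1))
  ifelse(nC <= 1L, "linear", ifelse(nC == 2L, "two_cysteine",
                                    "cysteine_rich"))
}

#' Expression evidence flag from a TPM table
#'
#' A gene is flagged expressed when its TPM exceeds the cutoff (strictly)
#' in at least one sample or life stage. Genes absent from the table yield
#' \code{NA} ("unknown"), not \code{FALSE}.
#'
#' @param geneIds Gene identifiers to look up.
#' @param tpmTable data.frame with columns \code{gene_id}, \code{tpm}
#'   (one row per gene x sample).
#' @param cutoff Strict TPM threshold (default 2).
#' @return Logical vector (with NA for unknown genes), named by gene id.
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g1", "g2"), tpm = c(0.5, 2.1, 2.0))
#' expressionFlag(c("g1", "g2", "g3"), tab)
#' @export
expressionFlag <- function(geneIds, tpmTable, cutoff = 2) {
  stopifnot(all(c("gene_id", "tpm") %in% names(tpmTable)),
            all(tpmTable$tpm >= 0))
  expressed <- tapply(tpmTable$tpm, tpmTable$gene_id,
                      function(v) any(v > cutoff))
  out <- as.logical(expressed[geneIds])
  names(out) <- geneIds
  out
}
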