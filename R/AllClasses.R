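#' ModifiedPeptide: a peptide sequence plus its modification state
#'
#' Container for the peptide forms used in mass, charge and fragment
#' computations: an amino-acid sequence together with its N-terminal state
#' (free or pyroglutamate), C-terminal state (free or amide) and any
#' residue-level modifications (methionine oxidation, tyrosine sulfation).
#'
#' @slot sequence Amino-acid sequence (uppercase, 20-letter alphabet).
#' @slot nTerm Either \code{"free"} or \code{"pyro_glu"}; pyroglutamate is
#'   only valid when the first residue is Q or E.
#' @slot cTerm Either \code{"free"} or \code{"amide"}.
#' @slot residueMods Named character vector mapping 1-based positions
#'   (names) to modification labels (\code{"oxidation"} or
#'   \code{"sulfation"}).
#'
#' @examples
#' p <- ModifiedPeptide("QELAEDFSPDKRGMSS", nTerm = "pyro_glu")
#' monoisotopicMass(p)
#' @export
setClass("ModifiedPeptide",
  representation(sequence = "character",
                 nTerm = "character",
                 cTerm = "character",
                 residueMods = "character"))

setValidity("ModifiedPeptide", function(object) {
  msgs <- character()
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msgs <- c(msgs, "sequence must be a single non-empty string")
  else {
    res <- .splitResidues(object@sequence)
    if (any(!res %in% .AA20))
      msgs <- c(msgs, "sequence contains non-standard residues")
    if (object@nTerm == "pyro_glu" && !res[1] %in% c("Q", "E"))
      msgs <- c(msgs, "pyro_glu requires the first residue to be Q or E")
    if (length(object@residueMods)) {
      pos <- suppressWarnings(as.integer(names(object@residueMods)))
      if (anyNA(pos) || any(pos < 1L) || any(pos > length(res)))
        msgs <- c(msgs, "residueMods positions outside sequence")
      if (any(!object@residueMods %in% c("oxidation", "sulfation")))
        msgs <- c(msgs, "residueMods values must be 'oxidation' or 'sulfation'")
    }
  }
  if (!object@nTerm %in% c("free", "pyro_glu"))
    msgs <- c(msgs, "nTerm must be 'free' or 'pyro_glu'")
  if (!object@cTerm %in% c("free", "amide"))
    msgs <- c(msgs, "cTerm must be 'free' or 'amide'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModifiedPeptide
#'
#' @param sequence Amino-acid sequence (coerced to uppercase).
#' @param nTerm \code{"free"} (default) or \code{"pyro_glu"}.
#' @param cTerm \code{"free"} (default) or \code{"amide"}.
#' @param residueMods Named character vector of modifications keyed by
#'   1-based position, e.g. \code{c("10" = "oxidation")}.
#' @return A \linkS4class{ModifiedPeptide}.
#' @examples
#' ModifiedPeptide("GTLVMSSQFMLQ", residueMods = c("10" = "oxidation"))
#' @export
ModifiedPeptide <- function(sequence, nTerm = "free", cTerm = "free",
                            residueMods = character()) {
  new("ModifiedPeptide", sequence = toupper(sequence), nTerm = nTerm,
      cTerm = cTerm, residueMods = residueMods)
}

#' @describeIn ModifiedPeptide display a short summary
#' @param object A ModifiedPeptide.
#' @export
setMethod("show", "ModifiedPeptide", function(object) {
  mods <- character()
  if (object@nTerm != "free") mods <- c(mods, object@nTerm)
  if (object@cTerm != "free") mods <- c(mods, object@cTerm)
  if (length(object@residueMods))
    mods <- c(mods, paste0(object@residueMods, "@", names(object@residueMods)))
  cat("ModifiedPeptide (", nchar(object@sequence), " aa",
      if (length(mods)) paste0("; ", paste(mods, collapse = ", ")), ")\n",
      "  ", object@sequence, "\n", sep = "")
})

#' @rdname peptideSequence
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' Accessor for the amino-acid sequence of a ModifiedPeptide
#'
#' @param x A \linkS4class{ModifiedPeptide}.
#' @return A character scalar.
#' @examples peptideSequence(ModifiedPeptide("AAKK"))
#' @rdname peptideSequence
#' @export
setMethod("peptideSequence", "ModifiedPeptide", function(x) x@sequence)

#' SequelogGroupSet: sequelog groups of AMP-like peptides
#'
#' Result container for bit-score threshold grouping: each group is a
#' connected component of the sequelog graph (an edge joins two peptides
#' whose pairwise local-alignment bit score reaches the threshold).
#'
#' @slot groups data.frame with one row per group: \code{group_id},
#'   \code{n_members}, \code{n_genomes}, \code{representative},
#'   \code{consensus} (the last two may be NA until
#'   \code{\link{annotateGroups}} is run).
#' @slot membership data.frame with one row per member peptide:
#'   \code{group_id}, \code{peptide_id}, \code{genome_id}.
#' @slot minBits Bit-score threshold used to build the graph.
#'
#' @export
setClass("SequelogGroupSet",
  representation(groups = "data.frame",
                 membership = "data.frame",
                 minBits = "numeric"))

setValidity("SequelogGroupSet", function(object) {
  msgs <- character()
  need_g <- c("group_id", "n_members", "n_genomes")
  if (!all(need_g %in% names(object@groups)))
    msgs <- c(msgs, "groups must have group_id, n_members, n_genomes")
  need_m <- c("group_id", "peptide_id", "genome_id")
  if (!all(need_m %in% names(object@membership)))
    msgs <- c(msgs, "membership must have group_id, peptide_id, genome_id")
  if (!length(msgs)) {
    if (anyDuplicated(object@membership$peptide_id))
      msgs <- c(msgs, "a peptide cannot belong to two groups")
    if (!all(object@membership$group_id %in% object@groups$group_id))
      msgs <- c(msgs, "membership refers to unknown group_id")
    tab <- table(object@membership$group_id)
    sizes <- as.integer(tab[as.character(object@groups$group_id)])
    if (!identical(sizes, as.integer(object@groups$n_members)))
      msgs <- c(msgs, "n_members inconsistent with membership")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SequelogGroupSet display a summary
#' @param object A SequelogGroupSet.
#' @export
setMethod("show", "SequelogGroupSet", function(object) {
  cat("SequelogGroupSet with", nrow(object@groups), "group(s),",
      nrow(object@membership), "member peptide(s); min bits",
      object@minBits, "\n")
  if (nrow(object@groups)) {
    head_df <- utils::head(object@groups, 5L)
    print(head_df, row.names = FALSE)
    if (nrow(object@groups) > 5L) cat("  ...\n")
  }
})

#' @rdname sequelogAccessors
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
#' @rdname sequelogAccessors
#' @export
setGeneric("groupMembership", function(x) standardGeneric("groupMembership"))
#' @rdname sequelogAccessors
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' Accessors for SequelogGroupSet
#'
#' \code{groupTable} returns the per-group summary table,
#' \code{groupMembership} the peptide-to-group assignment, and
#' \code{nGroups} the number of groups.
#'
#' @param x A \linkS4class{SequelogGroupSet}.
#' @return A data.frame (or integer for \code{nGroups}).
#' @name sequelogAccessors
NULL

#' @rdname sequelogAccessors
#' @export
setMethod("groupTable", "SequelogGroupSet", function(x) x@groups)
#' @rdname sequelogAccessors
#' @export
setMethod("groupMembership", "SequelogGroupSet", function(x) x@membership)
#' @rdname sequelogAccessors
#' @export
setMethod("nGroups", "SequelogGroupSet", function(x) nrow(x@groups))
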