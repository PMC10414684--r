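#' AmpRunConfig: pipeline run configuration
#'
#' Holds every numeric threshold of the discovery pipeline in one place so
#' a run is fully described by a single serialisable object: precursor
#' length cutoff, peptide length gate, consensus fraction, sequelog
#' bit-score threshold, group length cutoff, TPM cutoff, exclusion
#' threshold, PSM tier cutoffs and the MIC activity bound.
#'
#' @slot maxPrecursorLen numeric. Precursor length cutoff (150).
#' @slot minPeptideLen numeric. Peptide gate lower bound (10).
#' @slot maxPeptideLen numeric. Peptide gate upper bound (99).
#' @slot consensusFraction numeric. Strict majority fraction (0.5).
#' @slot minBits numeric. Sequelog edge threshold in bits (100).
#' @slot exclusionBits numeric. Known-AMP exclusion threshold (50).
#' @slot groupLengthCutoff numeric. Member-length cutoff (60).
#' @slot tpmCutoff numeric. Expression threshold (2).
#' @slot psmCutoffs numeric. Named -10lgP tier cutoffs (47.4, 20, 13).
#' @slot micActiveBound numeric. MIC activity bound in ug/ml (100).
#' @slot seed numeric. RNG seed for any stochastic stage.
#' @export
setClass("AmpRunConfig",
  representation(maxPrecursorLen = "numeric", minPeptideLen = "numeric",
                 maxPeptideLen = "numeric", consensusFraction = "numeric",
                 minBits = "numeric", exclusionBits = "numeric",
                 groupLengthCutoff = "numeric", tpmCutoff = "numeric",
                 psmCutoffs = "numeric", micActiveBound = "numeric",
                 seed = "numeric"))

setValidity("AmpRunConfig", function(object) {
  msgs <- character()
  num_pos <- c(maxPrecursorLen = object@maxPrecursorLen,
               minPeptideLen = object@minPeptideLen,
               maxPeptideLen = object@maxPeptideLen,
               minBits = object@minBits,
               exclusionBits = object@exclusionBits,
               groupLengthCutoff = object@groupLengthCutoff,
               micActiveBound = object@micActiveBound)
  if (any(num_pos <= 0))
    msgs <- c(msgs, paste("must be positive:",
                          paste(names(num_pos)[num_pos <= 0],
                                collapse = ", ")))
  if (object@consensusFraction <= 0 || object@consensusFraction >= 1)
    msgs <- c(msgs, "consensusFraction must be in (0, 1)")
  if (object@tpmCutoff < 0) msgs <- c(msgs, "tpmCutoff must be >= 0")
  if (!all(c("high", "medium", "low") %in% names(object@psmCutoffs)))
    msgs <- c(msgs, "psmCutoffs needs high, medium, low")
  else if (is.unsorted(rev(object@psmCutoffs[c("high", "medium", "low")])))
    msgs <- c(msgs, "psmCutoffs must decrease high > medium > low")
  if (object@minPeptideLen > object@maxPeptideLen)
    msgs <- c(msgs, "minPeptideLen must not exceed maxPeptideLen")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AmpRunConfig
#'
#' @param maxPrecursorLen,minPeptideLen,maxPeptideLen,consensusFraction
#'   See \linkS4class{AmpRunConfig}.
#' @param minBits,exclusionBits,groupLengthCutoff,tpmCutoff,psmCutoffs
#'   See \linkS4class{AmpRunConfig}.
#' @param micActiveBound,seed See \linkS4class{AmpRunConfig}.
#' @return A validated \linkS4class{AmpRunConfig}.
#' @examples ampRunConfig(seed = 17)
#' @export
ampRunConfig <- function(maxPrecursorLen = 150, minPeptideLen = 10,
                         maxPeptideLen = 99, consensusFraction = 0.5,
                         minBits = 100, exclusionBits = 50,
                         groupLengthCutoff = 60, tpmCutoff = 2,
                         psmCutoffs = c(high = 47.4, medium = 20, low = 13),
                         micActiveBound = 100, seed = 1) {
  new("AmpRunConfig", maxPrecursorLen = maxPrecursorLen,
      minPeptideLen = minPeptideLen, maxPeptideLen = maxPeptideLen,
      consensusFraction = consensusFraction, minBits = minBits,
      exclusionBits = exclusionBits, groupLengthCutoff = groupLengthCutoff,
      tpmCutoff = tpmCutoff, psmCutoffs = psmCutoffs,
      micActiveBound = micActiveBound, seed = seed)
}

#' @describeIn AmpRunConfig display the configuration
#' @param object An AmpRunConfig.
#' @export
setMethod("show", "AmpRunConfig", function(object) {
  cat("AmpRunConfig\n",
      "  precursor length <= ", object@maxPrecursorLen, "\n",
      "  peptide gate [", object@minPeptideLen, ", ",
      object@maxPeptideLen, "]\n",
      "  consensus fraction > ", object@consensusFraction, "\n",
      "  sequelog bits >= ", object@minBits,
      " (exclusion >= ", object@exclusionBits, ")\n",
      "  group length cutoff ", object@groupLengthCutoff,
      ", TPM > ", object@tpmCutoff, "\n",
      "  PSM -10lgP cutoffs ",
      paste(object@psmCutoffs, collapse = "/"), "\n",
      "  MIC active < ", object@micActiveBound, " ug/ml; seed ",
      object@seed, "\n", sep = "")
})

#' Write / read a run configuration as YAML
#'
#' @param config An \linkS4class{AmpRunConfig}.
#' @param path YAML path.
#' @return \code{writeRunConfig} returns \code{path} invisibly;
#'   \code{readRunConfig} returns an \linkS4class{AmpRunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  sl <- methods::slotNames(config)
  vals <- lapply(sl, function(s) {
    v <- methods::slot(config, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  v <- yaml::read_yaml(path)
  ampRunConfig(maxPrecursorLen = v$maxPrecursorLen,
               minPeptideLen = v$minPeptideLen,
               maxPeptideLen = v$maxPeptideLen,
               consensusFraction = v$consensusFraction,
               minBits = v$minBits, exclusionBits = v$exclusionBits,
               groupLengthCutoff = v$groupLengthCutoff,
               tpmCutoff = v$tpmCutoff,
               psmCutoffs = unlist(v$psmCutoffs),
               micActiveBound = v$micActiveBound, seed = v$seed)
}

#' Run the integrated AMP discovery pipeline
#'
#' Executes the full cascade on in-memory inputs: precursor filters,
#' cleavage-based excision, peptide length gate, ensemble consensus,
#' known-AMP exclusion, sequelog grouping on precursor sequences,
#' GO-blocklist and group-length curation, and physicochemical
#' characterisation of the surviving peptides. Per-stage counts are
#' accumulated so a run log can be laid beside the published pipeline
#' figure; every stage's output remains in the returned list.
#'
#' @param proteins \code{AAStringSet} with mcols \code{genome_id}.
#' @param config An \linkS4class{AmpRunConfig}.
#' @param annotations Cleavage annotations; default: the built-in
#'   heuristics via \code{\link{heuristicAnnotations}}.
#' @param toolCalls Long predictor call data.frame; default: the built-in
#'   reference rules.
#' @param exclusionLibrary Named character vector of known AMPs (optional).
#' @param goAnnotations GO data.frame (optional; see \code{\link{goFilter}}).
#' @param goBlocklist GO accessions (default
#'   \code{\link{defaultGoBlocklist}}).
#' @param tpmTable TPM data.frame (optional; adds an expression flag).
#' @return list with \code{report} (stage counts), \code{candidates},
#'   \code{profiles}, \code{ampLps}, \code{groups}
#'   (a \linkS4class{SequelogGroupSet}), \code{prioritised} (data.frame of
#'   surviving peptides with descriptors and group ids).
#' @export
runPipeline <- function(proteins, config = ampRunConfig(),
                        annotations = NULL, toolCalls = NULL,
                        exclusionLibrary = NULL, goAnnotations = NULL,
                        goBlocklist = defaultGoBlocklist(),
                        tpmTable = NULL) {
  methods::validObject(config)
  log_row <- function(rep, stage, n_in, n_out)
    rbind(rep, data.frame(stage = stage, n_in = n_in,
                          n_removed = n_in - n_out, n_out = n_out))
  fp <- filterPrecursors(proteins, maxLen = config@maxPrecursorLen)
  report <- fp$report
  prot <- fp$proteins
  if (is.null(annotations)) annotations <- heuristicAnnotations(prot)
  n0 <- length(prot)
  cand <- enumeratePeptides(prot, annotations)
  report <- log_row(report, "excision_precursors", n0,
                    length(unique(cand$protein_id)))
  n0 <- nrow(cand)
  cand <- lengthGate(cand, config@minPeptideLen, config@maxPeptideLen)
  report <- log_row(report, "length_gate", n0, nrow(cand))
  if (is.null(toolCalls))
    toolCalls <- referencePredictors(
      stats::setNames(cand$sequence, cand$peptide_id))
  toolCalls <- toolCalls[toolCalls$peptide_id %in% cand$peptide_id, ,
                         drop = FALSE]
  profiles <- consensusProfile(toolCalls)
  amp <- merge(cand, profiles, by = "peptide_id", sort = FALSE)
  amp <- amp[amp$n_positive / amp$n_tools > config@consensusFraction, ,
             drop = FALSE]
  report <- log_row(report, "ensemble_consensus", nrow(cand), nrow(amp))
  prec_seq <- as.character(prot)
  amp$precursor_sequence <- unname(prec_seq[match(amp$protein_id,
                                                  names(prot))])
  if (!is.null(exclusionLibrary) && length(exclusionLibrary)) {
    n0 <- nrow(amp)
    amp <- exclusionFilter(amp, exclusionLibrary,
                           minBits = config@exclusionBits)
    report <- log_row(report, "known_amp_exclusion", n0, nrow(amp))
  }
  if (!nrow(amp))
    return(list(report = report, candidates = cand, profiles = profiles,
                ampLps = amp, groups = NULL,
                prioritised = data.frame()))
  groups <- buildGroups(amp, minBits = config@minBits)
  report <- log_row(report, "sequelog_grouping", nrow(amp),
                    nrow(groupMembership(groups)))
  if (!is.null(goAnnotations)) {
    n0 <- nGroups(groups)
    geneOf <- stats::setNames(amp$protein_id, amp$peptide_id)
    groups <- goFilter(groups, goAnnotations, geneOf = geneOf,
                       blocklist = goBlocklist)
    report <- log_row(report, "go_filter", n0, nGroups(groups))
  }
  n0 <- nGroups(groups)
  lens <- stats::setNames(amp$length, amp$peptide_id)
  groups <- groupLengthFilter(groups, lens,
                              cutoff = config@groupLengthCutoff)
  report <- log_row(report, "group_length_filter", n0, nGroups(groups))
  mem <- groupMembership(groups)
  pri <- amp[amp$peptide_id %in% mem$peptide_id, , drop = FALSE]
  pri$group_id <- mem$group_id[match(pri$peptide_id, mem$peptide_id)]
  pri$cysteine_class <- cysteineClass(pri$sequence)
  if (!is.null(tpmTable))
    pri$expressed <- unname(expressionFlag(pri$protein_id, tpmTable,
                                           cutoff = config@tpmCutoff))
  pri <- pri[order(pri$group_id, pri$peptide_id), , drop = FALSE]
  rownames(pri) <- NULL
  list(report = report, candidates = cand, profiles = profiles,
       ampLps = amp, groups = groups, prioritised = pri)
}
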