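#' Load per-tool AMP predictor call tables
#'
#' Each TSV must have columns \code{peptide_id}, \code{tool_name},
#' \code{call}; \code{call} is a boolean (TRUE/FALSE, 1/0) or a probability
#' thresholded at \code{threshold}. A peptide missing from a tool's table is
#' an abstention: in the default lenient mode that tool simply does not
#' count towards the peptide's denominator; in strict mode an incomplete
#' peptide-by-tool matrix is an error.
#'
#' @param paths Character vector of TSV paths (one or more tools per file).
#' @param threshold Probability cutoff for positive calls (default 0.5).
#' @param strict Error on missing peptide-tool combinations (default FALSE).
#' @return Long data.frame: \code{peptide_id}, \code{tool_name},
#'   \code{call} (logical).
#' @export
loadToolCalls <- function(paths, threshold = 0.5, strict = FALSE) {
  tabs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, colClasses = "character")
    need <- c("peptide_id", "tool_name", "call")
    if (!all(need %in% names(df)))
      stop("tool-call TSV must have columns ", paste(need, collapse = ", "),
           ": ", p, call. = FALSE)
    df[need]
  })
  calls <- do.call(rbind, tabs)
  if (anyDuplicated(calls[c("peptide_id", "tool_name")]))
    stop("duplicate peptide x tool rows in call tables", call. = FALSE)
  v <- calls$call
  logi <- toupper(v) %in% c("TRUE", "FALSE", "T", "F")
  num <- suppressWarnings(as.numeric(v))
  call_logical <- ifelse(logi, toupper(v) %in% c("TRUE", "T"),
                         num >= threshold)
  if (anyNA(call_logical))
    stop("unparseable call value: ", v[is.na(call_logical)][1], call. = FALSE)
  calls$call <- call_logical
  if (strict) {
    full <- length(unique(calls$peptide_id)) * length(unique(calls$tool_name))
    if (nrow(calls) < full)
      stop("strict mode: missing peptide x tool entries", call. = FALSE)
  }
  calls
}

#' Consensus AMP-like designation over an ensemble of predictors
#'
#' A peptide is designated an AMP-like peptide (AMP-LP) when strictly more
#' than half of the contributing prediction tools call it antimicrobial.
#' The overall score is the positive fraction as a nearest-integer
#' percentage (half-up), so with 11 tools the attainable scores form the
#' lattice \{0, 9, 18, 27, 36, 45, 55, 64, 73, 82, 91, 100\} and the lowest
#' AMP-LP score is 55\%.
#'
#' @param calls Long data.frame from \code{\link{loadToolCalls}} (columns
#'   \code{peptide_id}, \code{tool_name}, \code{call}).
#' @return data.frame: \code{peptide_id}, \code{n_tools},
#'   \code{n_positive}, \code{overall_pct}, \code{is_amp_lp}.
#' @examples
#' calls <- data.frame(peptide_id = "p", tool_name = paste0("t", 1:11),
#'                     call = rep(c(TRUE, FALSE), c(6, 5)))
#' consensusProfile(calls)  # 55%, AMP-LP
#' @export
consensusProfile <- function(calls) {
  stopifnot(all(c("peptide_id", "tool_name", "call") %in% names(calls)))
  if (!nrow(calls)) stop("no calls: consensus undefined", call. = FALSE)
  n_tools <- tapply(calls$call, calls$peptide_id, length)
  n_pos <- tapply(calls$call, calls$peptide_id, sum)
  ids <- names(n_tools)
  out <- data.frame(
    peptide_id = ids,
    n_tools = as.integer(n_tools),
    n_positive = as.integer(n_pos),
    overall_pct = as.integer(.roundHalfUp(100 * n_pos / n_tools)),
    is_amp_lp = as.vector(n_pos / n_tools > 0.5),
    stringsAsFactors = FALSE)
  out <- out[order(out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Eisenberg hydrophobic moment over an ideal alpha helix
#'
#' Mean-vector magnitude of Eisenberg consensus hydrophobicities placed on
#' an ideal helical wheel (100 degrees per residue).
#'
#' @param sequence Peptide sequence.
#' @return Numeric moment (per residue).
#' @examples hydrophobicMoment("KLAKLAKKLAKLAK")
#' @export
hydrophobicMoment <- function(sequence) {
  h <- unname(.EISENBERG[.checkStandardResidues(sequence)])
  n <- length(h)
  ang <- (seq_len(n) - 1L) * 100 * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / n
}

#' Built-in reference predictor rules
#'
#' Three deterministic physicochemical rules used as stand-ins for external
#' AMP predictors so fixtures and examples run self-contained (they are
#' documented heuristics, not reproductions of any published tool):
#' \itemize{
#'   \item \code{charge}: simple-count net charge >= +2;
#'   \item \code{hydrophobic}: hydrophobic residue fraction in [0.3, 0.6];
#'   \item \code{moment}: Eisenberg hydrophobic moment >= 0.2 on an ideal
#'     alpha helix.
#' }
#'
#' @param sequences Character vector of peptide sequences (length >= 10).
#' @param peptideIds Identifiers (default: names or seq_along).
#' @return Long call data.frame compatible with
#'   \code{\link{consensusProfile}}.
#' @examples
#' referencePredictors(c(polyK = strrep("K", 15)))
#' @export
referencePredictors <- function(sequences, peptideIds = NULL) {
  if (is.null(peptideIds))
    peptideIds <- if (!is.null(names(sequences))) names(sequences)
                  else as.character(seq_along(sequences))
  stopifnot(all(nchar(sequences) >= 10L))
  charge <- vapply(sequences, function(s)
    netCharge(ModifiedPeptide(s)) >= 2, logical(1))
  hfrac <- vapply(sequences, function(s)
    hydrophobicFraction(s) / 100, numeric(1))
  moment <- vapply(sequences, hydrophobicMoment, numeric(1))
  data.frame(
    peptide_id = rep(peptideIds, times = 3L),
    tool_name = rep(c("rule_charge", "rule_hydrophobic", "rule_moment"),
                    each = length(sequences)),
    call = c(unname(charge),
             hfrac >= 0.3 & hfrac <= 0.6,
             moment >= 0.2),
    stringsAsFactors = FALSE)
}
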