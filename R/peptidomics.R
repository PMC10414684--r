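# LC-MS/MS validation support: PSM confidence tiers, theoretical b/y
# ladders, consecutive-ion checks and precursor sequence coverage.

.TIER_LEVELS <- c("high", "medium", "low", "rejected")

#' PSM confidence tier from a -10lgP score
#'
#' Tier cutoffs follow the usual PEAKS confidence bands: \code{high} at or
#' above 47.4 (1\% FDR), \code{medium} in [20, 47.4) (P < 0.01),
#' \code{low} in [13, 20) (P < 0.05), \code{rejected} below 13. Scores
#' exactly at a boundary fall into the higher tier.
#'
#' @param score Numeric -10lgP score(s).
#' @param cutoffs Named numeric vector \code{c(high=, medium=, low=)}.
#' @return Character tier(s).
#' @examples
#' psmTier(c(55.71, 47.4, 20, 13, 12.9))
#' @export
psmTier <- function(score, cutoffs = c(high = 47.4, medium = 20, low = 13)) {
  stopifnot(is.finite(score), cutoffs[["high"]] >= cutoffs[["medium"]],
            cutoffs[["medium"]] >= cutoffs[["low"]])
  ifelse(score >= cutoffs[["high"]], "high",
         ifelse(score >= cutoffs[["medium"]], "medium",
                ifelse(score >= cutoffs[["low"]], "low", "rejected")))
}

# residue monoisotopic masses with modifications applied in place
.residueMassesMod <- function(p) {
  res <- .checkStandardResidues(peptideSequence(p))
  m <- unname(.MONO_MASS[res])
  if (length(p@residueMods)) {
    pos <- as.integer(names(p@residueMods))
    m[pos] <- m[pos] + unname(.MOD_DELTA[p@residueMods])
  }
  if (p@nTerm == "pyro_glu") m[1] <- m[1] + .MOD_DELTA[["pyro_glu"]]
  m
}

#' Theoretical b/y fragment ion ladder
#'
#' Singly protonated b- and y-ion m/z series for CID fragmentation:
#' \code{b_i} = sum of the first i residue masses + proton; \code{y_j} =
#' sum of the last j residue masses + water + proton. Terminal and residue
#' modifications are applied to the fragment that contains them (the
#' N-terminal pyroglutamate travels with the b series, a C-terminal amide
#' with the y series). For an n-residue peptide each series has n-1 ions,
#' and \code{b_i + y_(n-i)} equals the neutral mass plus two protons.
#'
#' @param p A \linkS4class{ModifiedPeptide} of length >= 2.
#' @param charge Fragment charge (default 1; higher charges divide).
#' @return list with numeric vectors \code{b} and \code{y} (named b1..,
#'   y1..).
#' @examples
#' fragmentLadder(ModifiedPeptide("GG"))
#' @export
fragmentLadder <- function(p, charge = 1L) {
  m <- .residueMassesMod(p)
  n <- length(m)
  stopifnot(n >= 2L, charge >= 1L)
  amide <- if (p@cTerm == "amide") .MOD_DELTA[["amide"]] else 0
  b <- cumsum(m)[-n] + .MASS_PROTON
  y <- cumsum(rev(m))[-n] + .MASS_WATER_MONO + .MASS_PROTON + amide
  if (charge > 1L) {
    b <- (b + (charge - 1L) * .MASS_PROTON) / charge
    y <- (y + (charge - 1L) * .MASS_PROTON) / charge
  }
  list(b = stats::setNames(b, paste0("b", seq_len(n - 1L))),
       y = stats::setNames(y, paste0("y", seq_len(n - 1L))))
}

#' Check for k consecutive matched b- or y-ions
#'
#' TRUE iff the matched-ion set contains \code{k} consecutive indices all
#' within the b series or all within the y series — the manual-validation
#' rule applied to positive identifications.
#'
#' @param matchedIons Character vector of ion labels like \code{"b2"},
#'   \code{"y7"}.
#' @param k Required run length (default 3).
#' @return Logical scalar.
#' @examples
#' consecutiveIonCheck(c("b2", "b3", "b4"))        # TRUE
#' consecutiveIonCheck(c("b2", "b4", "y1", "y3"))  # FALSE
#' @export
consecutiveIonCheck <- function(matchedIons, k = 3L) {
  if (!length(matchedIons)) return(FALSE)
  ok <- grepl("^[by]\\d+$", matchedIons)
  if (any(!ok))
    stop("malformed ion label: ", matchedIons[!ok][1], call. = FALSE)
  hasRun <- function(idx) {
    if (length(idx) < k) return(FALSE)
    idx <- sort(unique(idx))
    runs <- rle(diff(idx) == 1L)
    any(runs$values & runs$lengths >= k - 1L)
  }
  series <- substr(matchedIons, 1L, 1L)
  idx <- as.integer(sub("^[by]", "", matchedIons))
  hasRun(idx[series == "b"]) || hasRun(idx[series == "y"])
}

#' Precursor sequence coverage from PSMs
#'
#' Percentage of the prepropeptide covered by the union of PSM intervals
#' at or above a confidence tier (overlaps are never double-counted),
#' rounded half-up to the nearest integer. Coverage can only grow as the
#' tier requirement is relaxed.
#'
#' @param precursorLength Prepropeptide length in residues.
#' @param psms data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive) and \code{tier} (or \code{score}, tiered on the fly).
#' @param minTier Loosest accepted tier: \code{"high"}, \code{"medium"} or
#'   \code{"low"}.
#' @return Integer percentage.
#' @examples
#' psms <- data.frame(start = 61, end = 68, tier = "high")
#' sequenceCoverage(27 + 41, psms, "high")
#' @export
sequenceCoverage <- function(precursorLength, psms,
                             minTier = c("high", "medium", "low")) {
  minTier <- match.arg(minTier)
  if (!nrow(psms)) return(0L)
  if (is.null(psms$tier)) psms$tier <- psmTier(psms$score)
  stopifnot(all(psms$start >= 1L), all(psms$end <= precursorLength),
            all(psms$start <= psms$end))
  accept <- match(psms$tier, .TIER_LEVELS) <= match(minTier, .TIER_LEVELS)
  psms <- psms[accept, , drop = FALSE]
  if (!nrow(psms)) return(0L)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(psms$start, psms$end))))
  as.integer(.roundHalfUp(100 * covered / precursorLength))
}

#' Read a PSM table
#'
#' TSV with columns \code{precursor_id}, \code{sequence}, \code{start},
#' \code{end}, \code{score} and optionally \code{mods} (";"-separated
#' \code{pos:mod} entries, \code{nterm:pyro_glu}, \code{cterm:amide}) and
#' \code{matched_ions} (";"-separated labels). Tier is derived from the
#' score; PSM length must equal \code{end - start + 1}.
#'
#' @param path TSV path.
#' @return data.frame with a \code{tier} column and list-column
#'   \code{matched_ions}.
#' @export
readPsmTable <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("precursor_id", "sequence", "start", "end", "score")
  if (!all(need %in% names(df)))
    stop("PSM TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$score <- as.numeric(df$score)
  bad <- df$end - df$start + 1L != nchar(df$sequence)
  if (any(bad))
    stop("PSM length inconsistent with coordinates for ",
         df$precursor_id[bad][1], call. = FALSE)
  df$tier <- psmTier(df$score)
  df$matched_ions <- if (is.null(df$matched_ions))
    replicate(nrow(df), character(), simplify = FALSE)
  else lapply(strsplit(df$matched_ions, ";"),
              function(v) v[nzchar(v)])
  df
}
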