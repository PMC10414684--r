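.massDeltasMono <- function(p) {
  d <- 0
  if (p@nTerm == "pyro_glu") d <- d + .MOD_DELTA[["pyro_glu"]]
  if (p@cTerm == "amide") d <- d + .MOD_DELTA[["amide"]]
  if (length(p@residueMods))
    d <- d + sum(.MOD_DELTA[p@residueMods])
  d
}

#' Neutral monoisotopic mass of a modified peptide
#'
#' Sum of monoisotopic residue masses plus one water, with modification
#' deltas: pyroglutamate -17.026549, oxidation +15.994915, sulfation
#' +79.956815, C-terminal amide -0.984016 Da. Reported to 4 decimals.
#'
#' @param p A \linkS4class{ModifiedPeptide}.
#' @return Mass in Da, rounded to 4 decimals.
#' @examples
#' monoisotopicMass(ModifiedPeptide("YGGVYSKT"))  # 873.4232
#' @export
monoisotopicMass <- function(p) {
  res <- .checkStandardResidues(peptideSequence(p))
  m <- sum(.MONO_MASS[res]) + .MASS_WATER_MONO + .massDeltasMono(p)
  round(m, 4)
}

#' Average (molecular-weight) mass of a modified peptide
#'
#' Sum of average residue masses plus water (18.015); the C-terminal amide
#' subtracts 0.985. Used for concentration unit conversion, where the
#' molecular weight (not the monoisotopic mass) is the relevant quantity.
#'
#' @param p A \linkS4class{ModifiedPeptide}.
#' @return Mass in Da.
#' @examples
#' averageMass(ModifiedPeptide("GG"))  # ~132.12
#' @export
averageMass <- function(p) {
  res <- .checkStandardResidues(peptideSequence(p))
  m <- sum(.AVG_MASS[res]) + .MASS_WATER_AVG
  if (p@cTerm == "amide") m <- m + .MOD_DELTA_AVG_AMIDE
  if (p@nTerm == "pyro_glu") m <- m + .MOD_DELTA[["pyro_glu"]]
  if (length(p@residueMods)) m <- m + sum(.MOD_DELTA[p@residueMods])
  m
}

#' Convert an MIC from ug/ml to micromolar
#'
#' \code{round_half_up(1000 * mic_ug_ml / averageMass(p))}, matching the
#' integer micromolar values conventionally reported in brackets beside
#' MICs in ug/ml. Under the APD3 activity criterion a peptide counts as an
#' AMP when its MIC is below 100 ug/ml.
#'
#' @param micUgMl MIC in ug/ml (positive).
#' @param p The synthesised \linkS4class{ModifiedPeptide} form (amidation
#'   matters for the molecular weight).
#' @return Integer micromolar value.
#' @examples
#' p <- ModifiedPeptide("GFGKWVKKKWGSVRKGASKLVKGVKKVFPKKGIPIIRYERRF")
#' micToMicromolar(8, p)  # 2
#' @export
micToMicromolar <- function(micUgMl, p) {
  stopifnot(all(micUgMl > 0))
  as.integer(.roundHalfUp(1000 * micUgMl / averageMass(p)))
}

#' Net charge of a modified peptide
#'
#' The default \code{"simple"} model counts +1 per Lys/Arg, -1 per
#' Asp/Glu, +0.5 per His, +1 for a free N-terminus (0 when cyclised to
#' pyroglutamate) and -1 for a free C-terminus (0 when amidated). The
#' \code{"hh"} model instead sums Henderson-Hasselbalch fractional charges
#' at pH 7 with standard side-chain pKa values.
#'
#' @param p A \linkS4class{ModifiedPeptide}.
#' @param model \code{"simple"} (default) or \code{"hh"}.
#' @param pH pH for the \code{"hh"} model (default 7).
#' @return Signed (half-integer under \code{"simple"}) net charge.
#' @examples
#' netCharge(ModifiedPeptide("KKDD"))  # 0
#' @export
netCharge <- function(p, model = c("simple", "hh"), pH = 7) {
  model <- match.arg(model)
  res <- .checkStandardResidues(peptideSequence(p))
  if (model == "simple") {
    q <- sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")) +
      0.5 * sum(res == "H")
    if (p@nTerm == "free") q <- q + 1
    if (p@cTerm == "free") q <- q - 1
    q
  } else {
    pka_pos <- c(K = 10.5, R = 12.5, H = 6.0)
    pka_neg <- c(D = 3.9, E = 4.1, C = 8.3, Y = 10.1)
    q <- 0
    for (r in names(pka_pos))
      q <- q + sum(res == r) / (1 + 10^(pH - pka_pos[[r]]))
    for (r in names(pka_neg))
      q <- q - sum(res == r) / (1 + 10^(pka_neg[[r]] - pH))
    if (p@nTerm == "free") q <- q + 1 / (1 + 10^(pH - 9.0))
    if (p@cTerm == "free") q <- q - 1 / (1 + 10^(2.1 - pH))
    q
  }
}

#' Hydrophobic residue percentage
#'
#' Percentage of residues in the hydrophobic set
#' \{A, C, F, I, L, M, V, W\}, rounded half-up to the nearest integer.
#'
#' @param sequence Peptide sequence(s).
#' @return Integer percentage(s).
#' @examples
#' hydrophobicFraction(strrep("L", 10))  # 100
#' hydrophobicFraction(strrep("K", 10))  # 0
#' @export
hydrophobicFraction <- function(sequence) {
  vapply(strsplit(toupper(sequence), "", fixed = TRUE), function(r)
    as.integer(.roundHalfUp(100 * sum(r %in% .HYDROPHOBIC_SET) /
                              length(r))), integer(1))
}

#' Physicochemical summary of peptides
#'
#' Convenience wrapper computing length, cysteine class, net charge,
#' hydrophobic percentage, hydrophobic moment and masses for a set of
#' peptide sequences in their synthesis form (see
#' \code{\link{synthesisForm}}).
#'
#' @param sequences Character vector of peptide sequences.
#' @param ids Identifiers (default: names).
#' @return data.frame of descriptors, one row per peptide.
#' @export
characterizePeptides <- function(sequences, ids = names(sequences)) {
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  forms <- lapply(sequences, synthesisForm)
  data.frame(
    peptide_id = ids,
    sequence = unname(sequences),
    synthesis_sequence = vapply(forms, peptideSequence, character(1)),
    amidated = vapply(forms, function(f) f@cTerm == "amide", logical(1)),
    length = nchar(sequences),
    cysteine_class = cysteineClass(sequences),
    net_charge = vapply(forms, netCharge, numeric(1)),
    hydrophobic_pct = hydrophobicFraction(sequences),
    hydrophobic_moment = vapply(unname(sequences), hydrophobicMoment,
                                numeric(1)),
    monoisotopic_mass = vapply(forms, monoisotopicMass, numeric(1)),
    average_mass = vapply(forms, averageMass, numeric(1)),
    row.names = NULL)
}
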