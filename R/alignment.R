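#' Alignment and bit-score parameters
#'
#' Defaults are the standard gapped BLOSUM62 settings (gap open 11, gap
#' extend 1, a length-L gap costing 11 + L) with the corresponding
#' Karlin-Altschul constants lambda = 0.267 and K = 0.041 used by BLASTP
#' for the bit-score conversion.
#'
#' @param matrix Substitution matrix name (default \code{"BLOSUM62"}).
#' @param gapOpen Gap opening penalty (default 11).
#' @param gapExtend Gap extension penalty per residue (default 1).
#' @param lambda Karlin-Altschul lambda (default 0.267).
#' @param karlinK Karlin-Altschul K (default 0.041).
#' @return A list of validated parameters.
#' @examples alignmentParams()
#' @export
alignmentParams <- function(matrix = "BLOSUM62", gapOpen = 11,
                            gapExtend = 1, lambda = 0.267, karlinK = 0.041) {
  stopifnot(lambda > 0, karlinK > 0, gapOpen >= 0, gapExtend >= 0)
  sub <- .getSubMatrix(matrix)
  list(matrix = matrix, submat = sub, gapOpen = gapOpen,
       gapExtend = gapExtend, lambda = lambda, karlinK = karlinK)
}

.getSubMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal local alignment score (Smith-Waterman, affine gaps)
#'
#' Raw optimal local-alignment score of two sequences under the given
#' substitution matrix and affine gap penalties (a gap of length L costs
#' \code{gapOpen + L * gapExtend}). The empty alignment scores 0, so the
#' result is never negative; the function is symmetric in its arguments.
#'
#' @param a,b Amino-acid sequences (20-letter alphabet).
#' @param params From \code{\link{alignmentParams}}.
#' @return Non-negative integer raw score.
#' @examples
#' smithWaterman("GFGRWLKKTWSKV", "GFGRWLKKTWSKV")  # 77
#' smithWaterman("KKKK", "DDDD")                    # 0
#' @export
smithWaterman <- function(a, b, params = alignmentParams()) {
  .checkStandardResidues(a, "first sequence")
  .checkStandardResidues(b, "second sequence")
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$submat, gapOpening = params$gapOpen,
    gapExtension = params$gapExtend, scoreOnly = TRUE)
  max(0, sc)
}

# Vectorised pairwise raw scores of each query against one subject.
.localScores <- function(queries, subject, params) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = params$submat,
    gapOpening = params$gapOpen, gapExtension = params$gapExtend,
    scoreOnly = TRUE)
  pmax(0, sc)
}

#' Convert a raw alignment score to bits
#'
#' Karlin-Altschul normalisation:
#' \code{bits = (lambda * raw - log(K)) / log(2)}. Strictly increasing in
#' the raw score; under the default constants, 100 bits requires a raw
#' score of at least 248.
#'
#' @param raw Non-negative raw score(s).
#' @param params From \code{\link{alignmentParams}}.
#' @return Numeric bit score(s).
#' @examples
#' bitScore(0)    # ~4.61
#' bitScore(100)  # ~43.13
#' @export
bitScore <- function(raw, params = alignmentParams()) {
  stopifnot(all(raw >= 0))
  (params$lambda * raw - log(params$karlinK)) / log(2)
}

#' Raw score needed to reach a bit-score threshold
#'
#' Algebraic inversion of \code{\link{bitScore}}, rounded up.
#'
#' @param bits Bit-score threshold.
#' @param params From \code{\link{alignmentParams}}.
#' @return Minimal integer raw score whose bit score reaches \code{bits}.
#' @examples rawScoreForBits(100)  # 248
#' @export
rawScoreForBits <- function(bits, params = alignmentParams()) {
  ceiling((bits * log(2) + log(params$karlinK)) / params$lambda)
}
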