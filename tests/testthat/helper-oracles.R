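# Independent oracles used to cross-check package results. These are kept
# deliberately naive (nested loops, exhaustive scans) and share no code
# with the implementation paths they verify.

# Gotoh affine-gap local alignment DP; gap of length L costs open + L*ext
bruteForceLocalScore <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (consume B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (consume A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# plain union-find over an edge list
unionFindComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# random peptide sequences over the 20-letter alphabet
randomPeptides <- function(n, len_range = c(10, 60)) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  vapply(seq_len(n), function(i)
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), TRUE),
          collapse = ""), character(1))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
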