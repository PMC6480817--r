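#' TN93 pairwise distance
#'
#' Closed-form Tamura-Nei distance between two aligned sequences with
#' pairwise deletion of gapped columns:
#' `d = -k1 log(w1) - k2 log(w2) - k3 log(w3)` with
#' `k1 = 2 gA gG / gR`, `k2 = 2 gC gT / gY`,
#' `k3 = 2 (gR gY - gA gG gY / gR - gC gT gR / gY)`,
#' `w1 = 1 - P1/(2 gA gG / gR) - Q/(2 gR)`,
#' `w2 = 1 - P2/(2 gC gT / gY) - Q/(2 gY)`, `w3 = 1 - Q/(2 gR gY)`,
#' where `P1`, `P2` are the observed proportions of A<->G and C<->T
#' transition differences and `Q` of transversion differences. A saturated
#' pair (any `w <= 0`) yields `Inf` with a warning.
#'
#' @param seqA,seqB aligned sequences (equal length; `-` treated as missing).
#' @param freqs base frequencies `c(A=,C=,G=,T=)`; defaults to the pooled
#'   empirical frequencies of the pair.
#' @return distance in expected substitutions per site (>= 0; 0 iff the
#'   sequences are identical on shared columns).
#' @export
tn93_distance <- function(seqA, seqB, freqs = NULL) {
  a <- if (length(seqA) == 1L) chars(toupper(seqA)) else toupper(seqA)
  b <- if (length(seqB) == 1L) chars(toupper(seqB)) else toupper(seqB)
  if (length(a) != length(b)) stopf("tn93_distance: sequences must be aligned")
  if (is.null(freqs)) {
    pool <- c(a, b)
    counts <- vapply(IUPAC_BASES, function(x) sum(pool == x), 0)
    if (sum(counts) == 0) stopf("tn93_distance: no bases")
    freqs <- pmax(counts / sum(counts), 1e-6)
    freqs <- freqs / sum(freqs)
  }
  pp <- pair_proportions(a, b)
  gA <- freqs[["A"]]; gC <- freqs[["C"]]; gG <- freqs[["G"]]; gT <- freqs[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - pp$P1 / k1 - pp$Q / (2 * gR)
  w2 <- 1 - pp$P2 / k2 - pp$Q / (2 * gY)
  w3 <- 1 - pp$Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    warnf("tn93_distance: saturated pair (non-positive logarithm argument)")
    return(Inf)
  }
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  max(d, 0)
}

#' TN93 distance matrix
#'
#' @param aln alignment (named character vector of equal-length rows).
#' @param freqs base frequencies; defaults to [empirical_base_freqs()] of
#'   the whole alignment (pooled, the convention used for tree building).
#' @return symmetric matrix with zero diagonal; entries may be `Inf` for
#'   saturated pairs.
#' @export
tn93_distance_matrix <- function(aln, freqs = NULL) {
  m <- as_aln_matrix(aln)
  if (is.null(freqs)) freqs <- empirical_base_freqs(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- tn93_distance(m[i, ], m[j, ], freqs)
  d
}
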