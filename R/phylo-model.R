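## Tamura-Nei (TN93) substitution model.
##
## TN93 allows unequal base frequencies and distinct A<->G and C<->T
## transition rates; transversions share one rate. Writing gR = gA + gG,
## gY = gC + gT and the per-branch decay factors
##   e2 = exp(-beta t), e3 = exp(-(gR alpha1 + gY beta) t),
##   e4 = exp(-(gY alpha2 + gR beta) t),
## the transition probabilities have a closed form, which this module uses
## for distances, likelihoods and sequence simulation alike.

## alignment helpers -------------------------------------------------------

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stopf("alignment rows must carry unique names")
  L <- unique(nchar(aln))
  if (length(L) != 1L) stopf("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Empirical base frequencies of an alignment
#'
#' Pooled over all rows; gaps and non-ACGT symbols are excluded. Zero counts
#' are floored at `1e-6` and the vector renormalised, so downstream
#' logarithms stay finite even for degenerate alignments.
#'
#' @param aln named character vector of equal-length sequences (or a
#'   character matrix of single bases).
#' @return named numeric vector `c(A=,C=,G=,T=)` summing to 1.
#' @export
empirical_base_freqs <- function(aln) {
  m <- as_aln_matrix(aln)
  counts <- vapply(IUPAC_BASES, function(b) sum(m == b), 0)
  if (sum(counts) == 0) stopf("empirical_base_freqs: no A/C/G/T symbols")
  f <- counts / sum(counts)
  f <- pmax(f, 1e-6)
  f / sum(f)
}

## observed pairwise proportions over shared ungapped columns
pair_proportions <- function(a, b) {
  ok <- a %in% IUPAC_BASES & b %in% IUPAC_BASES
  n <- sum(ok)
  if (n == 0L) stopf("no shared ungapped columns between sequences")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ag <- diff & (a %in% c("A", "G")) & (b %in% c("A", "G"))
  ct <- diff & (a %in% c("C", "T")) & (b %in% c("C", "T"))
  list(n = n, P1 = sum(ag) / n, P2 = sum(ct) / n,
       Q = sum(diff & !ag & !ct) / n)
}

#' TN93 model parameters
#'
#' Estimates base frequencies from the alignment and the two
#' transition/transversion rate ratios (`kappa1` = alpha1/beta for A<->G,
#' `kappa2` = alpha2/beta for C<->T) by inverting the closed-form expected
#' proportions pooled over all sequence pairs. The rate matrix is normalised
#' to one expected substitution per site per unit branch length.
#'
#' @param aln alignment (named character vector), or `NULL` when `freqs`,
#'   `kappa1` and `kappa2` are given directly.
#' @param freqs,kappa1,kappa2 optional explicit parameter values.
#' @return a `tn93_params` object: list with `freqs`, `gR`, `gY`, `kappa1`,
#'   `kappa2` and the normalised rates `alpha1`, `alpha2`, `beta`.
#' @export
tn93_params <- function(aln = NULL, freqs = NULL, kappa1 = NULL, kappa2 = NULL) {
  if (is.null(freqs)) {
    if (is.null(aln)) stopf("tn93_params: supply an alignment or frequencies")
    freqs <- empirical_base_freqs(aln)
  }
  freqs <- freqs[IUPAC_BASES]
  gR <- freqs[["A"]] + freqs[["G"]]; gY <- freqs[["C"]] + freqs[["T"]]
  if (is.null(kappa1) || is.null(kappa2)) {
    k1 <- k2 <- 2  # fallback for degenerate data
    if (!is.null(aln)) {
      m <- as_aln_matrix(aln)
      if (nrow(m) >= 2L) {
        P1 <- P2 <- Q <- W <- 0
        for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
          pp <- tryCatch(pair_proportions(m[i, ], m[j, ]), error = function(e) NULL)
          if (is.null(pp)) next
          P1 <- P1 + pp$n * pp$P1; P2 <- P2 + pp$n * pp$P2
          Q <- Q + pp$n * pp$Q; W <- W + pp$n
        }
        if (W > 0) {
          P1 <- P1 / W; P2 <- P2 / W; Q <- Q / W
          w1 <- 1 - P1 * gR / (2 * freqs[["A"]] * freqs[["G"]]) - Q / (2 * gR)
          w2 <- 1 - P2 * gY / (2 * freqs[["C"]] * freqs[["T"]]) - Q / (2 * gY)
          w3 <- 1 - Q / (2 * gR * gY)
          if (w1 > 0 && w2 > 0 && w3 > 0 && w3 < 1) {
            bt <- -log(w3)
            a1t <- (-log(w1) + gY * log(w3)) / gR
            a2t <- (-log(w2) + gR * log(w3)) / gY
            if (bt > 0) { k1 <- max(a1t / bt, 1e-6); k2 <- max(a2t / bt, 1e-6) }
          } else {
            warnf("tn93_params: saturated or invariant alignment; using kappa = 2")
          }
        }
      }
    }
    if (is.null(kappa1)) kappa1 <- k1
    if (is.null(kappa2)) kappa2 <- k2
  }
  ## normalise total rate to 1 substitution/site
  beta <- 1 / (2 * freqs[["A"]] * freqs[["G"]] * kappa1 +
               2 * freqs[["C"]] * freqs[["T"]] * kappa2 + 2 * gR * gY)
  structure(list(freqs = freqs, gR = gR, gY = gY,
                 kappa1 = kappa1, kappa2 = kappa2,
                 alpha1 = kappa1 * beta, alpha2 = kappa2 * beta, beta = beta),
            class = "tn93_params")
}

#' TN93 transition probability matrix
#'
#' Closed-form `P(t)`; rows and columns ordered A, C, G, T; rows sum to 1.
#'
#' @param params a [tn93_params()] object.
#' @param t branch length in expected substitutions per site.
#' @return 4x4 stochastic matrix.
#' @export
tn93_prob_matrix <- function(params, t) {
  f <- params$freqs; gR <- params$gR; gY <- params$gY
  e2 <- exp(-params$beta * t)
  e3 <- exp(-(gR * params$alpha1 + gY * params$beta) * t)
  e4 <- exp(-(gY * params$alpha2 + gR * params$beta) * t)
  A <- f[["A"]]; C <- f[["C"]]; G <- f[["G"]]; T <- f[["T"]]
  P <- matrix(0, 4, 4, dimnames = list(IUPAC_BASES, IUPAC_BASES))
  ## purines
  P["A", "A"] <- A + A * gY / gR * e2 + G / gR * e3
  P["A", "G"] <- G + G * gY / gR * e2 - G / gR * e3
  P["G", "G"] <- G + G * gY / gR * e2 + A / gR * e3
  P["G", "A"] <- A + A * gY / gR * e2 - A / gR * e3
  P["A", "C"] <- P["G", "C"] <- C * (1 - e2)
  P["A", "T"] <- P["G", "T"] <- T * (1 - e2)
  ## pyrimidines
  P["C", "C"] <- C + C * gR / gY * e2 + T / gY * e4
  P["C", "T"] <- T + T * gR / gY * e2 - T / gY * e4
  P["T", "T"] <- T + T * gR / gY * e2 + C / gY * e4
  P["T", "C"] <- C + C * gR / gY * e2 - C / gY * e4
  P["C", "A"] <- P["T", "A"] <- A * (1 - e2)
  P["C", "G"] <- P["T", "G"] <- G * (1 - e2)
  P
}

## instantaneous rate matrix (mainly for cross-checks)
tn93_rate_matrix <- function(params) {
  f <- params$freqs
  Q <- matrix(0, 4, 4, dimnames = list(IUPAC_BASES, IUPAC_BASES))
  for (i in IUPAC_BASES) for (j in IUPAC_BASES) {
    if (i == j) next
    transition1 <- all(c(i, j) %in% c("A", "G"))
    transition2 <- all(c(i, j) %in% c("C", "T"))
    rate <- if (transition1) params$alpha1 else if (transition2) params$alpha2
            else params$beta
    Q[i, j] <- rate * f[[j]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}
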