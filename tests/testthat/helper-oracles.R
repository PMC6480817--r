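## Independent numerical oracles used across the suite. These deliberately
## avoid the package's closed-form transition probabilities: P(t) is obtained
## by eigen-decomposition of the rate matrix.

BASES <- c("A", "C", "G", "T")

oracle_rate_matrix <- function(a1, a2, be, f) {
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in BASES) for (j in BASES) {
    if (i == j) next
    r <- if (all(c(i, j) %in% c("A", "G"))) a1
         else if (all(c(i, j) %in% c("C", "T"))) a2 else be
    Q[i, j] <- r * f[[j]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

oracle_prob_matrix <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  dimnames(P) <- list(BASES, BASES)
  P
}

## Numerical pairwise-ML oracle for the TN93 distance: maximises the
## multinomial likelihood of the observed transition/transversion difference
## counts over (alpha1 t, alpha2 t, beta t), then reports the implied
## expected number of substitutions per site.
tn93_ml_oracle <- function(seqA, seqB, f) {
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  n <- length(a); d <- a != b
  n1 <- sum(d & a %in% c("A", "G") & b %in% c("A", "G"))
  n2 <- sum(d & a %in% c("C", "T") & b %in% c("C", "T"))
  nq <- sum(d) - n1 - n2
  nll <- function(logp) {
    Q <- oracle_rate_matrix(exp(logp[1]), exp(logp[2]), exp(logp[3]), f)
    P <- oracle_prob_matrix(Q, 1)
    p1 <- f[["A"]] * P["A", "G"] + f[["G"]] * P["G", "A"]
    p2 <- f[["C"]] * P["C", "T"] + f[["T"]] * P["T", "C"]
    q <- sum(f * (1 - diag(P))) - p1 - p2
    p0 <- 1 - p1 - p2 - q
    if (min(p1, p2, q, p0) <= 0) return(1e10)
    -(n1 * log(p1) + n2 * log(p2) + nq * log(q) + (n - n1 - n2 - nq) * log(p0))
  }
  o <- stats::optim(log(c(0.1, 0.1, 0.03)), nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 20000))
  o <- stats::optim(o$par, nll, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 1000))
  p <- exp(o$par)
  2 * (f[["A"]] * f[["G"]] * p[1] + f[["C"]] * f[["T"]] * p[2] +
       (f[["A"]] + f[["G"]]) * (f[["C"]] + f[["T"]]) * p[3])
}

## Draw a simulated pair in which all three difference classes (A<->G,
## C<->T, transversion) are observed - the domain on which the closed-form
## TN93 estimator coincides with the constrained ML optimum.
simulate_informative_pair <- function(d, params, n_sites, seed) {
  for (off in 0:50) {
    pr <- simulate_sequence_pair(d, params, n_sites, seed + 1000L * off)
    a <- strsplit(pr[1], "")[[1]]; b <- strsplit(pr[2], "")[[1]]
    df <- a != b
    n1 <- sum(df & a %in% c("A", "G") & b %in% c("A", "G"))
    n2 <- sum(df & a %in% c("C", "T") & b %in% c("C", "T"))
    if (n1 >= 1 && n2 >= 1 && sum(df) - n1 - n2 >= 1) return(pr)
  }
  stop("no informative pair found")
}

## Brute-force tree likelihood: explicit sum over all internal-node state
## assignments (feasible for <= 4 taxa).
brute_force_loglik <- function(tree, aln, params) {
  ntip <- length(tree$tip.label)
  m <- do.call(rbind, strsplit(toupper(aln), ""))[tree$tip.label, , drop = FALSE]
  Qr <- oracle_rate_matrix(params$alpha1, params$alpha2, params$beta,
                           params$freqs)
  Pm <- lapply(tree$edge.length, function(t) oracle_prob_matrix(Qr, max(t, 0)))
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  combos <- expand.grid(rep(list(BASES), length(internal)),
                        stringsAsFactors = FALSE)
  total <- 0
  for (s in seq_len(ncol(m))) {
    site <- 0
    for (r in seq_len(nrow(combos))) {
      st <- character(ntip + tree$Nnode)
      st[seq_len(ntip)] <- m[, s]
      st[internal] <- as.character(combos[r, ])
      pr <- params$freqs[[st[ntip + 1L]]]
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * Pm[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      site <- site + pr
    }
    total <- total + log(site)
  }
  total
}

## Shared simulation cache so expensive datasets are built once per run.
.sim_cache <- new.env(parent = emptyenv())

cached_study_sim <- function(n_total, seed) {
  key <- sprintf("sim_%d_%d", n_total, seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- study_simulation_config(seed = seed, n_total = n_total)
    .sim_cache[[key]] <- simulate_dataset(cfg)
  }
  .sim_cache[[key]]
}

## truth table in long genotype-record form
truth_records <- function(truth) {
  codons <- as.integer(sub("^gt_", "", grep("^gt_", names(truth), value = TRUE)))
  do.call(rbind, lapply(codons, function(cn)
    data.frame(individual_id = truth$individual_id,
               population = truth$population, codon = cn,
               genotype = truth[[paste0("gt_", cn)]], status = "called",
               stringsAsFactors = FALSE)))
}
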