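par0 <- tn93_params(freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                    kappa1 = 4, kappa2 = 2)

test_that("base frequency estimation counts correctly and floors zeros", {
  aln <- c(a = "ACGT", b = "ACGT")
  expect_equal(unname(empirical_base_freqs(aln)), rep(0.25, 4))
  ## all-A alignment: floored, renormalised, no division by zero
  f <- empirical_base_freqs(c(a = "AAAA", b = "AA-A"))
  expect_equal(sum(f), 1)
  expect_true(all(f > 0))
  expect_gt(f[["A"]], 0.99)
  ## direct counting oracle on a random alignment
  set.seed(1)
  rows <- replicate(4, paste(sample(c("A", "C", "G", "T", "-"), 100, TRUE,
                                    prob = c(.3, .2, .2, .25, .05)),
                             collapse = ""))
  names(rows) <- paste0("t", 1:4)
  pooled <- unlist(strsplit(rows, ""))
  pooled <- pooled[pooled != "-"]
  expect_equal(unname(empirical_base_freqs(rows)),
               as.numeric(table(factor(pooled, c("A", "C", "G", "T")))) / length(pooled),
               tolerance = 1e-12)
})

test_that("transition probabilities form a proper reversible kernel", {
  for (t in c(0, 0.01, 0.3, 2)) {
    P <- tn93_prob_matrix(par0, t)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= 0))
    ## detailed balance
    f <- par0$freqs
    expect_equal(f[["A"]] * P["A", "G"], f[["G"]] * P["G", "A"], tolerance = 1e-12)
    expect_equal(f[["C"]] * P["C", "T"], f[["T"]] * P["T", "C"], tolerance = 1e-12)
  }
  expect_equal(unname(tn93_prob_matrix(par0, 0)), diag(4), tolerance = 1e-12)
  ## matches the eigen-decomposition matrix exponential
  Q <- kdrhap:::tn93_rate_matrix(par0)
  expect_equal(tn93_prob_matrix(par0, 0.37), oracle_prob_matrix(Q, 0.37),
               tolerance = 1e-10)
  ## normalisation: one expected substitution per unit branch length
  expect_equal(-sum(par0$freqs * diag(Q)), 1, tolerance = 1e-12)
})

test_that("TN93 distance: identity, saturation sentinel, missing data", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)
  expect_warning(d <- tn93_distance(strrep("A", 40), strrep("C", 40),
                                    c(A = .25, C = .25, G = .25, T = .25)),
                 "saturated")
  expect_equal(d, Inf)
  expect_error(tn93_distance("--", "AC"), "columns")
  ## pairwise deletion: the gapped column is simply dropped
  expect_equal(tn93_distance("ACG-", "ACGT"), 0)
})

test_that("TN93 reduces to Jukes-Cantor in the symmetric configuration", {
  ## equal frequencies; substitutions spread uniformly over the 12 ordered
  ## changes, i.e. P1 = P2 = Q/4 - the configuration a Jukes-Cantor process
  ## actually produces
  n <- 480
  a <- rep(c("A", "C", "G", "T"), n / 4)  # A at 1 mod 4, C at 2, G at 3, T at 0
  b <- a
  b[seq(1, 37, 4)] <- "G"    # 10 A->G transitions
  b[seq(122, 158, 4)] <- "T" # 10 C->T transitions
  b[seq(243, 319, 4)] <- "C" # 20 G->C transversions
  b[seq(364, 440, 4)] <- "A" # 20 T->A transversions
  f <- c(A = .25, C = .25, G = .25, T = .25)
  d <- tn93_distance(paste(a, collapse = ""), paste(b, collapse = ""), f)
  p <- 60 / n
  expect_equal(d, -3 / 4 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("distances agree with an independent implementation (ape)", {
  for (s in 1:5) {
    pr <- simulate_sequence_pair(0.08, par0, 1500, seed = 400 + s)
    bin <- ape::as.DNAbin(rbind(a = strsplit(pr[1], "")[[1]],
                                b = strsplit(pr[2], "")[[1]]))
    d_ape <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    d_mine <- tn93_distance(pr[1], pr[2], empirical_base_freqs(pr))
    expect_equal(d_mine, d_ape, tolerance = 1e-9)
  }
})

test_that("the distance matrix is symmetric with zero diagonal", {
  tr <- read_newick("((a:0.05,b:0.06):0.02,(c:0.05,d:0.04):0.03,e:0.08);")
  aln <- simulate_alignment(tr, par0, 400, seed = 17)
  D <- tn93_distance_matrix(aln)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_true(all(D[upper.tri(D)] > 0))
})
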