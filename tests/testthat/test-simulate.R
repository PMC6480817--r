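d2 <- d2_amplicon()
d3 <- d3_amplicon()

test_that("haplotype pools are built from variant descriptions", {
  pool <- build_haplotype_pool(d2, list(
    hap_variant("wild"),
    hap_variant("g1016", codons = c(`1016` = "GGA"))))
  expect_equal(nrow(pool), 2)
  expect_equal(pool$res_1016, c("V", "G"))
  ## exactly one substitution apart
  expect_equal(nrow(pairwise_differences(pool$seq[1], pool$seq[2])), 1)

  ## two 1534S haplotypes differing in both exon and intron
  pool3 <- build_haplotype_pool(d3, list(
    hap_variant("s1", codons = c(`1534` = "TCC")),
    hap_variant("s2", codons = c(`1534` = "TCC"),
                snps = stats::setNames("A", codon_positions(d3, 1495)[3]),
                intron_del = c(30L, 15L))))
  expect_equal(nrow(pool3), 2)
  expect_true(all(pool3$res_1534 == "S"))
  expect_equal(pool3$intron_length, c(83, 68))

  ## a D3 double mutant is refused
  expect_error(build_haplotype_pool(d3, list(
    hap_variant("bad", codons = c(`1532` = "ACC", `1534` = "TCC")))),
    "both")
  ## as are duplicate sequences
  expect_error(build_haplotype_pool(d2, list(hap_variant("a"), hap_variant("b"))),
               "duplicate")
})

test_that("study pools mirror the catalogued haplotype structure", {
  p2 <- study_haplotype_pool(d2)
  p3 <- study_haplotype_pool(d3)
  expect_equal(nrow(p2), 17)
  expect_equal(nrow(p3), 19)
  expect_false(anyDuplicated(p2$seq) > 0)
  expect_false(anyDuplicated(p3$seq) > 0)
  expect_true(all(p2$intron_length >= 71 & p2$intron_length <= 91))
  expect_true(all(p3$intron_length >= 67 & p3$intron_length <= 83))
  ## one 1016G, one 1000Y, one 1532T, two 1534S, one 1534L
  expect_equal(sum(p2$res_1016 == "G"), 1)
  expect_equal(sum(p2$res_1000 == "Y"), 1)
  expect_equal(sum(p3$res_1532 == "T"), 1)
  expect_equal(sum(p3$res_1534 == "S"), 2)
  expect_equal(sum(p3$res_1534 == "L"), 1)
  ## the resistant haplotype is one mutational step from its wild background
  expect_equal(nrow(pairwise_differences(p2$seq[p2$label == "D2H07"],
                                         p2$seq[p2$label == "D2H05"])), 1)
})

make_cfg <- function(freq_g, n, seed = 42) {
  pool <- build_haplotype_pool(d2, list(
    hap_variant("wild"),
    hap_variant("g1016", codons = c(`1016` = "GGA"))))
  simulation_config(populations = c(P1 = n), specs = list(D2 = d2),
                    pools = list(D2 = pool),
                    freqs = list(D2 = c(wild = 1 - freq_g, g1016 = freq_g)),
                    seed = seed)
}

test_that("sampling follows the configured haplotype frequencies", {
  ## degenerate pool: everyone homozygous wild
  fixed <- sample_individuals(make_cfg(0, 50))
  expect_true(all(fixed$hap1_D2 == "wild" & fixed$hap2_D2 == "wild"))
  expect_true(all(fixed$gt_1016 == "V/V"))

  ## law of large numbers: observed allele frequency within 3 binomial SE
  big <- sample_individuals(make_cfg(0.5, 10000))
  p_hat <- mean(c(big$hap1_D2, big$hap2_D2) == "g1016")
  se <- sqrt(0.5 * 0.5 / 20000)
  expect_lt(abs(p_hat - 0.5), 3 * se)

  ## truth genotypes re-derive from the haplotype pair
  pool <- make_cfg(0.5, 1)$pools$D2
  rederived <- format_genotype(
    pool$res_1016[match(big$hap1_D2, pool$label)],
    pool$res_1016[match(big$hap2_D2, pool$label)], "V")
  expect_identical(big$gt_1016, rederived)
})

test_that("populations with different frequencies differ accordingly", {
  pool <- build_haplotype_pool(d2, list(
    hap_variant("wild"),
    hap_variant("g1016", codons = c(`1016` = "GGA"))))
  cfg <- simulation_config(
    populations = c(A = 400, B = 400), specs = list(D2 = d2),
    pools = list(D2 = pool),
    freqs = list(A = list(D2 = c(wild = 1, g1016 = 0)),
                 B = list(D2 = c(wild = 0.2, g1016 = 0.8))),
    seed = 3)
  truth <- sample_individuals(cfg)
  fa <- mean(c(truth$hap1_D2, truth$hap2_D2)[rep(truth$population == "A", 2)] == "g1016")
  fb <- mean(c(truth$hap1_D2, truth$hap2_D2)[rep(truth$population == "B", 2)] == "g1016")
  expect_equal(fa, 0)
  expect_gt(fb, 0.7)
})

test_that("consensus rendering merges alleles and truncates at indels", {
  p2 <- study_haplotype_pool(d2)
  h05 <- p2[p2$label == "D2H05", ]; h07 <- p2[p2$label == "D2H07", ]
  cons <- render_consensus(h05, h07)
  expect_false(cons$length_het)
  expect_equal(cons$n_het, 1)
  ## the double peak sits at codon 1016: consensus codon is GKA
  pos <- codon_positions(d2, 1016)
  expect_equal(substr(cons$seq, pos[1] + 1, pos[3] + 1), "GKA")

  ## identical haplotypes: consensus equals the haplotype
  hom <- render_consensus(h05, h05)
  expect_equal(hom$seq, h05$seq)
  expect_equal(hom$n_het, 0)

  ## 91-bp + 71-bp intron pair: heterozygous indel, truncated consensus
  h02 <- p2[p2$label == "D2H02", ]; h10 <- p2[p2$label == "D2H10", ]
  lh <- render_consensus(h02, h10)
  expect_true(lh$length_het)
  expect_lt(nchar(lh$seq), nchar(h02$seq))

  expect_error(render_consensus(h05, study_haplotype_pool(d3)[1, ]),
               "different amplicons")
})

test_that("clone rendering is faithful and covers both alleles often enough", {
  p2 <- study_haplotype_pool(d2)
  a <- p2$seq[1]; b <- p2$seq[2]
  expect_error(render_clones(a, b, 1, seed = 1), "at least 2")
  expect_length(render_clones(a, b, 3, seed = 1), 3)
  expect_true(all(render_clones(a, a, 5, seed = 1) == a))
  expect_true(all(render_clones(a, b, 8, seed = 2) %in% c(a, b)))
  ## both haplotypes present with probability 1 - 2 (1/2)^k = 0.998 at k = 10
  both <- vapply(1:200, function(s)
    length(unique(render_clones(a, b, 10, seed = s))) == 2, TRUE)
  expect_gte(sum(both), 190)
  ## completed-protocol mode guarantees coverage
  both_forced <- vapply(1:50, function(s)
    length(unique(render_clones(a, b, 3, seed = s, ensure_both = TRUE))) == 2, TRUE)
  expect_true(all(both_forced))
})

test_that("datasets round-trip through FASTA/TSV on disk", {
  sim <- cached_study_sim(40, seed = 5)
  expect_equal(nrow(sim$consensus), 2 * nrow(sim$truth))  # two amplicons each
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  back <- read_dataset(dir)
  key <- function(df) paste(df$individual_id, df$amplicon)
  i <- match(key(sim$consensus), key(back$consensus))
  expect_identical(back$consensus$seq[i], sim$consensus$seq)
  expect_identical(back$consensus$length_het[i], sim$consensus$length_het)
  expect_equal(nrow(back$clones), nrow(sim$clones))
  expect_identical(sort(back$clones$seq), sort(sim$clones$seq))
  expect_equal(back$truth$individual_id, sim$truth$individual_id)
})
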