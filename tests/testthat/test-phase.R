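d2 <- d2_amplicon()

cons_of <- function(a, b) render_consensus(list(amplicon = "D2", seq = a),
                                           list(amplicon = "D2", seq = b))

p2 <- study_haplotype_pool(d2)
wild <- p2$seq[p2$label == "D2H05"]
mut <- p2$seq[p2$label == "D2H07"]    # one step away (1016G)
other <- p2$seq[p2$label == "D2H02"]  # several steps + length difference

test_that("direct phasing: homozygote and one-site rules", {
  hom <- phase_direct(cons_of(wild, wild))
  expect_equal(hom$status, "resolved")
  expect_equal(hom$haplotypes, c(wild, wild))

  ## a single K double peak at codon 1016 splits into GTA- and GGA-alleles
  one <- phase_direct(cons_of(wild, mut))
  expect_equal(one$status, "resolved")
  expect_setequal(one$haplotypes, c(wild, mut))

  ## two heterozygous sites (equal-length pair): unknowable from one trace
  eq_pair <- p2$seq[p2$label %in% c("D2H02", "D2H04")]  # both 91-bp introns
  two_het <- cons_of(eq_pair[1], eq_pair[2])
  expect_gte(two_het$n_het, 2)
  expect_equal(phase_direct(two_het)$status, "unresolved_requires_clones")

  ## heterozygous intron indel: clones required regardless of het count
  lh <- cons_of(wild, other)
  expect_true(lh$length_het)
  expect_equal(phase_direct(lh)$status, "unresolved_requires_clones")
})

test_that("clone cross-checking resolves multi-site heterozygotes", {
  eq_pair <- p2$seq[p2$label %in% c("D2H02", "D2H04")]
  cons <- cons_of(eq_pair[1], eq_pair[2])
  got <- phase_with_clones(cons, c(rep(eq_pair[1], 4), rep(eq_pair[2], 3)))
  expect_equal(got$status, "resolved")
  expect_setequal(got$haplotypes, eq_pair)

  ## homozygote with all-identical clones
  hom <- phase_with_clones(cons_of(wild, wild), rep(wild, 3))
  expect_equal(hom$status, "resolved")
  expect_equal(hom$haplotypes, c(wild, wild))

  ## clones that cannot merge back to the consensus are inconsistent
  expect_equal(phase_with_clones(cons, rep(eq_pair[1], 3))$status, "inconsistent")

  ## length-heterozygous individuals resolve over the readable prefix
  lh <- cons_of(wild, other)
  got_lh <- phase_with_clones(lh, c(wild, other, wild))
  expect_equal(got_lh$status, "resolved")
  expect_setequal(got_lh$haplotypes, c(wild, other))

  expect_error(phase_with_clones(cons, wild), "at least 2")
  expect_error(
    phase_with_clones(cons, data.frame(individual_id = "x", seq = wild),
                      individual_id = "y"),
    "different individual")
})

test_that("resolved pairs always re-merge to their consensus", {
  sim <- cached_study_sim(40, seed = 5)
  ph <- phase_individuals(sim$consensus, sim$clones)
  expect_true(all(ph$status == "resolved"))
  for (i in seq_len(nrow(ph))) {
    m <- render_consensus(list(amplicon = ph$amplicon[i], seq = ph$hap1[i]),
                          list(amplicon = ph$amplicon[i], seq = ph$hap2[i]))
    co <- sim$consensus[sim$consensus$individual_id == ph$individual_id[i] &
                        sim$consensus$amplicon == ph$amplicon[i], ]
    expect_identical(m$seq, co$seq)
    expect_identical(m$length_het, co$length_het)
  }
})

test_that("the catalog names, annotates and tallies unique haplotypes", {
  ## 32 phased individuals all sharing one 1016G haplotype -> one G entry
  ph <- data.frame(individual_id = sprintf("i%02d", 1:32), population = "P",
                   amplicon = "D2", status = "resolved", method = "direct",
                   hap1 = wild, hap2 = mut, stringsAsFactors = FALSE)
  cat32 <- build_catalog(ph, d2)
  expect_equal(nrow(cat32), 2)
  expect_equal(sum(cat32$res_1016 == "G"), 1)
  expect_equal(sum(cat32$count), 64)
  expect_equal(cat32$name, c("D2H01", "D2H02"))  # first-observation order

  ## empty input -> empty catalog
  expect_equal(nrow(build_catalog(ph[0, ], d2)), 0)
})

test_that("catalog recovered from a simulation matches the generating pool", {
  sim <- cached_study_sim(200, seed = 11)
  ph <- phase_individuals(sim$consensus, sim$clones)
  expect_true(all(ph$status == "resolved"))
  for (amp in c("D2", "D3")) {
    spec <- sim$config$specs[[amp]]
    pool <- sim$config$pools[[amp]]
    ctg <- build_catalog(ph, spec)
    sampled <- unique(pool$seq[match(c(sim$truth[[paste0("hap1_", amp)]],
                                       sim$truth[[paste0("hap2_", amp)]]),
                                     pool$label)])
    expect_setequal(ctg$seq, sampled)
    ## chromosome conservation
    expect_equal(sum(ctg$count),
                 2 * sum(ph$amplicon == amp & ph$status == "resolved"))
    ## intron lengths agree with the pool annotation
    expect_equal(ctg$intron_length,
                 pool$intron_length[match(ctg$seq, pool$seq)])
  }
})
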