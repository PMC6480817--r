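fx <- load_paper_fixture()

test_that("allele frequencies follow the diploid count and half-up rounding", {
  expect_equal(round_half_up(allele_frequency(12, 5, 17)), 0.647)
  expect_equal(round_half_up(allele_frequency(11, 9, 27)), 0.537)
  expect_equal(round_half_up(allele_frequency(14, 1, 29)), 0.276)
  expect_equal(round_half_up(allele_frequency(1, 0, 27)), 0.019)
  expect_equal(allele_frequency(0, 0, 10), 0)
  expect_error(allele_frequency(1, 0, 0), "positive")
  expect_error(allele_frequency(8, 5, 10), "exceed")
  ## half-up, not banker's rounding
  expect_equal(round_half_up(1 / 54), 0.019)
  expect_equal(round_half_up(22 / 34), 0.647)
  expect_equal(round_half_up(0.0185), 0.019)
})

test_that("genotype counts conserve individuals and survive shuffling", {
  tbl <- fx$table2
  ## every population row sums to its n at every locus
  for (p in unique(tbl$population)) for (cn in unique(tbl$codon)) {
    expect_equal(sum(tbl$count[tbl$population == p & tbl$codon == cn]),
                 unname(fx$n[p]))
  }
  ## totals row equals column sums
  wide <- genotype_table_wide(tbl)
  tot <- wide[wide$population == "Total", ]
  expect_equal(tot$n, 426)
  expect_equal(unname(unlist(tot[paste0("1016.", c("V/V", "V/G", "G/G"))])),
               c(360, 55, 11))
  expect_equal(unname(unlist(tot[paste0("1532.", c("I/I", "I/T", "T/T"))])),
               c(265, 119, 42))
  expect_equal(unname(unlist(tot[paste0("1534.", c("F/F", "F/S", "F/L", "S/S"))])),
               c(405, 19, 1, 1))

  ## invariance to record order
  shuffled <- fx$records[sample(nrow(fx$records)), ]
  ft1 <- allele_frequency_table(build_genotype_count_table(shuffled))
  ft0 <- allele_frequency_table(tbl)
  key <- function(d) d[order(d$population, d$codon, d$allele), "frequency"]
  expect_equal(key(ft1), key(ft0))
})

test_that("combination types partition individuals with Type 1 the wild triple", {
  cls <- classify_combination(fx$records, fx$label_map)
  expect_equal(cls$type[cls$signature == "V/V|I/I|F/F"][1], 1)
  expect_equal(nrow(cls) + nrow(attr(cls, "excluded")), 426)
  cft <- combination_frequency_table(fx$records, fx$label_map)
  ## per population, type counts sum to n
  for (p in unique(cft$population))
    expect_equal(sum(cft$count[cft$population == p]), unname(fx$n[p]))
  ## published examples
  expect_equal(cft$type[cft$population == "HR"], 1)
  expect_equal(cft$freq_3dp[cft$population == "HR"], 1.000)
  tz <- cft[cft$population == "TZ", ]
  expect_equal(nrow(tz), 10)
  gg <- cft[cft$signature == "G/G|I/I|F/F", ]
  expect_true(all(gg$type == 2))
})

test_that("first-observation labelling still reserves Type 1 for the wild triple", {
  ## records whose first individual is a mutant combination
  rec <- fx$records[fx$records$population == "HD", ]
  cls <- classify_combination(rec)  # no label map supplied
  expect_false("V/V|I/I|F/F" %in% cls$signature)  # HD has no wild triples
  expect_true(all(cls$type >= 2))

  ## a single all-wild population yields one type at frequency 1
  hr <- fx$records[fx$records$population == "HR", ]
  cft <- combination_frequency_table(hr)
  expect_equal(nrow(cft), 1)
  expect_equal(cft$type, 1)
  expect_equal(cft$freq_3dp, 1.000)
})

test_that("individuals missing a call are excluded and reported", {
  rec <- fx$records[fx$records$population == "CP", ]
  rec$status[rec$individual_id == "CP_001" & rec$codon == 1534] <- "missing"
  cls <- classify_combination(rec)
  expect_false("CP_001" %in% cls$individual_id)
  expect_equal(attr(cls, "excluded")$individual_id, "CP_001")
})

test_that("carriers and allele presence match the published counts", {
  expect_equal(carrier_count(fx$records, 1532, "T"), 161)
  expect_equal(carrier_count(fx$records, 1534, "S"), 20)
  expect_equal(carrier_count(fx$records, 1534, "C"), 0)
  pg <- populations_with_allele(fx$records, 1016, "G")
  expect_equal(pg$count, 13)
  expect_setequal(pg$absent, c("HR", "YQ", "PG", "SY"))
  expect_equal(populations_with_allele(fx$records, 1532, "T")$count, 15)
  none <- populations_with_allele(fx$records, 1534, "C")
  expect_equal(none$count, 0)
})
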