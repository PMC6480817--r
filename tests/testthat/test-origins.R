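d3 <- d3_amplicon()

test_that("pairwise differences: identity, symmetry, gap-as-one-event", {
  expect_equal(nrow(pairwise_differences("ACGT", "ACGT")), 0)
  d <- pairwise_differences("ACGTA", "AGGTA")
  expect_equal(d$position, 1)
  expect_equal(d$a, "C"); expect_equal(d$b, "G")
  ## symmetry
  d2 <- pairwise_differences("AGGTA", "ACGTA")
  expect_equal(d2$a, "G"); expect_equal(d2$b, "C")
  ## an indel counts once
  g <- pairwise_differences("ACGTTTACGT", "ACGTACGT")
  expect_equal(nrow(g), 1)
  expect_equal(g$b, "-")
})

test_that("difference count is a metric on equal-length sequences", {
  ## exhaustive over all length-3 strings on a two-letter alphabet
  strs <- apply(expand.grid(c("A", "C"), c("A", "C"), c("A", "C")), 1,
                paste, collapse = "")
  n <- length(strs)
  d <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- nrow(pairwise_differences(strs[i], strs[j]))
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all((d == 0) == (outer(strs, strs, "=="))))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j])
})

test_that("the two 1534S study haplotypes differ in both exon and intron", {
  p3 <- study_haplotype_pool(d3)
  s1 <- p3$seq[p3$label == "D3H03"]  # 83-bp intron
  s2 <- p3$seq[p3$label == "D3H13"]  # 68-bp intron
  diffs <- pairwise_differences(s1, s2)
  i0 <- d3$intron_interval[1]; i1 <- d3$intron_interval[2]
  in_intron <- diffs$position >= i0 & diffs$position < i1
  expect_true(any(in_intron))
  expect_true(any(!in_intron))
})

## a small constructed catalog exercising the origin logic
toy_catalog <- function() {
  p3 <- study_haplotype_pool(d3)
  keep <- c("D3H02", "D3H04", "D3H06", "D3H08",   # wild backgrounds
            "D3H01", "D3H03", "D3H13")            # 1532T + the two 1534S
  ctg <- p3[match(keep, p3$label), ]
  ph <- data.frame(individual_id = paste0("i", seq_along(keep)),
                   population = "P", amplicon = "D3", status = "resolved",
                   method = "clones", hap1 = ctg$seq, hap2 = ctg$seq,
                   stringsAsFactors = FALSE)
  build_catalog(ph, d3)
}

test_that("nearest wild neighbours identify one-step origins, ties and all", {
  ctg <- toy_catalog()
  nw <- nearest_wild_neighbors(ctg)
  expect_equal(nrow(nw), 3)  # D3H01, D3H03, D3H13 (catalog naming order)
  expect_true(all(nw$distance == 1))
  ## each mutant points at exactly its generating wild background
  by_seq <- stats::setNames(ctg$name, ctg$seq)
  p3 <- study_haplotype_pool(d3)
  lookup <- function(lbl) unname(by_seq[p3$seq[p3$label == lbl]])
  expect_equal(nw$wild[nw$mutant == lookup("D3H01")], lookup("D3H08"))
  expect_equal(nw$wild[nw$mutant == lookup("D3H03")], lookup("D3H04"))
  expect_equal(nw$wild[nw$mutant == lookup("D3H13")], lookup("D3H06"))
})

test_that("constructed distances give minimal sets exactly", {
  ## mutant M differs from wild W1 by 1 and W2 by 5 -> {W1}, distance 1
  base <- strrep("A", 30)
  w1 <- base
  w2 <- base; for (k in 1:5) substr(w2, k, k) <- "C"
  m <- base; substr(m, 10, 10) <- "G"
  ctg <- data.frame(name = c("W1", "W2", "M"), amplicon = "X",
                    seq = c(w1, w2, m), intron_length = 0L,
                    res_1534 = c("F", "F", "S"), count = 1L,
                    stringsAsFactors = FALSE)
  attr(ctg, "wild_residues") <- c(`1534` = "F")
  attr(ctg, "kdr_codons") <- 1534L
  nw <- nearest_wild_neighbors(ctg)
  expect_equal(nw$mutant, "M")
  expect_equal(nw$distance, 1)
  expect_equal(nw$wild, "W1")
})

test_that("distant same-residue mutants with disjoint parents are flagged", {
  ctg <- toy_catalog()
  flags <- independent_origin_candidates(ctg)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$codon, 1534)
  expect_equal(flags$residue, "S")
  expect_gte(flags$mutual_distance, 3)
  ## catalog with no mutants -> nothing to report
  wilds <- ctg[ctg$res_1532 == "I" & ctg$res_1534 == "F", ]
  attr(wilds, "wild_residues") <- attr(ctg, "wild_residues")
  attr(wilds, "kdr_codons") <- attr(ctg, "kdr_codons")
  expect_equal(nrow(nearest_wild_neighbors(wilds)), 0)
  expect_equal(nrow(independent_origin_candidates(wilds)), 0)
})
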