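d2 <- d2_amplicon()
d3 <- d3_amplicon()

## plant a (possibly ambiguous) codon into the reference consensus
with_codon <- function(spec, codon_number, codon) {
  s <- spec$reference_seq
  pos <- codon_positions(spec, codon_number)
  for (k in 1:3) substr(s, pos[k] + 1, pos[k] + 1) <- substr(codon, k, k)
  s
}

test_that("documented double-peak codons call the documented genotypes", {
  cases <- list(
    list(d2, 1016, "GKA", "V/G"),   # GTA/GGA
    list(d2, 1000, "TMC", "S/Y"),   # TCC/TAC
    list(d3, 1532, "AYC", "I/T"),   # ATC/ACC
    list(d3, 1534, "TYC", "F/S"),   # TTC/TCC
    list(d3, 1534, "TTS", "F/L"),   # TTC/TTG
    list(d3, 1534, "TKC", "F/C"))   # TTC/TGC: 1534C capability
  for (cs in cases) {
    g <- call_codon_genotype(cs[[1]], with_codon(cs[[1]], cs[[2]], cs[[3]]), cs[[2]])
    expect_equal(g$status, "called", info = cs[[3]])
    expect_equal(g$genotype, cs[[4]], info = cs[[3]])
  }
})

test_that("multi-het codons are called only when every decomposition agrees", {
  ## AYM = merge of ATA and ACC; both decompositions {ATA,ACC} and {ACA,ATC}
  ## translate to {Ile, Thr}
  decomp_aminos <- unique(t(sapply(list(c("ATA", "ACC"), c("ACA", "ATC")),
                                   function(p) sort(sapply(p, translate_codon)))))
  expect_equal(nrow(decomp_aminos), 1)
  g <- call_codon_genotype(d3, with_codon(d3, 1532, "AYM"), 1532)
  expect_equal(g$status, "called")
  expect_equal(g$genotype, "I/T")

  ## RTA at 1016 = GTA/ATA is V/I unambiguously, but RKA (GTA/GGA/ATA/AGA)
  ## mixes amino pairs and must come back ambiguous
  amb <- call_codon_genotype(d2, with_codon(d2, 1016, "RKA"), 1016)
  expect_equal(amb$status, "ambiguous")
  expect_true(is.na(amb$genotype))
})

test_that("degenerate evidence yields missing, never an error", {
  bad <- with_codon(d2, 1016, "GNA")  # four-allele/unknown symbol
  g <- call_codon_genotype(d2, structure(list(amplicon = "D2", seq = bad,
                                              length_het = FALSE),
                                         class = "diploid_consensus"), 1016)
  expect_equal(g$status, "missing")
  expect_equal(g$flag, "non_iupac_symbol")
})

test_that("calling is invariant to haplotype input order", {
  p3 <- study_haplotype_pool(d3)
  pairs <- utils::combn(which(p3$intron_length == 83), 2, simplify = FALSE)
  for (ij in pairs[1:10]) {
    c1 <- render_consensus(p3[ij[1], ], p3[ij[2], ])
    c2 <- render_consensus(p3[ij[2], ], p3[ij[1], ])
    expect_identical(c1$seq, c2$seq)
    for (cn in c(1532, 1534))
      expect_identical(call_codon_genotype(d3, c1, cn),
                       call_codon_genotype(d3, c2, cn))
  }
})

test_that("consensus-level round trip is exact for equal-length pairs", {
  for (spec in list(d2, d3)) {
    pool <- study_haplotype_pool(spec)
    idx <- seq_len(nrow(pool))
    pairs <- Filter(function(ij)
      pool$intron_length[ij[1]] == pool$intron_length[ij[2]],
      utils::combn(idx, 2, simplify = FALSE))
    for (ij in pairs) {
      cons <- render_consensus(pool[ij[1], ], pool[ij[2], ])
      for (cn in spec$kdr_codons) {
        g <- call_codon_genotype(spec, cons, cn)
        want <- format_genotype(pool[[paste0("res_", cn)]][ij[1]],
                                pool[[paste0("res_", cn)]][ij[2]],
                                unname(spec$wild_residues[as.character(cn)]))
        pos <- codon_positions(spec, cn)
        n_het_in_codon <- sum(!strsplit(cons$seq, "")[[1]][pos + 1] %in%
                                c("A", "C", "G", "T"))
        if (n_het_in_codon <= 1) {
          ## a single double peak per codon always calls unambiguously
          expect_equal(g$status, "called")
          expect_equal(g$genotype, want)
        } else if (g$status == "called") {
          ## multi-het codons may be ambiguous; when called, never wrong
          expect_equal(g$genotype, want)
        } else {
          expect_equal(g$status, "ambiguous")
        }
      }
    }
  }
})

test_that("absent amplicons yield missing calls for their codons", {
  p3 <- study_haplotype_pool(d3)
  cons <- render_consensus(p3[2, ], p3[2, ])
  rec <- call_individual(list(D2 = d2, D3 = d3), list(cons), "ind1", "P1")
  expect_equal(rec$status[rec$codon == 1016], "missing")
  expect_equal(rec$genotype[rec$codon == 1532], "I/I")
  expect_equal(rec$genotype[rec$codon == 1534], "F/F")
})

test_that("genotype tables round-trip through TSV", {
  sim <- cached_study_sim(40, seed = 5)
  gt <- call_genotypes(sim$config$specs, sim$consensus, sim$clones)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gt, path)
  back <- read_genotypes(path)
  expect_equal(back$genotype, gt$genotype)
  expect_equal(back$codon, gt$codon)
})
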