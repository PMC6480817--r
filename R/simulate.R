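## Ground-truthed synthetic amplicon data.
##
## The generator emulates the statistical structure of a multi-population
## kdr survey: per-amplicon haplotype pools with relative frequencies,
## Hardy-Weinberg random union of gametes within each population, diploid
## Sanger consensus reads (IUPAC merge; truncation at a heterozygous indel),
## and clone reads for individuals the direct trace cannot phase.

#' Describe one synthetic haplotype as edits to the reference
#'
#' @param label haplotype name (e.g. `"D2H07"`).
#' @param codons named character vector: codon number -> replacement 3-base
#'   codon (e.g. `c("1016" = "GGA")`).
#' @param snps named character vector: 0-based amplicon coordinate ->
#'   replacement base (applied in reference coordinates).
#' @param intron_del `c(offset, length)`: delete `length` bases starting at
#'   0-based offset inside the intron.
#' @param intron_snps named character vector: 0-based intron offset -> base.
#' @param intron full replacement string for the intron (overrides
#'   `intron_del` / `intron_snps`).
#' @return a variant description for [build_haplotype_pool()].
#' @export
hap_variant <- function(label, codons = NULL, snps = NULL, intron_del = NULL,
                        intron_snps = NULL, intron = NULL) {
  structure(list(label = label, codons = codons, snps = snps,
                 intron_del = intron_del, intron_snps = intron_snps,
                 intron = intron), class = "hap_variant")
}

build_one_haplotype <- function(spec, v) {
  s <- chars(spec$reference_seq)
  if (!is.null(v$codons)) {
    for (cn in names(v$codons)) {
      rep <- toupper(v$codons[[cn]])
      if (nchar(rep) != 3L || !is_acgt(rep))
        stopf("haplotype '%s': codon replacement '%s' malformed", v$label, rep)
      s[codon_positions(spec, cn) + 1L] <- chars(rep)
    }
  }
  if (!is.null(v$snps))
    s[as.integer(names(v$snps)) + 1L] <- toupper(unlist(v$snps))
  i0 <- spec$intron_interval[1]; i1 <- spec$intron_interval[2]
  intron <- s[(i0 + 1L):i1]
  if (!is.null(v$intron)) {
    intron <- chars(toupper(v$intron))
  } else {
    if (!is.null(v$intron_snps))
      intron[as.integer(names(v$intron_snps)) + 1L] <- toupper(unlist(v$intron_snps))
    if (!is.null(v$intron_del)) {
      off <- v$intron_del[1]; len <- v$intron_del[2]
      if (len > 0L) {
        if (off + len > length(intron))
          stopf("haplotype '%s': intron deletion outside intron", v$label)
        intron <- intron[-((off + 1L):(off + len))]
      }
    }
  }
  ## residues are intron-independent: the exon frame is untouched
  coding <- paste(s[spec$exon_pos + 1L], collapse = "")
  res <- vapply(spec$kdr_codons, function(cn) {
    off <- spec$codon_offsets[[as.character(cn)]]
    translate_codon(substr(coding, off + 1L, off + 3L))
  }, "")
  names(res) <- spec$kdr_codons
  seq <- paste(c(s[seq_len(i0)], intron, s[(i1 + 1L):length(s)]), collapse = "")
  list(label = v$label, seq = seq, intron_length = length(intron), residues = res)
}

#' Build a pool of distinct synthetic haplotypes
#'
#' Applies each variant description to the reference and annotates intron
#' length and kdr-codon residues. Duplicate sequences are rejected, as is
#' any domain III haplotype carrying both a 1532 and a 1534 mutation (such
#' double-mutant haplotypes were never observed and the generator refuses to
#' fabricate them).
#'
#' @param spec an [amplicon_spec()].
#' @param variants list of [hap_variant()] descriptions.
#' @return a `haplotype_pool` data frame: `label`, `amplicon`, `seq`,
#'   `intron_length`, and one `res_<codon>` column per kdr codon.
#' @export
build_haplotype_pool <- function(spec, variants) {
  built <- lapply(variants, function(v) build_one_haplotype(spec, v))
  seqs <- vapply(built, `[[`, "", "seq")
  labels <- vapply(built, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("build_haplotype_pool: duplicate labels")
  if (anyDuplicated(seqs))
    stopf("build_haplotype_pool: duplicate haplotype sequences (%s)",
          paste(labels[duplicated(seqs) | duplicated(seqs, fromLast = TRUE)],
                collapse = ", "))
  if (all(c(1532L, 1534L) %in% spec$kdr_codons)) {
    for (b in built) {
      if (b$residues[["1532"]] != wild_residue(spec, 1532) &&
          b$residues[["1534"]] != wild_residue(spec, 1534))
        stopf("haplotype '%s' carries both a 1532 and a 1534 mutation; no such haplotype is observed",
              b$label)
    }
  }
  pool <- data.frame(label = labels, amplicon = spec$name, seq = seqs,
                     intron_length = vapply(built, `[[`, 0L, "intron_length"),
                     stringsAsFactors = FALSE)
  for (cn in spec$kdr_codons)
    pool[[paste0("res_", cn)]] <- vapply(built, function(b)
      b$residues[[as.character(cn)]], "")
  class(pool) <- c("haplotype_pool", "data.frame")
  attr(pool, "spec_name") <- spec$name
  pool
}

## ---- study-shaped pools ---------------------------------------------------

## Intron lengths of the 17 D2 and 19 D3 haplotypes catalogued in the survey
## (D2 intron range 71-91 bp, D3 range 67-83 bp). Mutant haplotypes:
## D2H07 = 1016G (one step from wild D2H05), D2H10 = 1000Y, D3H01 = 1532T
## (one step from wild D3H08), D3H03/D3H13 = the two 1534S haplotypes
## (derived from different wild parents, differing in exon and intron),
## D3H12 = 1534L.
STUDY_D2_INTRONS <- c(82, 91, 88, 91, 89, 90, 89, 90, 91, 71, 90, 91, 91, 90, 91, 90, 82)
STUDY_D3_INTRONS <- c(68, 83, 83, 83, 83, 68, 83, 68, 83, 83, 70, 83, 68, 72, 68, 68, 68, 67, 83)

## (index of the defining wild background, codon edits) for mutant entries
STUDY_D2_MUTANTS <- list(`7` = list(base = 5L, codons = c(`1016` = "GGA")),
                         `10` = list(base = 10L, codons = c(`1000` = "TAC")))
STUDY_D3_MUTANTS <- list(`1` = list(base = 8L, codons = c(`1532` = "ACC")),
                         `3` = list(base = 4L, codons = c(`1534` = "TCC")),
                         `12` = list(base = 2L, codons = c(`1534` = "TTG")),
                         `13` = list(base = 6L, codons = c(`1534` = "TCC")))

#' Study-shaped haplotype pool for a built-in amplicon
#'
#' Emulates the catalogued haplotype diversity of the survey: 17 D2
#' haplotypes (intron 71-91 bp; one 1016G, one 1000Y) or 19 D3 haplotypes
#' (intron 67-83 bp; one 1532T, two independent 1534S, one 1534L). Each
#' background is made unique by intron tag substitutions; every third
#' background also carries a silent exon SNP, so haplotype diversity spans
#' both exon and intron as in the survey.
#'
#' @param spec [d2_amplicon()] or [d3_amplicon()].
#' @return a `haplotype_pool` data frame (see [build_haplotype_pool()]).
#' @export
study_haplotype_pool <- function(spec) {
  if (spec$name == "D2") {
    lens <- STUDY_D2_INTRONS; muts <- STUDY_D2_MUTANTS; silent_codon <- 995L
  } else if (spec$name == "D3") {
    lens <- STUDY_D3_INTRONS; muts <- STUDY_D3_MUTANTS; silent_codon <- 1495L
  } else stopf("study_haplotype_pool: no built-in pool for amplicon '%s'", spec$name)
  ref_intron_len <- spec$intron_interval[2] - spec$intron_interval[1]
  intron_ref <- chars(substr(spec$reference_seq, spec$intron_interval[1] + 1L,
                             spec$intron_interval[2]))
  tag_offsets <- c(4L, 6L, 8L)
  background <- function(i, len) {
    ## base-3 digits of (i-1) choose one of the three non-reference bases at
    ## each tag offset: backgrounds are pairwise distinct by construction
    digs <- c((i - 1L) %% 3L, ((i - 1L) %/% 3L) %% 3L, ((i - 1L) %/% 9L) %% 3L)
    tags <- vapply(seq_along(tag_offsets), function(k) {
      setdiff(IUPAC_BASES, intron_ref[tag_offsets[k] + 1L])[digs[k] + 1L]
    }, "")
    names(tags) <- tag_offsets
    snps <- NULL
    if (i %% 3L == 0L) {
      pos <- codon_positions(spec, silent_codon)
      alt <- synonymous_codon(ref_codon(spec, silent_codon))
      snps <- stats::setNames(chars(alt), pos)
      snps <- snps[chars(alt) != chars(ref_codon(spec, silent_codon))]
    }
    list(intron_snps = tags,
         intron_del = c(30L, ref_intron_len - len),
         snps = snps)
  }
  variants <- lapply(seq_along(lens), function(i) {
    key <- as.character(i)
    if (!is.null(muts[[key]])) {
      bg <- background(muts[[key]]$base, lens[i])
      hap_variant(sprintf("%sH%02d", spec$name, i), codons = muts[[key]]$codons,
                  snps = bg$snps, intron_del = bg$intron_del,
                  intron_snps = bg$intron_snps)
    } else {
      bg <- background(i, lens[i])
      hap_variant(sprintf("%sH%02d", spec$name, i), snps = bg$snps,
                  intron_del = bg$intron_del, intron_snps = bg$intron_snps)
    }
  })
  build_haplotype_pool(spec, variants)
}

## ---- configuration --------------------------------------------------------

#' Configure a synthetic survey
#'
#' @param populations named integer vector (population -> number of
#'   individuals) or a data frame with columns `name`, `n`.
#' @param specs list of [amplicon_spec()] objects, named by amplicon.
#' @param pools named list (amplicon -> `haplotype_pool`).
#' @param freqs either a named list (amplicon -> named frequency vector over
#'   pool labels), applied to every population, or a list keyed by
#'   population of such lists. Frequencies must sum to 1 per amplicon.
#' @param clone_range integer pair: range of clone reads sequenced per
#'   flagged individual (default 3-10, the documented range).
#' @param error_rate per-base substitution error applied to clone reads
#'   (default 0).
#' @param seed master seed; per-population streams are derived from it
#'   deterministically.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(populations, specs, pools, freqs,
                              clone_range = c(3L, 10L), error_rate = 0,
                              seed = 1L) {
  if (is.data.frame(populations))
    populations <- stats::setNames(as.integer(populations$n), populations$name)
  if (is.null(names(populations)) || any(populations < 1L))
    stopf("simulation_config: populations must be a named vector with n >= 1")
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "name")
  if (!setequal(names(pools), names(specs)))
    stopf("simulation_config: pools and specs must cover the same amplicons")
  per_pop <- !any(names(freqs) %in% names(specs))
  norm_freq <- function(fl) {
    for (amp in names(fl)) {
      f <- fl[[amp]]
      if (any(f < 0)) stopf("simulation_config: negative frequency")
      if (abs(sum(f) - 1) > 1e-9)
        stopf("simulation_config: frequencies for '%s' sum to %.12f, not 1", amp, sum(f))
      if (!all(names(f) %in% pools[[amp]]$label))
        stopf("simulation_config: unknown haplotype label in frequencies for '%s'", amp)
    }
    fl
  }
  freqs <- if (per_pop) lapply(freqs, norm_freq) else norm_freq(freqs)
  clone_range <- as.integer(clone_range)
  if (clone_range[1] < 2L || clone_range[2] > 50L || clone_range[1] > clone_range[2])
    stopf("simulation_config: clone_range must lie within [2, 50]")
  structure(list(populations = populations, specs = specs, pools = pools,
                 freqs = freqs, per_pop_freqs = per_pop,
                 clone_range = clone_range, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

pop_freqs <- function(config, pop) {
  if (config$per_pop_freqs) config$freqs[[pop]] else config$freqs
}

#' Study-shaped simulation configuration
#'
#' Populations and allele frequencies mirror the 17-site Beijing survey: the
#' bundled genotype-count table supplies each population's mutant allele
#' frequencies, which are assigned to the corresponding catalogued mutant
#' haplotypes (1016G -> D2H07; 1000Y -> D2H10, Tong Zhou only; 1532T ->
#' D3H01; 1534S -> D3H03 in Tong Zhou and D3H13 elsewhere; 1534L -> D3H12).
#' The wild remainder is spread over the wild backgrounds with geometrically
#' decaying weights.
#'
#' @param seed master seed.
#' @param n_total total individuals (default 426, the survey size); per-site
#'   sizes are scaled proportionally.
#' @param clone_range,error_rate see [simulation_config()].
#' @return a `simulation_config`.
#' @export
study_simulation_config <- function(seed = 1L, n_total = NULL,
                                    clone_range = c(3L, 10L), error_rate = 0) {
  specs <- list(D2 = d2_amplicon(), D3 = d3_amplicon())
  pools <- lapply(specs, study_haplotype_pool)
  fx <- load_paper_fixture()
  t2 <- fx$table2_wide
  ns <- stats::setNames(t2$n, t2$population)
  if (!is.null(n_total)) {
    if (n_total < length(ns))
      stopf("study_simulation_config: n_total must be at least %d (one per site)",
            length(ns))
    ## proportional allocation by largest remainder, one individual minimum
    raw <- ns * n_total / sum(ns)
    scaled <- pmax(floor(raw), 1)
    rem <- n_total - sum(scaled)
    ord <- order(raw - floor(raw), decreasing = TRUE)
    i <- 0L
    while (rem != 0L) {
      j <- ord[(i %% length(ord)) + 1L]
      if (rem > 0L) { scaled[j] <- scaled[j] + 1; rem <- rem - 1L }
      else if (scaled[j] > 1) { scaled[j] <- scaled[j] - 1; rem <- rem + 1L }
      i <- i + 1L
    }
    ns <- scaled
  }
  geom_w <- function(labels) {
    w <- 0.7^(seq_along(labels) - 1L)
    stats::setNames(w / sum(w), labels)
  }
  d2_wild <- setdiff(pools$D2$label, c("D2H07", "D2H10"))
  d3_wild <- setdiff(pools$D3$label, c("D3H01", "D3H03", "D3H12", "D3H13"))
  freqs <- lapply(t2$population, function(p) {
    r <- t2[t2$population == p, ]
    n2 <- 2 * r$n
    pG <- (r$VG + 2 * r$GG) / n2
    pY <- if (p == "TZ") 7 / n2 else 0
    pT <- (r$IT + 2 * r$TT) / n2
    pS <- (r$FS + 2 * r$SS) / n2
    pL <- r$FL / n2
    d2 <- c(stats::setNames(c(pG, pY), c("D2H07", "D2H10")),
            (1 - pG - pY) * geom_w(d2_wild))
    d3 <- c(stats::setNames(c(pT, if (p == "TZ") pS else 0,
                              if (p == "TZ") 0 else pS, pL),
                            c("D3H01", "D3H03", "D3H13", "D3H12")),
            (1 - pT - pS - pL) * geom_w(d3_wild))
    list(D2 = d2 / sum(d2), D3 = d3 / sum(d3))
  })
  names(freqs) <- t2$population
  simulation_config(populations = ns, specs = specs, pools = pools,
                    freqs = freqs, clone_range = clone_range,
                    error_rate = error_rate, seed = seed)
}

## ---- sampling -------------------------------------------------------------

#' Draw ground-truth individuals
#'
#' For each population, `n` diploid individuals are formed by random union of
#' gametes: the two haplotypes per amplicon are drawn i.i.d. from the pool
#' frequencies (Hardy-Weinberg within population). Reproducible under the
#' config's master seed via derived per-population streams.
#'
#' @param config a [simulation_config()].
#' @return an `individual_truth` data frame: `individual_id`, `population`,
#'   `hap1_<amp>`/`hap2_<amp>` label columns and `gt_<codon>` truth genotypes.
#' @export
sample_individuals <- function(config) {
  amps <- names(config$specs)
  out <- vector("list", length(config$populations))
  for (i in seq_along(config$populations)) {
    pop <- names(config$populations)[i]
    n <- config$populations[[i]]
    fl <- pop_freqs(config, pop)
    rec <- data.frame(individual_id = sprintf("%s_%04d", pop, seq_len(n)),
                      population = pop, stringsAsFactors = FALSE)
    local_seed(derive_seed(config$seed, i), {
      for (amp in amps) {
        pool <- config$pools[[amp]]
        if (!nrow(pool)) stopf("sample_individuals: empty pool for '%s'", amp)
        f <- fl[[amp]]
        draws <- sample(names(f), 2L * n, replace = TRUE, prob = f)
        rec[[paste0("hap1_", amp)]] <- draws[seq_len(n)]
        rec[[paste0("hap2_", amp)]] <- draws[n + seq_len(n)]
      }
    })
    out[[i]] <- rec
  }
  truth <- do.call(rbind, out)
  ## derive genotype truth from the haplotype pairs
  for (amp in amps) {
    spec <- config$specs[[amp]]
    pool <- config$pools[[amp]]
    for (cn in spec$kdr_codons) {
      col <- paste0("res_", cn)
      r1 <- pool[[col]][match(truth[[paste0("hap1_", amp)]], pool$label)]
      r2 <- pool[[col]][match(truth[[paste0("hap2_", amp)]], pool$label)]
      truth[[paste0("gt_", cn)]] <- format_genotype(r1, r2, wild_residue(spec, cn))
    }
  }
  class(truth) <- c("individual_truth", "data.frame")
  truth
}

#' Merge two haplotypes into a diploid Sanger consensus
#'
#' Equal-length haplotypes merge position-wise with IUPAC codes at
#' heterozygous sites. Haplotypes of unequal length (a heterozygous intron
#' indel) cannot be read past the indel in a direct trace: the consensus is
#' flagged `length_het` and carries only the shared 5' prefix up to the
#' first indel position.
#'
#' @param hapA,hapB haplotype records (rows of a `haplotype_pool`, or lists
#'   with `amplicon` and `seq`).
#' @return a `diploid_consensus`: list with `amplicon`, `seq`, `length_het`,
#'   `het_positions` (0-based), `n_het`.
#' @export
render_consensus <- function(hapA, hapB) {
  getf <- function(h, f) if (is.data.frame(h)) h[[f]][1] else h[[f]]
  ampA <- getf(hapA, "amplicon"); ampB <- getf(hapB, "amplicon")
  if (!is.null(ampA) && !is.null(ampB) && ampA != ampB)
    stopf("render_consensus: haplotypes from different amplicons (%s, %s)", ampA, ampB)
  sa <- toupper(getf(hapA, "seq")); sb <- toupper(getf(hapB, "seq"))
  if (nchar(sa) == nchar(sb)) {
    a <- chars(sa); b <- chars(sb)
    merged <- ifelse(a == b, a, iupac_merge(a, b))
    het <- which(a != b) - 1L
    cons <- list(amplicon = ampA, seq = paste(merged, collapse = ""),
                 length_het = FALSE, het_positions = het, n_het = length(het))
  } else {
    long <- if (nchar(sa) > nchar(sb)) sa else sb
    short <- if (nchar(sa) > nchar(sb)) sb else sa
    g <- best_single_gap(long, short)$start
    a <- chars(long)[seq_len(g)]; b <- chars(short)[seq_len(g)]
    merged <- if (g > 0L) ifelse(a == b, a, iupac_merge(a, b)) else character()
    het <- which(a != b) - 1L
    cons <- list(amplicon = ampA, seq = paste(merged, collapse = ""),
                 length_het = TRUE, het_positions = het, n_het = length(het))
  }
  structure(cons, class = "diploid_consensus")
}

#' Render clone reads of one individual's amplicon
#'
#' Each clone is a faithful copy of one of the two true haplotypes, chosen
#' uniformly at random (both haplotypes are present in the set with
#' probability `1 - 2 * 0.5^k` for a heterozygote). An optional uniform
#' per-base error substitutes bases independently.
#'
#' @param hapA,hapB the two true haplotype sequences (character).
#' @param k number of clones to sequence (>= 2).
#' @param seed RNG seed.
#' @param error_rate per-base substitution probability.
#' @param ensure_both when `TRUE`, emulate the completed laboratory
#'   protocol, in which cloning continues until both alleles of a
#'   heterozygote have been observed: if the uniform draw covers only one
#'   haplotype, the last read is replaced by the missing one.
#' @return character vector of `k` clone sequences.
#' @export
render_clones <- function(hapA, hapB, k, seed, error_rate = 0,
                          ensure_both = FALSE) {
  if (k < 2L) stopf("render_clones: at least 2 clones are required (k = %d)", k)
  local_seed(seed, {
    choice <- sample(1:2, k, replace = TRUE)
    if (ensure_both && hapA != hapB && length(unique(choice)) == 1L)
      choice[k] <- 3L - choice[1]
    reads <- c(hapA, hapB)[choice]
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        b <- chars(r)
        hit <- which(stats::runif(length(b)) < error_rate)
        for (j in hit) b[j] <- sample(setdiff(IUPAC_BASES, b[j]), 1L)
        paste(b, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    reads
  })
}

## ---- whole datasets -------------------------------------------------------

#' Simulate a complete survey dataset
#'
#' Draws individuals, renders diploid consensus reads for every individual
#' and amplicon, and renders clone reads for every individual the direct
#' trace cannot phase (two or more heterozygous sites, or a heterozygous
#' intron indel) - the clone path of the study.
#'
#' @param config a [simulation_config()].
#' @return a `kdr_simulation`: list with `truth`, `consensus` (data frame:
#'   `individual_id`, `population`, `amplicon`, `seq`, `length_het`,
#'   `n_het`), `clones` (data frame: `individual_id`, `amplicon`, `clone`,
#'   `seq`) and `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- sample_individuals(config)
  amps <- names(config$specs)
  cons_rows <- vector("list", nrow(truth) * length(amps))
  clone_rows <- list()
  idx <- 0L
  for (r in seq_len(nrow(truth))) {
    for (amp in amps) {
      idx <- idx + 1L
      pool <- config$pools[[amp]]
      h1 <- pool[match(truth[[paste0("hap1_", amp)]][r], pool$label), ]
      h2 <- pool[match(truth[[paste0("hap2_", amp)]][r], pool$label), ]
      cons <- render_consensus(h1, h2)
      cons_rows[[idx]] <- data.frame(
        individual_id = truth$individual_id[r], population = truth$population[r],
        amplicon = amp, seq = cons$seq, length_het = cons$length_het,
        n_het = cons$n_het, stringsAsFactors = FALSE)
      if (cons$length_het || cons$n_het >= 2L) {
        sd <- derive_seed(config$seed, 100000L + idx)
        k <- local_seed(sd, sample(config$clone_range[1]:config$clone_range[2], 1L))
        reads <- render_clones(h1$seq, h2$seq, k, derive_seed(sd, 1L),
                               config$error_rate, ensure_both = TRUE)
        clone_rows[[length(clone_rows) + 1L]] <- data.frame(
          individual_id = truth$individual_id[r], amplicon = amp,
          clone = seq_len(k), seq = reads, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(truth = truth,
                 consensus = do.call(rbind, cons_rows),
                 clones = if (length(clone_rows)) do.call(rbind, clone_rows)
                          else data.frame(individual_id = character(),
                                          amplicon = character(),
                                          clone = integer(), seq = character(),
                                          stringsAsFactors = FALSE),
                 config = config),
            class = "kdr_simulation")
}

#' Write / read a simulated dataset as FASTA + TSV
#'
#' Emits a consensus FASTA (record names `id|amplicon`, with a `|LH` suffix
#' on length-heterozygous truncated records), one clone FASTA per flagged
#' individual and amplicon, a sample sheet TSV and a truth TSV.
#'
#' @param sim a `kdr_simulation`.
#' @param dir output directory (created if needed).
#' @return `write_dataset()` returns the directory invisibly;
#'   `read_dataset()` returns a list with `consensus`, `clones`, `sheet`,
#'   `truth` mirroring the written dataset.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cons <- sim$consensus
  recs <- stats::setNames(cons$seq, paste0(cons$individual_id, "|", cons$amplicon,
                                           ifelse(cons$length_het, "|LH", "")))
  write_fasta(recs, file.path(dir, "consensus.fasta"))
  dir.create(file.path(dir, "clones"), showWarnings = FALSE)
  clone_file <- rep("", nrow(cons))
  if (nrow(sim$clones)) {
    key <- paste(sim$clones$individual_id, sim$clones$amplicon)
    for (k in unique(key)) {
      sub <- sim$clones[key == k, ]
      fn <- file.path("clones", sprintf("%s_%s.fasta", sub$individual_id[1], sub$amplicon[1]))
      write_fasta(stats::setNames(sub$seq, paste0(sub$individual_id, "|",
                                                  sub$amplicon, "|", sub$clone)),
                  file.path(dir, fn))
      clone_file[cons$individual_id == sub$individual_id[1] &
                 cons$amplicon == sub$amplicon[1]] <- fn
    }
  }
  sheet <- data.frame(individual_id = cons$individual_id,
                      population = cons$population, amplicon = cons$amplicon,
                      consensus_file = "consensus.fasta",
                      clone_file = clone_file, stringsAsFactors = FALSE)
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  sheet <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  recs <- read_fasta(file.path(dir, "consensus.fasta"))
  parts <- strsplit(names(recs), "|", fixed = TRUE)
  cons <- data.frame(individual_id = vapply(parts, `[[`, "", 1L),
                     amplicon = vapply(parts, `[[`, "", 2L),
                     seq = unname(recs),
                     length_het = vapply(parts, function(p) length(p) > 2L && p[3] == "LH", TRUE),
                     stringsAsFactors = FALSE)
  cons$population <- sheet$population[match(paste(cons$individual_id, cons$amplicon),
                                            paste(sheet$individual_id, sheet$amplicon))]
  cons$n_het <- vapply(cons$seq, function(s) sum(!chars(s) %in% IUPAC_BASES), 0L,
                       USE.NAMES = FALSE)
  clone_rows <- list()
  for (fn in unique(sheet$clone_file[sheet$clone_file != ""])) {
    cr <- read_fasta(file.path(dir, fn))
    p <- strsplit(names(cr), "|", fixed = TRUE)
    clone_rows[[length(clone_rows) + 1L]] <- data.frame(
      individual_id = vapply(p, `[[`, "", 1L), amplicon = vapply(p, `[[`, "", 2L),
      clone = as.integer(vapply(p, `[[`, "", 3L)), seq = unname(cr),
      stringsAsFactors = FALSE)
  }
  truth_path <- file.path(dir, "truth.tsv")
  list(consensus = cons,
       clones = if (length(clone_rows)) do.call(rbind, clone_rows)
                else data.frame(individual_id = character(), amplicon = character(),
                                clone = integer(), seq = character(),
                                stringsAsFactors = FALSE),
       sheet = sheet,
       truth = if (file.exists(truth_path))
         utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL)
}
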