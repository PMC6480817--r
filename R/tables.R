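## Population summaries: per-population genotype counts, allele frequencies
## and triple-locus genotype-combination types, mirroring the survey's
## reporting conventions (blank table cells are zeros; frequencies reported
## half-up to three decimals).

#' Wild-type residues at the kdr codons
#'
#' @return named character vector keyed by codon number.
#' @export
kdr_wild_residues <- function() {
  c(`989` = "S", `1000` = "S", `1011` = "I", `1016` = "V",
    `1532` = "I", `1534` = "F")
}

#' Diploid allele frequency from genotype counts
#'
#' The standard diploid count: `p = (n_het + 2 n_hom) / (2 n)`.
#'
#' @param n_het heterozygous carriers of the allele.
#' @param n_hom_mut homozygous carriers.
#' @param n individuals genotyped at the locus.
#' @return frequency in `[0, 1]` (exact; round for reporting with
#'   [round_half_up()]).
#' @export
#' @examples
#' allele_frequency(12, 5, 17)             # 0.6470588...
#' round_half_up(allele_frequency(12, 5, 17)) # 0.647
allele_frequency <- function(n_het, n_hom_mut, n) {
  if (any(n <= 0)) stopf("allele_frequency: n must be positive")
  if (any(n_het + n_hom_mut > n))
    stopf("allele_frequency: carriers exceed population size")
  (n_het + 2 * n_hom_mut) / (2 * n)
}

#' Tabulate genotype counts per population and locus
#'
#' @param records long-format genotype data frame (`individual_id`,
#'   `population`, `codon`, `genotype`, `status`); only `"called"` rows are
#'   counted, missing calls are tracked separately.
#' @return a `genotype_count_table`: long data frame `population`, `codon`,
#'   `genotype`, `count`, with attributes `n` (called individuals per
#'   population and codon) and `missing` (uncalled records per population
#'   and codon).
#' @export
build_genotype_count_table <- function(records) {
  called <- records[records$status == "called", , drop = FALSE]
  out <- if (nrow(called)) {
    agg <- stats::aggregate(list(count = called$individual_id),
                            by = list(population = called$population,
                                      codon = called$codon,
                                      genotype = called$genotype),
                            FUN = length)
    agg[order(agg$population, agg$codon, agg$genotype), , drop = FALSE]
  } else data.frame(population = character(), codon = integer(),
                    genotype = character(), count = integer(),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  miss <- records[records$status != "called", , drop = FALSE]
  n_tab <- if (nrow(called))
    stats::aggregate(list(n = called$individual_id),
                     by = list(population = called$population,
                               codon = called$codon), FUN = length)
  else data.frame(population = character(), codon = integer(), n = integer())
  structure(out, class = c("genotype_count_table", "data.frame"),
            n = n_tab,
            missing = if (nrow(miss))
              stats::aggregate(list(n_missing = miss$individual_id),
                               by = list(population = miss$population,
                                         codon = miss$codon), FUN = length)
            else NULL)
}

## genotype column order for wide rendering: wild homozygote first, then
## descending total count; ties put heterozygotes before homozygotes, then
## alphabetical (reproduces the published column order F/F, F/S, F/L, S/S)
order_genotypes <- function(genotypes, totals, wild) {
  wild_hom <- paste0(wild, "/", wild)
  is_hom <- vapply(strsplit(genotypes, "/", fixed = TRUE),
                  function(p) p[1] == p[2], TRUE)
  ord <- order(genotypes != wild_hom, -totals, is_hom, genotypes)
  genotypes[ord]
}

#' Render a genotype count table in the published wide shape
#'
#' One row per population plus a totals row; one column per observed
#' genotype, grouped by codon; absent cells are zeros.
#'
#' @param tbl a `genotype_count_table`.
#' @return data frame with `population`, `n`, then one column per
#'   `codon.genotype`.
#' @export
genotype_table_wide <- function(tbl) {
  pops <- unique(tbl$population)
  codons <- sort(unique(tbl$codon))
  wild <- kdr_wild_residues()
  n_pop <- vapply(pops, function(p)
    max(stats::aggregate(count ~ codon, data = tbl[tbl$population == p, , drop = FALSE],
                         FUN = sum)$count), 0)
  out <- data.frame(population = pops, n = as.integer(n_pop),
                    stringsAsFactors = FALSE)
  for (cn in codons) {
    sub <- tbl[tbl$codon == cn, , drop = FALSE]
    gts <- unique(sub$genotype)
    totals <- vapply(gts, function(g) sum(sub$count[sub$genotype == g]), 0)
    gts <- order_genotypes(gts, totals, wild[[as.character(cn)]])
    for (g in gts) {
      col <- paste0(cn, ".", g)
      out[[col]] <- vapply(pops, function(p)
        sum(sub$count[sub$population == p & sub$genotype == g]), 0)
    }
  }
  tot <- out[1, , drop = FALSE]
  tot$population <- "Total"
  for (j in 2:ncol(out)) tot[[j]] <- sum(out[[j]])
  rbind(out, tot)
}

#' Allele frequencies per population, locus and mutant allele
#'
#' Applies [allele_frequency()] to every mutant residue observed at each
#' locus; at a tri-allelic locus such as 1534 (F/S/L) each mutant allele is
#' tabulated separately.
#'
#' @param tbl a `genotype_count_table`.
#' @param include_total also emit pooled rows over all populations.
#' @return data frame: `population`, `codon`, `allele`, `n`, `n_het`,
#'   `n_hom`, `frequency` (exact) and `freq_3dp` (rounded half-up).
#' @export
allele_frequency_table <- function(tbl, include_total = FALSE) {
  wild <- kdr_wild_residues()
  pops <- unique(tbl$population)
  if (include_total) pops <- c(pops, "Total")
  rows <- list()
  for (cn in sort(unique(tbl$codon))) {
    w <- wild[[as.character(cn)]]
    sub <- tbl[tbl$codon == cn, , drop = FALSE]
    alleles <- setdiff(unique(unlist(strsplit(sub$genotype, "/", fixed = TRUE))), w)
    for (p in pops) {
      psub <- if (p == "Total") sub else sub[sub$population == p, , drop = FALSE]
      n <- sum(psub$count)
      if (n == 0) next
      for (al in alleles) {
        split_gt <- strsplit(psub$genotype, "/", fixed = TRUE)
        n_al <- vapply(split_gt, function(g) sum(g == al), 0L)
        n_het <- sum(psub$count[n_al == 1L])
        n_hom <- sum(psub$count[n_al == 2L])
        f <- allele_frequency(n_het, n_hom, n)
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, codon = cn, allele = al, n = n, n_het = n_het,
          n_hom = n_hom, frequency = f, freq_3dp = round_half_up(f, 3),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## wide per-individual view of the three combination loci
genotype_wide <- function(records, loci = c(1016L, 1532L, 1534L)) {
  sub <- records[records$codon %in% loci, , drop = FALSE]
  ids <- unique(sub[, c("individual_id", "population")])
  for (cn in loci) {
    csub <- sub[sub$codon == cn & sub$status == "called", , drop = FALSE]
    ids[[paste0("gt_", cn)]] <- csub$genotype[match(ids$individual_id,
                                                    csub$individual_id)]
  }
  ids
}

#' Classify triple-locus genotype combinations
#'
#' Every individual with called genotypes at codons 1016, 1532 and 1534 is
#' assigned a combination type. Type 1 is reserved for the triple-locus wild
#' homozygote (V/V, I/I, F/F); remaining types are numbered in
#' first-observation order unless a label map (signature -> type number,
#' e.g. the published ordering) is supplied. Individuals missing any of the
#' three calls are excluded and reported.
#'
#' @param records long-format genotype data frame.
#' @param label_map optional named integer vector mapping signatures like
#'   `"V/V|I/T|F/F"` to type numbers.
#' @return data frame: `individual_id`, `population`, `gt_1016`, `gt_1532`,
#'   `gt_1534`, `signature`, `type`; excluded individuals in attribute
#'   `excluded`.
#' @export
classify_combination <- function(records, label_map = NULL) {
  wide <- genotype_wide(records)
  ok <- stats::complete.cases(wide[, c("gt_1016", "gt_1532", "gt_1534")])
  excluded <- wide[!ok, , drop = FALSE]
  wide <- wide[ok, , drop = FALSE]
  wide$signature <- paste(wide$gt_1016, wide$gt_1532, wide$gt_1534, sep = "|")
  wild_sig <- "V/V|I/I|F/F"
  if (is.null(label_map)) {
    sigs <- unique(wide$signature)
    sigs <- c(intersect(wild_sig, sigs), setdiff(sigs, wild_sig))
    label_map <- stats::setNames(seq_along(sigs), sigs)
    if (!wild_sig %in% names(label_map))
      label_map <- label_map + 1L  # keep Type 1 reserved for the wild triple
  }
  wide$type <- unname(label_map[wide$signature])
  if (anyNA(wide$type))
    stopf("classify_combination: signature(s) missing from label map: %s",
          paste(unique(wide$signature[is.na(wide$type)]), collapse = ", "))
  structure(wide, excluded = excluded)
}

#' Per-population frequencies of combination types
#'
#' @param records long-format genotype data frame.
#' @param label_map optional signature -> type map (see
#'   [classify_combination()]).
#' @return data frame: `population`, `type`, `signature`, `count`, `n`,
#'   `frequency`, `freq_3dp`; attributes `n_types` (distinct types overall)
#'   and `types_per_population`.
#' @export
combination_frequency_table <- function(records, label_map = NULL) {
  cls <- classify_combination(records, label_map)
  pops <- unique(cls$population)
  rows <- list()
  for (p in pops) {
    sub <- cls[cls$population == p, , drop = FALSE]
    n <- nrow(sub)
    for (ty in sort(unique(sub$type))) {
      cnt <- sum(sub$type == ty)
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, type = ty,
        signature = sub$signature[match(ty, sub$type)], count = cnt, n = n,
        frequency = cnt / n, freq_3dp = round_half_up(cnt / n, 3),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_types = length(unique(cls$type)),
            types_per_population = vapply(pops, function(p)
              length(unique(cls$type[cls$population == p])), 0L))
}

#' Individuals carrying at least one copy of a mutant allele
#'
#' @param records long-format genotype data frame.
#' @param codon locus.
#' @param residue mutant one-letter residue.
#' @return integer count of carrier individuals (het + hom).
#' @export
carrier_count <- function(records, codon, residue) {
  sub <- records[records$codon == codon & records$status == "called", , drop = FALSE]
  carriers <- vapply(strsplit(sub$genotype, "/", fixed = TRUE),
                     function(g) residue %in% g, TRUE)
  length(unique(sub$individual_id[carriers]))
}

#' Populations in which an allele was detected
#'
#' @param records long-format genotype data frame.
#' @param codon locus.
#' @param residue allele residue.
#' @return list with `count`, `present`, `absent`.
#' @export
populations_with_allele <- function(records, codon, residue) {
  sub <- records[records$codon == codon & records$status == "called", , drop = FALSE]
  carriers <- vapply(strsplit(sub$genotype, "/", fixed = TRUE),
                     function(g) residue %in% g, TRUE)
  present <- unique(sub$population[carriers])
  all_pops <- unique(sub$population)
  list(count = length(present), present = present,
       absent = setdiff(all_pops, present))
}
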