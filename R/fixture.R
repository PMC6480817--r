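## Published-table fixtures.
##
## The package bundles plain-text transcriptions of the survey's
## per-population genotype counts (grouped by codons 1016/1532/1534) and
## triple-locus combination frequencies. The loader reconstructs
## individual-level records from the combination frequencies and verifies
## them, with zero tolerance, against the genotype-count marginals - the two
## tables are internally consistent, so any transcription slip fails loudly.

#' Path to a bundled fixture file
#'
#' @param which `"table2"` (genotype counts) or `"table3"` (combination
#'   frequencies).
#' @return file path within the installed package.
#' @export
kdr_fixture_path <- function(which = c("table2", "table3")) {
  which <- match.arg(which)
  fn <- switch(which,
               table2 = "table2_genotype_counts.tsv",
               table3 = "table3_combination_freqs.tsv")
  path <- system.file("extdata", fn, package = "kdrhap")
  if (path == "") stopf("bundled fixture '%s' not found", fn)
  path
}

GENOTYPE_COLS <- list(
  `1016` = c(VV = "V/V", VG = "V/G", GG = "G/G"),
  `1532` = c(II = "I/I", IT = "I/T", TT = "T/T"),
  `1534` = c(FF = "F/F", FS = "F/S", FL = "F/L", SS = "S/S"))

#' Load the published-table fixture
#'
#' Reads the genotype-count and combination-frequency transcriptions,
#' reconstructs per-individual records (per population and type,
#' `count = round(frequency * n)` half-up) and checks the reconstruction:
#' type counts must sum to `n` in every population and the per-locus
#' marginals must equal the genotype-count table exactly.
#'
#' @param counts_path,freqs_path TSV paths; default to the bundled files.
#' @return a `paper_fixture`: list with `table2_wide` (as transcribed),
#'   `table2` (a `genotype_count_table`), `table3` (long frequencies),
#'   `records` (reconstructed long-format genotype records), `label_map`
#'   (signature -> published type number) and `n` (per-population sizes).
#' @export
load_paper_fixture <- function(counts_path = NULL, freqs_path = NULL) {
  if (is.null(counts_path)) counts_path <- kdr_fixture_path("table2")
  if (is.null(freqs_path)) freqs_path <- kdr_fixture_path("table3")
  t2 <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
  t3 <- utils::read.delim(freqs_path, stringsAsFactors = FALSE)

  ## row sums per locus must reproduce n
  for (cn in names(GENOTYPE_COLS)) {
    cols <- names(GENOTYPE_COLS[[cn]])
    bad <- rowSums(t2[, cols, drop = FALSE]) != t2$n
    if (any(bad))
      stopf("fixture: genotype counts at codon %s do not sum to n for %s",
            cn, paste(t2$population[bad], collapse = ", "))
  }

  pops <- setdiff(names(t3), c("type", "gt_1016", "gt_1532", "gt_1534"))
  if (!setequal(pops, t2$population))
    stopf("fixture: population sets of the two tables differ")
  label_map <- stats::setNames(as.integer(t3$type),
                               paste(t3$gt_1016, t3$gt_1532, t3$gt_1534, sep = "|"))

  ## reconstruct individuals
  rec_rows <- list()
  t3_long <- list()
  for (p in t2$population) {
    n <- t2$n[t2$population == p]
    counts <- as.integer(round_half_up(t3[[p]] * n, 0))
    if (sum(counts) != n)
      stopf("fixture: reconstructed type counts for %s sum to %d, not n = %d",
            p, sum(counts), n)
    k <- 0L
    for (i in which(counts > 0L)) {
      t3_long[[length(t3_long) + 1L]] <- data.frame(
        population = p, type = t3$type[i], frequency = t3[[p]][i],
        count = counts[i], n = n, stringsAsFactors = FALSE)
      for (j in seq_len(counts[i])) {
        k <- k + 1L
        id <- sprintf("%s_%03d", p, k)
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          individual_id = id, population = p, codon = c(1016L, 1532L, 1534L),
          genotype = c(t3$gt_1016[i], t3$gt_1532[i], t3$gt_1534[i]),
          status = "called", stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL

  ## marginal cross-check against the genotype-count table (tolerance 0)
  for (cn in names(GENOTYPE_COLS)) {
    gmap <- GENOTYPE_COLS[[cn]]
    sub <- records[records$codon == as.integer(cn), , drop = FALSE]
    for (p in t2$population) {
      for (col in names(gmap)) {
        got <- sum(sub$population == p & sub$genotype == gmap[[col]])
        want <- t2[t2$population == p, col]
        if (got != want)
          stopf("fixture: reconstructed %s count at codon %s in %s is %d, table says %d",
                gmap[[col]], cn, p, got, want)
      }
    }
  }

  structure(list(table2_wide = t2,
                 table2 = build_genotype_count_table(records),
                 table3 = do.call(rbind, t3_long),
                 records = records,
                 label_map = label_map,
                 n = stats::setNames(t2$n, t2$population)),
            class = "paper_fixture")
}
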