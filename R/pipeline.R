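## End-to-end pipeline driver.
##
## Chains the modules the way the survey analysis was run: simulate (or
## load) amplicon data, call genotypes, phase haplotypes, tabulate
## populations, and build TN93 trees. Every run writes a manifest recording
## the seed and input digests; reruns with identical inputs and seed are
## byte-identical.

pipeline_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

#' Run the kdr analysis pipeline
#'
#' @param subcommand one of `"simulate"`, `"genotype"`, `"phase"`,
#'   `"tabulate"`, `"tree"`, `"all"`.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for every stochastic step.
#' @param n_total individuals to simulate (`simulate` / `all`).
#' @param data_dir directory holding a written dataset (`genotype`,
#'   `phase`, `all` on pre-existing data).
#' @param genotypes_path genotype TSV (`tabulate`).
#' @param fixture use the bundled published-table fixture instead of a
#'   genotype TSV (`tabulate`).
#' @param fasta_path haplotype FASTA (`tree`); sequences are anchored to
#'   `amplicon` before distance computation.
#' @param amplicon `"D2"` or `"D3"` (`tree`).
#' @param bootstrap bootstrap replicates for `tree` (0 disables supports).
#' @param verbose log progress to stderr.
#' @return invisibly, a list with `status` (0 on success), `outputs`
#'   (paths written) and `manifest`.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "genotype", "phase",
                                        "tabulate", "tree"),
                         out_dir, seed = 1L, n_total = 100L, data_dir = NULL,
                         genotypes_path = NULL, fixture = FALSE,
                         fasta_path = NULL, amplicon = "D2", bootstrap = 100L,
                         verbose = FALSE) {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))
  outputs <- character(0)
  specs <- list(D2 = d2_amplicon(), D3 = d3_amplicon())

  sim <- NULL
  dataset <- NULL
  if (subcommand %in% c("simulate", "all") && is.null(data_dir)) {
    log("simulating %d individuals (seed %d)", n_total, seed)
    cfg <- study_simulation_config(seed = seed, n_total = n_total)
    sim <- simulate_dataset(cfg)
    ddir <- file.path(out_dir, "dataset")
    write_dataset(sim, ddir)
    outputs <- c(outputs, ddir)
    dataset <- list(consensus = sim$consensus, clones = sim$clones,
                    truth = sim$truth)
  } else if (!is.null(data_dir)) {
    dataset <- read_dataset(data_dir)
  }

  genotypes <- NULL
  if (subcommand %in% c("genotype", "all")) {
    if (is.null(dataset)) stopf("run_pipeline: no dataset to genotype")
    log("calling genotypes")
    genotypes <- call_genotypes(specs, dataset$consensus, dataset$clones)
    outputs <- c(outputs, write_genotypes(genotypes,
                                          file.path(out_dir, "genotypes.tsv")))
  }

  catalogs <- NULL
  if (subcommand %in% c("phase", "all")) {
    if (is.null(dataset)) stopf("run_pipeline: no dataset to phase")
    log("phasing haplotypes")
    phased <- phase_individuals(dataset$consensus, dataset$clones)
    outputs <- c(outputs, pipeline_tsv(phased, file.path(out_dir, "phased.tsv")))
    catalogs <- lapply(specs, function(sp) build_catalog(phased, sp))
    for (amp in names(catalogs)) {
      cat_df <- catalogs[[amp]]
      outputs <- c(outputs,
                   pipeline_tsv(as.data.frame(cat_df),
                                file.path(out_dir, sprintf("catalog_%s.tsv", amp))))
      if (nrow(cat_df))
        outputs <- c(outputs, write_fasta(stats::setNames(cat_df$seq, cat_df$name),
                                          file.path(out_dir, sprintf("haplotypes_%s.fasta", amp))))
      nw <- nearest_wild_neighbors(cat_df)
      if (nrow(nw))
        outputs <- c(outputs, pipeline_tsv(nw,
                                           file.path(out_dir, sprintf("origins_%s.tsv", amp))))
    }
  }

  if (subcommand %in% c("tabulate", "all")) {
    if (fixture) {
      fx <- load_paper_fixture()
      records <- fx$records
      label_map <- fx$label_map
    } else {
      if (is.null(genotypes) && !is.null(genotypes_path))
        genotypes <- read_genotypes(genotypes_path)
      if (is.null(genotypes)) stopf("run_pipeline: no genotypes to tabulate")
      records <- genotypes
      label_map <- NULL
    }
    log("tabulating populations")
    tbl <- build_genotype_count_table(records)
    outputs <- c(outputs,
                 pipeline_tsv(genotype_table_wide(tbl),
                              file.path(out_dir, "genotype_counts.tsv")),
                 pipeline_tsv(allele_frequency_table(tbl),
                              file.path(out_dir, "allele_frequencies.tsv")))
    if (all(c(1016L, 1532L, 1534L) %in% records$codon))
      outputs <- c(outputs,
                   pipeline_tsv(combination_frequency_table(records, label_map),
                                file.path(out_dir, "combination_types.tsv")))
  }

  if (subcommand %in% c("tree", "all")) {
    spec <- specs[[amplicon]]
    seqs <- if (!is.null(fasta_path)) read_fasta(fasta_path)
            else if (!is.null(catalogs) && nrow(catalogs[[amplicon]]))
              stats::setNames(catalogs[[amplicon]]$seq, catalogs[[amplicon]]$name)
            else NULL
    if (is.null(seqs)) stopf("run_pipeline: no haplotype sequences for the tree")
    if (length(seqs) >= 3L) {
      log("building TN93 tree on %d haplotypes", length(seqs))
      aln <- align_to_reference(spec, seqs)
      dm <- tn93_distance_matrix(aln)
      if (any(!is.finite(dm))) {
        warnf("run_pipeline: capping saturated distances for tree building")
        dm[!is.finite(dm)] <- max(dm[is.finite(dm)]) * 2
      }
      tree <- if (bootstrap > 0L) bootstrap_support(aln, B = bootstrap, seed = seed)
              else nj_tree(dm)
      nwk <- file.path(out_dir, sprintf("tree_%s.nwk", amplicon))
      write_newick(tree, nwk)
      dm_df <- data.frame(taxon = rownames(dm), dm, check.names = FALSE)
      outputs <- c(outputs, nwk,
                   pipeline_tsv(dm_df, file.path(out_dir,
                                                 sprintf("distances_%s.tsv", amplicon))))
    } else log("fewer than 3 haplotypes; skipping tree")
  }

  manifest <- list(
    package = "kdrhap",
    version = as.character(utils::packageVersion("kdrhap")),
    subcommand = subcommand, seed = seed,
    inputs = Filter(Negate(is.null),
                    list(data_dir = data_dir, genotypes = genotypes_path,
                         fasta = fasta_path)),
    input_digests = {
      files <- Filter(function(f) !is.null(f) && file.exists(f),
                      list(genotypes_path, fasta_path))
      if (length(files)) as.list(tools::md5sum(unlist(files))) else list()
    },
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, outputs = outputs, manifest = manifest))
}
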