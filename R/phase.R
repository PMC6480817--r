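## Rule-based haplotype identification.
##
## Haplotypes are clarified exactly as in the survey protocol: read directly
## from homozygotes; split the two alleles of a heterozygote carrying a
## single-site variation; and clone-sequence heterozygotes with multiple-site
## variations, cross-checking the clone haplotypes against the direct
## consensus. A heterozygous intron indel makes the direct trace unreadable
## past the indel, so such individuals are phase-eligible only via clones.

#' Phase a consensus directly (homozygote / one-site rule)
#'
#' @param consensus a `diploid_consensus`.
#' @param individual_id,amplicon optional identifiers copied into the result.
#' @return a `phase_result`: list with `individual_id`, `amplicon`, `status`
#'   (`"resolved"`, `"unresolved_requires_clones"` or `"inconsistent"`),
#'   `haplotypes` (character pair when resolved) and `method`.
#' @export
phase_direct <- function(consensus, individual_id = NA_character_,
                         amplicon = NULL) {
  amp <- if (!is.null(amplicon)) amplicon else consensus$amplicon
  res <- function(status, haps = NULL, method = "direct")
    structure(list(individual_id = individual_id, amplicon = amp,
                   status = status, haplotypes = haps, method = method),
              class = "phase_result")
  if (isTRUE(consensus$length_het))
    return(res("unresolved_requires_clones"))
  het <- which(!chars(consensus$seq) %in% IUPAC_BASES)
  if (length(het) == 0L)
    return(res("resolved", c(consensus$seq, consensus$seq), "direct_homozygote"))
  if (length(het) == 1L) {
    pair <- iupac_split(substr(consensus$seq, het, het))
    h <- c(consensus$seq, consensus$seq)
    substr(h[1], het, het) <- pair[1]
    substr(h[2], het, het) <- pair[2]
    return(res("resolved", h, "direct_split"))
  }
  res("unresolved_requires_clones")
}

#' Phase a heterozygote with clone reads
#'
#' Clone sequences are deduplicated and every candidate pair of distinct (or
#' identical) clone haplotypes is re-merged as a diploid consensus; the pair
#' whose merge reproduces the observed consensus at all readable positions
#' (the truncated 5' prefix for length-heterozygous individuals) is the
#' resolution. Zero consistent pairs, or several consistent pairs among more
#' than two distinct clone sequences, are surfaced as `"inconsistent"` for
#' manual review - never silently resolved.
#'
#' @param consensus a `diploid_consensus`.
#' @param clones character vector of clone sequences, or a data frame with
#'   columns `individual_id`, `seq` (ids are then checked).
#' @param individual_id optional identifier.
#' @return a `phase_result` (see [phase_direct()]).
#' @export
phase_with_clones <- function(consensus, clones, individual_id = NA_character_) {
  if (is.data.frame(clones)) {
    if (!is.na(individual_id) && any(clones$individual_id != individual_id))
      stopf("phase_with_clones: clone reads from a different individual")
    clones <- clones$seq
  }
  if (length(clones) < 2L)
    stopf("phase_with_clones: at least 2 clone reads are required")
  res <- function(status, haps = NULL)
    structure(list(individual_id = individual_id, amplicon = consensus$amplicon,
                   status = status, haplotypes = haps, method = "clones"),
              class = "phase_result")
  uniq <- unique(toupper(clones))
  idx <- if (length(uniq) >= 2L) utils::combn(length(uniq), 2, simplify = FALSE)
         else list()
  cand <- c(lapply(seq_along(uniq), function(i) c(uniq[i], uniq[i])),
            lapply(idx, function(ij) uniq[ij]))
  consistent <- Filter(function(p) {
    m <- render_consensus(list(amplicon = consensus$amplicon, seq = p[1]),
                          list(amplicon = consensus$amplicon, seq = p[2]))
    identical(m$seq, consensus$seq) &&
      identical(m$length_het, isTRUE(consensus$length_het))
  }, cand)
  if (length(consistent) == 1L) return(res("resolved", consistent[[1]]))
  res("inconsistent")
}

#' Phase every individual in a dataset
#'
#' Applies the direct rules first and falls back to clone cross-checking for
#' individuals with multiple heterozygous sites or a heterozygous indel.
#'
#' @param consensus consensus data frame (`individual_id`, `population`,
#'   `amplicon`, `seq`, `length_het`).
#' @param clones clone data frame (`individual_id`, `amplicon`, `seq`), may
#'   be `NULL`.
#' @return data frame: `individual_id`, `population`, `amplicon`, `status`,
#'   `method`, `hap1`, `hap2`.
#' @export
phase_individuals <- function(consensus, clones = NULL) {
  rows <- vector("list", nrow(consensus))
  for (r in seq_len(nrow(consensus))) {
    cons <- structure(list(amplicon = consensus$amplicon[r],
                           seq = consensus$seq[r],
                           length_het = isTRUE(consensus$length_het[r])),
                      class = "diploid_consensus")
    pr <- phase_direct(cons, consensus$individual_id[r])
    if (pr$status == "unresolved_requires_clones" && !is.null(clones)) {
      cl <- clones$seq[clones$individual_id == consensus$individual_id[r] &
                       clones$amplicon == consensus$amplicon[r]]
      if (length(cl) >= 2L)
        pr <- phase_with_clones(cons, cl, consensus$individual_id[r])
    }
    rows[[r]] <- data.frame(
      individual_id = consensus$individual_id[r],
      population = if ("population" %in% names(consensus))
        consensus$population[r] else NA_character_,
      amplicon = consensus$amplicon[r], status = pr$status, method = pr$method,
      hap1 = if (pr$status == "resolved") pr$haplotypes[1] else NA_character_,
      hap2 = if (pr$status == "resolved") pr$haplotypes[2] else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the haplotype catalog from phase results
#'
#' Unique resolved haplotype sequences are named `D2H01`, `D2H02`, ... in
#' first-observation order (the order of phased individuals, first allele
#' before second), annotated with intron length and kdr-codon residues, and
#' tallied over carrying chromosomes: counts sum to twice the number of
#' fully phased individuals.
#'
#' @param phase_df output of [phase_individuals()] (or any data frame with
#'   `amplicon`, `hap1`, `hap2`, `status`).
#' @param spec the [amplicon_spec()] whose amplicon is catalogued.
#' @return a `haplotype_catalog` data frame: `name`, `amplicon`, `seq`,
#'   `intron_length`, `res_<codon>` columns, `count`.
#' @export
build_catalog <- function(phase_df, spec) {
  sub <- phase_df[phase_df$amplicon == spec$name & phase_df$status == "resolved", ,
                  drop = FALSE]
  chrom <- as.vector(rbind(sub$hap1, sub$hap2))  # hap1/hap2 interleaved, row order
  uniq <- unique(chrom)
  ref_intron_len <- spec$intron_interval[2] - spec$intron_interval[1]
  rows <- lapply(seq_along(uniq), function(i) {
    s <- uniq[i]
    m <- anchor_align(spec, s)
    il <- ref_intron_len +
      if (is.null(m$gap)) 0L
      else if (m$gap$kind == "deletion") -m$gap$length else m$gap$length
    res <- vapply(spec$kdr_codons, function(cn)
      haplotype_residue(spec, s, cn, m), "")
    out <- data.frame(name = sprintf("%sH%02d", spec$name, i),
                      amplicon = spec$name, seq = s, intron_length = il,
                      stringsAsFactors = FALSE)
    for (k in seq_along(spec$kdr_codons))
      out[[paste0("res_", spec$kdr_codons[k])]] <- res[k]
    out$count <- sum(chrom == s)
    out
  })
  cat_df <- if (length(rows)) do.call(rbind, rows) else {
    out <- data.frame(name = character(), amplicon = character(),
                      seq = character(), intron_length = integer(),
                      stringsAsFactors = FALSE)
    for (cn in spec$kdr_codons) out[[paste0("res_", cn)]] <- character()
    out$count <- integer()
    out
  }
  class(cat_df) <- c("haplotype_catalog", "data.frame")
  attr(cat_df, "spec_name") <- spec$name
  attr(cat_df, "wild_residues") <- spec$wild_residues
  attr(cat_df, "kdr_codons") <- spec$kdr_codons
  cat_df
}

#' Write a haplotype catalog as TSV
#'
#' @param catalog a `haplotype_catalog`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
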