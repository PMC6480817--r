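## Haplotype-origin inference.
##
## Whether a resistance allele arose once or several times is read from the
## haplotype catalog: each mutant haplotype is compared against every wild
## haplotype, and a mutant one nucleotide step away from a wild background
## plausibly derives from it. Two haplotypes carrying the same resistance
## residue but sitting on distant backgrounds with different nearest wild
## neighbours are candidates for independent origins.

#' Nucleotide differences between two haplotypes
#'
#' Equal-length sequences are compared position-wise; unequal lengths are
#' aligned with a single gap (placed at maximal flanking identity, leftmost
#' on ties) and the indel is reported as one gap event, so intron-length
#' variation counts as a single mutational step.
#'
#' @param hapA,hapB gapless sequences (character).
#' @return data frame with one row per difference: `position` (0-based, in
#'   the longer sequence's coordinates), `a`, `b` (bases, or `-` / the
#'   inserted segment for the gap event). Zero rows iff the sequences are
#'   identical.
#' @export
pairwise_differences <- function(hapA, hapB) {
  a <- toupper(hapA); b <- toupper(hapB)
  empty <- data.frame(position = integer(), a = character(), b = character(),
                      stringsAsFactors = FALSE)
  if (nchar(a) == nchar(b)) {
    ca <- chars(a); cb <- chars(b)
    d <- which(ca != cb)
    if (!length(d)) return(empty)
    return(data.frame(position = d - 1L, a = ca[d], b = cb[d],
                      stringsAsFactors = FALSE))
  }
  swap <- nchar(a) < nchar(b)
  long <- if (swap) b else a
  short <- if (swap) a else b
  g <- best_single_gap(long, short)
  cl <- chars(long); cs <- chars(short)
  ins <- paste(cl[(g$start + 1L):(g$start + g$length)], collapse = "")
  ## aligned: long[1..g] ~ short[1..g]; long[g+d+1..] ~ short[g+1..]
  head_d <- if (g$start > 0L) which(cl[seq_len(g$start)] != cs[seq_len(g$start)]) else integer()
  n_tail <- length(cs) - g$start
  tail_d <- if (n_tail > 0L)
    which(cl[(g$start + g$length + 1L):length(cl)] != cs[(g$start + 1L):length(cs)])
  else integer()
  rows <- data.frame(
    position = c(head_d - 1L, g$start, g$start + g$length + tail_d - 1L),
    a = c(cl[head_d], ins, cl[g$start + g$length + tail_d]),
    b = c(cs[head_d], "-", cs[g$start + tail_d]),
    stringsAsFactors = FALSE)
  rows <- rows[order(rows$position), , drop = FALSE]
  if (swap) rows[, c("a", "b")] <- rows[, c("b", "a")]
  rownames(rows) <- NULL
  rows
}

## difference count (gap event = 1)
n_differences <- function(hapA, hapB) nrow(pairwise_differences(hapA, hapB))

catalog_is_mutant <- function(catalog) {
  wild <- attr(catalog, "wild_residues")
  codons <- attr(catalog, "kdr_codons")
  if (is.null(wild) || is.null(codons))
    stopf("catalog lacks wild-residue annotation; build it with build_catalog()")
  Reduce(`|`, lapply(as.character(codons), function(cn)
    catalog[[paste0("res_", cn)]] != wild[[cn]]))
}

#' Nearest wild neighbours of each mutant haplotype
#'
#' For every mutant haplotype in the catalog (any kdr residue differing from
#' wild type) the wild haplotypes at minimal nucleotide difference are
#' reported, ties included. A mutant at distance 1 from a wild background
#' plausibly derives from it through one mutational step.
#'
#' @param catalog a `haplotype_catalog` from [build_catalog()].
#' @return data frame: `mutant`, `distance`, `wild` (comma-separated names
#'   of all wild haplotypes at that minimal distance). Zero rows when the
#'   catalog has no mutants.
#' @export
nearest_wild_neighbors <- function(catalog) {
  empty <- data.frame(mutant = character(), distance = integer(),
                      wild = character(), stringsAsFactors = FALSE)
  if (!nrow(catalog)) return(empty)
  mut <- catalog_is_mutant(catalog)
  if (!any(mut) || all(mut)) return(empty)
  wild_df <- catalog[!mut, , drop = FALSE]
  out <- lapply(which(mut), function(i) {
    d <- vapply(wild_df$seq, function(w) n_differences(catalog$seq[i], w), 0L)
    dmin <- min(d)
    data.frame(mutant = catalog$name[i], distance = dmin,
               wild = paste(wild_df$name[d == dmin], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag mutant haplotype pairs as independent-origin candidates
#'
#' Two haplotypes carrying the same mutant residue at the same codon, yet
#' separated by at least `min_mutual_distance` nucleotide differences and
#' derived from disjoint sets of nearest wild neighbours, are unlikely to
#' descend from a single mutational event and are flagged as candidates for
#' independent origins.
#'
#' @param catalog a `haplotype_catalog`.
#' @param min_mutual_distance minimal mutual difference count (default 3,
#'   i.e. more than the 1-2 steps seen within a shared origin).
#' @return data frame: `codon`, `residue`, `hap1`, `hap2`,
#'   `mutual_distance`, `wild1`, `wild2`.
#' @export
independent_origin_candidates <- function(catalog, min_mutual_distance = 3L) {
  empty <- data.frame(codon = integer(), residue = character(),
                      hap1 = character(), hap2 = character(),
                      mutual_distance = integer(), wild1 = character(),
                      wild2 = character(), stringsAsFactors = FALSE)
  nw <- nearest_wild_neighbors(catalog)
  if (!nrow(nw)) return(empty)
  wild <- attr(catalog, "wild_residues")
  rows <- list()
  for (cn in as.character(attr(catalog, "kdr_codons"))) {
    res <- catalog[[paste0("res_", cn)]]
    for (rmut in setdiff(unique(res), wild[[cn]])) {
      carriers <- which(res == rmut)
      if (length(carriers) < 2L) next
      for (p in utils::combn(carriers, 2, simplify = FALSE)) {
        d <- n_differences(catalog$seq[p[1]], catalog$seq[p[2]])
        w1 <- strsplit(nw$wild[nw$mutant == catalog$name[p[1]]], ",")[[1]]
        w2 <- strsplit(nw$wild[nw$mutant == catalog$name[p[2]]], ",")[[1]]
        if (d >= min_mutual_distance && !length(intersect(w1, w2)))
          rows[[length(rows) + 1L]] <- data.frame(
            codon = as.integer(cn), residue = rmut,
            hap1 = catalog$name[p[1]], hap2 = catalog$name[p[2]],
            mutual_distance = d,
            wild1 = paste(w1, collapse = ","), wild2 = paste(w2, collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
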