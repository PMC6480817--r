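## Diploid genotype calling from IUPAC consensus sequences.
##
## A direct Sanger read of a diploid template shows heterozygous sites as
## double peaks (two-allele IUPAC codes). Genotypes are called per codon by
## anchoring the consensus to the amplicon reference, extracting the three
## mapped symbols and exhaustively enumerating every consistent decomposition
## of the ambiguity codes into two alleles: if all decompositions agree on
## one unordered amino-acid pair the call is made, otherwise the locus is
## reported ambiguous. No assumption about phase within a codon is needed.

#' Format an unordered amino-acid pair as a genotype string
#'
#' Wild-type residue first (matching the conventional `V/V`, `V/G`, `G/G`
#' column headings), mutant pairs alphabetical.
#'
#' @param r1,r2 one-letter residues (vectorised).
#' @param wild the wild-type residue at the locus.
#' @return character vector like `"V/G"`.
#' @export
format_genotype <- function(r1, r2, wild) {
  mapply(function(a, b) {
    pair <- c(a, b)
    pair <- pair[order(pair != wild, pair)]
    paste(pair, collapse = "/")
  }, r1, r2, USE.NAMES = FALSE)
}

#' Call the diploid genotype at one kdr codon
#'
#' @param spec an [amplicon_spec()].
#' @param consensus a `diploid_consensus` (see [render_consensus()]), or a
#'   plain consensus string (assumed not length-heterozygous).
#' @param codon_number codon to call.
#' @param map optional precomputed [anchor_align()] mapping (ignored for
#'   length-heterozygous consensus records, which are read as a 5' prefix in
#'   reference coordinates).
#' @return a `locus_genotype`: list with `codon_number`, `amino_pair`
#'   (sorted pair or `NA`), `genotype` (formatted string or `NA`),
#'   `codon_pair`, `status` (`"called"`, `"ambiguous"` or `"missing"`) and
#'   `flag` (non-empty on three/four-allele evidence).
#' @details Degenerate data never raises an error: a gap, a truncated or
#'   absent position, or a non-two-allele symbol yields status `"missing"`;
#'   decompositions that disagree on the amino-acid pair yield
#'   `"ambiguous"`.
#' @export
call_codon_genotype <- function(spec, consensus, codon_number, map = NULL) {
  if (is.character(consensus))
    consensus <- structure(list(amplicon = spec$name, seq = toupper(consensus),
                                length_het = FALSE), class = "diploid_consensus")
  pos <- codon_positions(spec, codon_number)
  miss <- function(flag = "") list(codon_number = codon_number,
                                   amino_pair = NA_character_,
                                   genotype = NA_character_,
                                   codon_pair = NA_character_,
                                   status = "missing", flag = flag)
  s <- chars(consensus$seq)
  if (isTRUE(consensus$length_het)) {
    ## truncated trace: readable 5' prefix; positions at or beyond the
    ## intron are not trustworthy in reference coordinates
    if (any(pos >= spec$intron_interval[1]) || any(pos >= length(s)))
      return(miss())
    sym <- s[pos + 1L]
  } else {
    if (is.null(map)) map <- anchor_align(spec, consensus$seq)
    cpos <- map$map[pos + 1L]
    if (any(is.na(cpos))) return(miss())
    sym <- s[cpos + 1L]
  }
  if (any(!sym %in% IUPAC_CODES))
    return(miss(flag = "non_iupac_symbol"))
  alleles <- lapply(sym, iupac_split)
  het <- vapply(alleles, function(p) p[1] != p[2], TRUE)
  ## enumerate orientations of the heterozygous positions (<= 8)
  orients <- expand.grid(rep(list(1:2), sum(het)))
  if (!nrow(orients)) orients <- data.frame(row.names = 1)
  pairs <- unique(t(apply(orients, 1, function(o) {
    pick <- integer(3); pick[!het] <- 1L; pick[het] <- as.integer(o)
    c1 <- paste(mapply(function(a, k) a[k], alleles, pick), collapse = "")
    c2 <- paste(mapply(function(a, k) a[3L - k], alleles, pick), collapse = "")
    sort(c(c1, c2))
  })))
  aminos <- unique(t(apply(pairs, 1, function(p)
    sort(c(translate_codon(p[1]), translate_codon(p[2]))))))
  if (nrow(aminos) != 1L)
    return(list(codon_number = codon_number, amino_pair = NA_character_,
                genotype = NA_character_, codon_pair = NA_character_,
                status = "ambiguous", flag = ""))
  amino_pair <- as.character(aminos[1, ])
  list(codon_number = codon_number,
       amino_pair = amino_pair,
       genotype = format_genotype(amino_pair[1], amino_pair[2],
                                  wild_residue(spec, codon_number)),
       codon_pair = if (nrow(pairs) == 1L) as.character(pairs[1, ]) else NA_character_,
       status = "called", flag = "")
}

#' Call all kdr codons for one individual
#'
#' @param specs list of [amplicon_spec()] objects.
#' @param consensus_list list of `diploid_consensus` records for this
#'   individual (one per available amplicon; absent amplicons yield missing
#'   calls).
#' @param individual_id,population identifiers copied into the output.
#' @return long-format data frame: `individual_id`, `population`,
#'   `amplicon`, `codon`, `genotype`, `status`, `flag`.
#' @export
call_individual <- function(specs, consensus_list, individual_id = NA_character_,
                            population = NA_character_) {
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "name")
  amps_have <- vapply(consensus_list, `[[`, "", "amplicon")
  rows <- list()
  for (amp in names(specs)) {
    spec <- specs[[amp]]
    idx <- match(amp, amps_have)
    cons <- if (is.na(idx)) NULL else consensus_list[[idx]]
    map <- NULL
    if (!is.null(cons) && !isTRUE(cons$length_het))
      map <- tryCatch(anchor_align(spec, cons$seq), error = function(e) NULL)
    for (cn in spec$kdr_codons) {
      g <- if (is.null(cons) || (!isTRUE(cons$length_het) && is.null(map)))
        list(codon_number = cn, genotype = NA_character_, status = "missing", flag = "")
      else call_codon_genotype(spec, cons, cn, map)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = individual_id, population = population, amplicon = amp,
        codon = as.integer(cn), genotype = g$genotype, status = g$status,
        flag = g$flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Call genotypes for a whole dataset
#'
#' The dataset-level caller: ordinary consensus records are called directly;
#' length-heterozygous individuals (whose trace is unreadable past the
#' intron indel) are resolved through their clone reads when available, as
#' in the study's clone-sequencing path, and the genotype is then read off
#' the two resolved haplotypes.
#'
#' @param specs list of [amplicon_spec()] objects.
#' @param consensus consensus data frame (`individual_id`, `population`,
#'   `amplicon`, `seq`, `length_het`), e.g. from [simulate_dataset()].
#' @param clones optional clone data frame (`individual_id`, `amplicon`,
#'   `seq`).
#' @return long-format genotype data frame as in [call_individual()].
#' @export
call_genotypes <- function(specs, consensus, clones = NULL) {
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "name")
  rows <- vector("list", nrow(consensus))
  for (r in seq_len(nrow(consensus))) {
    amp <- consensus$amplicon[r]
    spec <- specs[[amp]]
    if (is.null(spec)) next
    cons <- structure(list(amplicon = amp, seq = consensus$seq[r],
                           length_het = isTRUE(consensus$length_het[r])),
                      class = "diploid_consensus")
    clone_phase <- local({
      phased <- NULL; tried <- FALSE
      function() {
        if (!tried) {
          tried <<- TRUE
          if (!is.null(clones)) {
            cl <- clones$seq[clones$individual_id == consensus$individual_id[r] &
                             clones$amplicon == amp]
            if (length(cl) >= 2L) {
              pr <- phase_with_clones(cons, cl)
              if (pr$status == "resolved") phased <<- pr$haplotypes
            }
          }
        }
        phased
      }
    })
    calls <- lapply(spec$kdr_codons, function(cn) {
      g <- call_codon_genotype(spec, cons, cn)
      if (g$status != "called") {
        ## codons the direct trace cannot settle (unreadable past an intron
        ## indel, or ambiguous multi-het codons) go down the clone path
        phased <- clone_phase()
        if (!is.null(phased)) {
          res <- vapply(phased, function(h) haplotype_residue(spec, h, cn), "")
          if (!anyNA(res))
            g <- list(genotype = format_genotype(res[1], res[2],
                                                 wild_residue(spec, cn)),
                      status = "called", flag = "")
        }
      }
      g[c("genotype", "status", "flag")]
    })
    rows[[r]] <- data.frame(
      individual_id = consensus$individual_id[r],
      population = consensus$population[r], amplicon = amp,
      codon = spec$kdr_codons,
      genotype = vapply(calls, `[[`, "", "genotype"),
      status = vapply(calls, `[[`, "", "status"),
      flag = vapply(calls, `[[`, "", "flag"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Residue of a gapless haplotype at a codon, via anchored alignment.
haplotype_residue <- function(spec, hapseq, codon_number, map = NULL) {
  if (is.null(map)) map <- anchor_align(spec, hapseq)
  pos <- map$map[codon_positions(spec, codon_number) + 1L]
  if (any(is.na(pos))) return(NA_character_)
  translate_codon(paste(chars(hapseq)[pos + 1L], collapse = ""))
}

#' Write / read a genotype table as TSV
#'
#' Column order is fixed: `individual_id`, `population`, `amplicon`,
#' `codon`, `genotype`, `status`, `flag`.
#'
#' @param genotypes long-format genotype data frame.
#' @param path file path.
#' @return `read_genotypes()` returns the data frame; `write_genotypes()`
#'   the path, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  cols <- c("individual_id", "population", "amplicon", "codon", "genotype",
            "status", "flag")
  utils::write.table(genotypes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(codon = "integer"))
}
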