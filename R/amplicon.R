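## Amplicon reference model.
##
## Each PCR fragment of the VGSC gene is described by a reference haplotype,
## its exon/intron structure and a codon map translating community (Musca
## domestica) codon numbers into amplicon coordinates. All coordinates are
## 0-based half-open throughout the package; codon numbers follow the
## community numbering (e.g. V1016G).

#' Build a validated amplicon reference model
#'
#' Defines the coordinate system of one VGSC amplicon: a gapless reference
#' haplotype, ordered exon intervals, a single intron, and a codon map
#' anchored by one `(codon number, spliced offset)` pair. The codon map is
#' populated for every complete codon in the splice-joined exon region, so a
#' codon number like 1016 resolves to three amplicon coordinates.
#'
#' @param name amplicon identifier (e.g. `"D2"`).
#' @param reference_seq gapless A/C/G/T reference haplotype (the designated
#'   wild type for this amplicon).
#' @param exon_intervals list of `c(start, end)` 0-based half-open intervals.
#' @param intron_interval single `c(start, end)` interval; exactly one intron
#'   per amplicon.
#' @param codon_anchor `c(codon_number, exon_offset)`: the anchor codon and
#'   the 0-based offset of its first base within the splice-joined exon
#'   region. The offset must be a multiple of 3 (the spliced region is read
#'   in frame from its first base).
#' @param primer_pair optional character vector of length 2, stored as
#'   metadata.
#' @param kdr_codons codon numbers of interest for genotyping; defaults to
#'   the resistance-associated codons covered by this amplicon.
#' @return an object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, reference_seq, exon_intervals, intron_interval,
                          codon_anchor, primer_pair = NULL, kdr_codons = NULL) {
  reference_seq <- toupper(reference_seq)
  if (!is_acgt(reference_seq))
    stopf("amplicon_spec: reference_seq must be gapless A/C/G/T")
  L <- nchar(reference_seq)
  if (is.matrix(exon_intervals))
    exon_intervals <- lapply(seq_len(nrow(exon_intervals)),
                             function(i) exon_intervals[i, ])
  ivs <- c(exon_intervals, list(intron_interval))
  for (iv in ivs)
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > L || iv[1] >= iv[2])
      stopf("amplicon_spec: malformed interval [%s)", paste(iv, collapse = ","))
  ## disjoint and jointly covering [0, L)
  cov <- integer(L)
  for (iv in ivs) cov[(iv[1] + 1L):iv[2]] <- cov[(iv[1] + 1L):iv[2]] + 1L
  if (any(cov > 1L)) stopf("amplicon_spec: overlapping intervals")
  if (any(cov == 0L)) stopf("amplicon_spec: intervals do not tile the sequence")

  intron <- substr(reference_seq, intron_interval[1] + 1L, intron_interval[2])
  if (substr(intron, 1, 2) != "GT" || substr(intron, nchar(intron) - 1L, nchar(intron)) != "AG")
    warnf("amplicon_spec('%s'): intron boundaries are not GT...AG", name)

  ## spliced coordinate frame: amplicon positions of exon bases, in order
  exon_pos <- unlist(lapply(exon_intervals, function(iv) seq.int(iv[1], iv[2] - 1L)))
  exon_pos <- sort(exon_pos)
  n_spliced <- length(exon_pos)

  anchor_num <- as.integer(codon_anchor[1])
  anchor_off <- as.integer(codon_anchor[2])
  if (anchor_off %% 3L != 0L)
    stopf("amplicon_spec: anchor exon_offset must be in frame (multiple of 3)")
  if (anchor_off < 0L || anchor_off + 3L > n_spliced)
    stopf("amplicon_spec: anchor codon not fully inside the exon region")

  n_codons <- n_spliced %/% 3L
  first_codon <- anchor_num - anchor_off %/% 3L
  codon_numbers <- first_codon + seq_len(n_codons) - 1L
  codon_map <- lapply(seq_len(n_codons), function(k)
    exon_pos[(3L * (k - 1L) + 1L):(3L * k)])
  names(codon_map) <- codon_numbers
  codon_offsets <- stats::setNames(3L * (seq_len(n_codons) - 1L), codon_numbers)

  if (is.null(kdr_codons))
    kdr_codons <- intersect(c(1000L, 1016L, 1532L, 1534L), codon_numbers)

  spec <- structure(list(
    name = name,
    reference_seq = reference_seq,
    exon_intervals = exon_intervals,
    intron_interval = intron_interval,
    codon_map = codon_map,
    codon_offsets = codon_offsets,
    exon_pos = exon_pos,
    spliced_length = n_spliced,
    primer_pair = primer_pair,
    kdr_codons = as.integer(kdr_codons)
  ), class = "amplicon_spec")
  spec$wild_residues <- vapply(spec$kdr_codons, function(cn)
    translate_codon(ref_codon(spec, cn)), "")
  names(spec$wild_residues) <- spec$kdr_codons
  spec
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("Amplicon '%s': %d bp, %d exon bases (spliced), intron [%d,%d) (%d bp)\n",
              x$name, nchar(x$reference_seq), x$spliced_length,
              x$intron_interval[1], x$intron_interval[2],
              x$intron_interval[2] - x$intron_interval[1]))
  cat(sprintf("  codons %s..%s; kdr codons: %s\n",
              names(x$codon_map)[1], names(x$codon_map)[length(x$codon_map)],
              paste(x$kdr_codons, collapse = ", ")))
  invisible(x)
}

#' Splice an amplicon-aligned sequence to its coding region
#'
#' Concatenates the exon positions of a sequence laid out in amplicon
#' coordinates, dropping gap symbols (`-`). Intron-length variants aligned to
#' the reference therefore splice to the same-frame coding string.
#'
#' @param spec an [amplicon_spec()].
#' @param seq character string with one symbol per reference coordinate
#'   (`-` allowed).
#' @return the spliced coding string.
#' @export
splice_amplicon <- function(spec, seq) {
  if (nchar(seq) != nchar(spec$reference_seq))
    stopf("splice_amplicon: sequence length %d does not match reference length %d",
          nchar(seq), nchar(spec$reference_seq))
  s <- chars(toupper(seq))[spec$exon_pos + 1L]
  paste(s[s != "-"], collapse = "")
}

#' Amplicon coordinates of a codon
#'
#' @param spec an [amplicon_spec()].
#' @param codon_number community (Musca domestica) codon number.
#' @return integer vector of the three 0-based amplicon coordinates.
#' @export
codon_positions <- function(spec, codon_number) {
  key <- as.character(codon_number)
  pos <- spec$codon_map[[key]]
  if (is.null(pos))
    stopf("codon %s is not covered by amplicon '%s'", key, spec$name)
  as.integer(pos)
}

ref_codon <- function(spec, codon_number) {
  pos <- codon_positions(spec, codon_number)
  paste(chars(spec$reference_seq)[pos + 1L], collapse = "")
}

#' Translate an unambiguous codon
#'
#' Standard genetic code lookup; ambiguity codes and wrong lengths are
#' rejected (diploid codons are handled by [call_codon_genotype()], which
#' enumerates their decompositions before translation).
#'
#' @param codon 3-base A/C/G/T string.
#' @return one-letter amino acid (`*` for stop).
#' @export
#' @examples
#' translate_codon("GTA") # "V"
#' translate_codon("GGA") # "G"
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !is_acgt(codon))
    stopf("translate_codon: '%s' is not an unambiguous 3-base codon", codon)
  unname(Biostrings::GENETIC_CODE[codon])
}

## Wild-type residue at a codon of interest.
wild_residue <- function(spec, codon_number) {
  r <- spec$wild_residues[as.character(codon_number)]
  if (is.na(r)) r <- translate_codon(ref_codon(spec, codon_number))
  unname(r)
}

## Find a synonymous alternative codon (used to plant silent exon SNPs in
## synthetic haplotypes). Prefers third-position changes.
synonymous_codon <- function(codon) {
  aa <- translate_codon(codon)
  for (b in setdiff(IUPAC_BASES, substr(codon, 3, 3))) {
    alt <- paste0(substr(codon, 1, 2), b)
    if (translate_codon(alt) == aa) return(alt)
  }
  all_codons <- names(Biostrings::GENETIC_CODE)
  alt <- setdiff(all_codons[Biostrings::GENETIC_CODE == aa], codon)
  if (!length(alt)) stopf("codon %s has no synonymous alternative", codon)
  alt[1]
}

## ---- built-in amplicons ---------------------------------------------------

## Synthetic reference haplotypes with the documented structure of the two
## VGSC fragments (not database downloads): D2 = partial exon 20 + full
## 91-bp intron 20 + partial exon 21, spliced exon region 230 bp; D3 =
## partial exon 28 + full 83-bp intron 28 + partial exon 29, spliced coding
## region 246 bp. Intron defaults are the longest documented length variants.
D2_REFERENCE <- "TCGATTGTTTCGCCAAGTTAAATAAAAGTAACGTCCCCTCCACCCGGTTCAATTACCTTTTCAGTAATCTGGAACCCTGTTGTACCTAACTAGCAATACGCAGTTGAGGAGTTAAGATGATGTTGGCCACTCTGGAGGTACGGACCGAATGATTATATCATTTTGAGGGATATCCACTTAGCTCCAACATCGCCACGTCAGACTTCGGAAAAACTTAAGGTGGCTGTCAGCAGTCCAAATCTATTCCTACAAGTGGTGATATTCAAGCCGTATAGTTGAGTAAAACATGGATCAAAAAGGAATCCGTGCCGATAAGACTAA"

D3_REFERENCE <- "TCTTTCATTGAGTTGCTTGAAGGTATAGTTGTAGTGCTATAACTTGATAATAACTTTGAACTGAATACCATTCATCACGCGTTTTGAAACTTTATTCATCGTCGTACAGTTCAACGGTTACTAAACAAGTAGACAGGTGTAAGGAATAAAGCTTAGTTTTTAATGGGATATTGACAGCTCCAGAGTGTAACAAACAGCTTAGCTAGGATATCCTTTTCATTTTCCGAAAATCCCCCGTACCAACAGGGCTGAGCACGCCAACTGGTTGTTTCTGGGAATCAAGTCCTACGAATGATAATTACATAAAAGGCAAACCCTCTGACTGGATA"

#' Built-in domain II amplicon (D2)
#'
#' Partial exon 20 + full intron 20 (91 bp in the reference) + partial
#' exon 21; the spliced exon region is 230 bp and covers codons 989, 1000,
#' 1011 and 1016 (wild type S, S, I, V). The reference haplotype is a
#' synthetic stand-in with this documented structure.
#'
#' @return an [amplicon_spec()].
#' @export
d2_amplicon <- function() {
  amplicon_spec(
    name = "D2",
    reference_seq = D2_REFERENCE,
    exon_intervals = list(c(0L, 110L), c(201L, 321L)),
    intron_interval = c(110L, 201L),
    codon_anchor = c(989L, 0L),
    primer_pair = c(V2F = "GACAATGTGGATCGCTTCCC", V2R = "GCAATCTGGCTTGTTAACTTG"),
    kdr_codons = c(1000L, 1016L)
  )
}

#' Built-in domain III amplicon (D3)
#'
#' Partial exon 28 + full intron 28 (83 bp in the reference) + partial
#' exon 29; the spliced coding region is 246 bp, with codons 1532 and 1534
#' (wild type I and F) in exon 29, downstream of the intron. The reference
#' haplotype is a synthetic stand-in with this documented structure.
#'
#' @return an [amplicon_spec()].
#' @export
d3_amplicon <- function() {
  amplicon_spec(
    name = "D3",
    reference_seq = D3_REFERENCE,
    exon_intervals = list(c(0L, 100L), c(183L, 329L)),
    intron_interval = c(100L, 183L),
    codon_anchor = c(1490L, 0L),
    primer_pair = c(V3F = "GAGAACTCGCCGATGAACTT", V3R = "TAGCTTTCAGCGGCTTCTTC"),
    kdr_codons = c(1532L, 1534L)
  )
}

#' Serialise / read an amplicon spec as JSON
#'
#' @param spec an [amplicon_spec()].
#' @param path file path.
#' @return `read_amplicon_spec()` returns an [amplicon_spec()];
#'   `write_amplicon_spec()` returns `path` invisibly.
#' @export
write_amplicon_spec <- function(spec, path) {
  doc <- list(
    name = spec$name,
    reference_seq = spec$reference_seq,
    exon_intervals = lapply(spec$exon_intervals, as.integer),
    intron_interval = as.integer(spec$intron_interval),
    codon_anchor = c(as.integer(names(spec$codon_offsets)[1]), 0L),
    primer_pair = spec$primer_pair,
    kdr_codons = spec$kdr_codons
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_amplicon_spec
#' @export
read_amplicon_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  amplicon_spec(
    name = doc$name,
    reference_seq = doc$reference_seq,
    exon_intervals = if (is.matrix(doc$exon_intervals)) doc$exon_intervals
                     else lapply(doc$exon_intervals, as.integer),
    intron_interval = as.integer(doc$intron_interval),
    codon_anchor = as.integer(doc$codon_anchor),
    primer_pair = doc$primer_pair,
    kdr_codons = doc$kdr_codons
  )
}
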