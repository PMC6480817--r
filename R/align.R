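## Anchored single-gap alignment.
##
## The amplicons are fixed-locus fragments whose only structural variation is
## the length of their single intron, so a general-purpose multiple aligner
## is unnecessary: a consensus (or haplotype) is anchored to the reference
## exactly, and any length difference is absorbed as one contiguous gap
## placed inside the intron at the position of maximal flanking identity
## (ties broken leftmost).

#' Anchor a sequence to an amplicon reference
#'
#' Builds a monotone coordinate mapping from a consensus (IUPAC codes
#' allowed) or haplotype sequence onto the amplicon reference. Equal lengths
#' map one-to-one; a shorter sequence gets a single deletion gap inside the
#' intron; a longer one a single insertion. Exon positions always map
#' one-to-one.
#'
#' @param spec an [amplicon_spec()].
#' @param seq sequence over A/C/G/T plus two-allele IUPAC codes.
#' @param min_identity minimum fraction of exon positions compatible with the
#'   reference (an IUPAC code is compatible when one of its alleles matches);
#'   below this the sequence is rejected as the wrong amplicon.
#' @return an object of class `anchor_map`: a list with `map` (for each
#'   0-based reference coordinate, the 0-based sequence coordinate or `NA`
#'   inside a deletion), `gap` (`NULL` or `list(kind, start, length)` in
#'   reference coordinates), and `exon_identity`.
#' @export
anchor_align <- function(spec, seq, min_identity = 0.8) {
  seq <- toupper(seq)
  ref <- chars(spec$reference_seq)
  s <- chars(seq)
  ## three/four-allele symbols (mixed template) are tolerated here - they
  ## simply never match - and are flagged downstream by the caller
  if (any(!s %in% c(IUPAC_CODES, "B", "D", "H", "V", "N")))
    stopf("anchor_align: sequence contains non-IUPAC symbols")
  Lr <- length(ref); Ls <- length(s)
  if (abs(Ls - Lr) > 30L)
    stopf("anchor_align: length difference %d exceeds the supported +/-30", Ls - Lr)
  i0 <- spec$intron_interval[1]; i1 <- spec$intron_interval[2]

  score_map <- function(map) {
    ok <- !is.na(map)
    sum(iupac_compat_fast(s[map[ok] + 1L], ref[ok]))
  }

  if (Ls == Lr) {
    map <- seq.int(0L, Lr - 1L)
    gap <- NULL
  } else if (Ls < Lr) {
    d <- Lr - Ls
    if (d > i1 - i0)
      stopf("anchor_align: length deficit %d is not attributable to the intron", d)
    starts <- seq.int(i0, i1 - d)
    best <- NULL; best_score <- -1L
    for (g in starts) {
      map <- c(seq_len(g) - 1L, rep(NA_integer_, d),
               seq.int(g, Ls - 1L))
      sc <- score_map(map)
      if (sc > best_score) { best_score <- sc; best <- map; best_g <- g }
    }
    map <- best
    gap <- list(kind = "deletion", start = best_g, length = d)
  } else {
    d <- Ls - Lr
    starts <- seq.int(i0, i1)  # insertion point in reference coordinates
    best <- NULL; best_score <- -1L
    for (g in starts) {
      map <- c(seq_len(g) - 1L, seq.int(g + d, Ls - 1L))
      sc <- score_map(map)
      if (sc > best_score) { best_score <- sc; best <- map; best_g <- g }
    }
    map <- best
    gap <- list(kind = "insertion", start = best_g, length = d)
  }

  exon_idx <- spec$exon_pos + 1L
  emap <- map[exon_idx]
  ok <- !is.na(emap)
  exon_identity <- sum(iupac_compat_fast(s[emap[ok] + 1L],
                                         ref[exon_idx][ok])) / length(exon_idx)
  if (exon_identity < min_identity)
    stopf("anchor_align: exon identity %.2f below %.2f - wrong amplicon or species?",
          exon_identity, min_identity)
  structure(list(map = map, gap = gap, exon_identity = exon_identity,
                 seq_length = Ls), class = "anchor_map")
}

## Lay `seq` out in reference coordinates ('-' inside deletions). Inserted
## bases (longer-than-reference sequences) are dropped.
aligned_to_reference <- function(spec, seq, map = NULL) {
  if (is.null(map)) map <- anchor_align(spec, seq)
  s <- chars(toupper(seq))
  out <- rep("-", nchar(spec$reference_seq))
  ok <- !is.na(map$map)
  out[ok] <- s[map$map[ok] + 1L]
  paste(out, collapse = "")
}

#' Align haplotype sequences onto a common reference frame
#'
#' Anchors every sequence to the amplicon reference and returns equal-length
#' rows (deletions as `-`), suitable as input to the distance and likelihood
#' functions. Insertions relative to the reference are dropped with a
#' warning.
#'
#' @param spec an [amplicon_spec()].
#' @param seqs named character vector of gapless haplotype sequences.
#' @return named character vector of equal-length aligned sequences.
#' @export
align_to_reference <- function(spec, seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("align_to_reference: sequences must carry unique names")
  out <- vapply(seqs, function(x) {
    m <- anchor_align(spec, x)
    if (!is.null(m$gap) && m$gap$kind == "insertion")
      warnf("align_to_reference: insertion relative to reference dropped")
    aligned_to_reference(spec, x, m)
  }, "")
  names(out) <- names(seqs)
  out
}

## Generic best single-gap placement between two sequences of unequal
## length; used where no reference frame applies (consensus rendering,
## pairwise haplotype comparison). Returns list(start, length, matches):
## `start` is the 0-based position in the LONGER sequence where the extra
## bases sit. Ties go leftmost.
best_single_gap <- function(long, short) {
  a <- chars(long); b <- chars(short)
  d <- length(a) - length(b)
  stopifnot(d > 0L)
  n <- length(b)
  ## prefix[i]: matches among first i positions aligned head-to-head
  pm <- cumsum(a[seq_len(n)] == b)
  sm <- rev(cumsum(rev(a[(d + 1L):length(a)] == b)))
  best_g <- 0L; best_score <- -1L
  for (g in 0L:n) {
    sc <- (if (g > 0L) pm[g] else 0L) + (if (g < n) sm[g + 1L] else 0L)
    if (sc > best_score) { best_score <- sc; best_g <- g }
  }
  list(start = best_g, length = d, matches = best_score)
}
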