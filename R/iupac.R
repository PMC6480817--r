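## Two-allele IUPAC nucleotide ambiguity codes. A diploid Sanger trace shows
## a heterozygous site as two superimposed peaks, conventionally written as
## the code covering both bases. Only the six two-allele codes (plus the
## four plain bases) are representable; three- and four-allele codes signal
## mixed template and are rejected upstream.

IUPAC_BASES <- c("A", "C", "G", "T")

IUPAC_SPLIT <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

IUPAC_CODES <- names(IUPAC_SPLIT)

## pair key ("AG") -> code, both orders present
IUPAC_MERGE_LOOKUP <- local({
  codes <- vapply(IUPAC_SPLIT, function(p) paste0(p[1], p[2]), "")
  out <- c(stats::setNames(names(codes), codes),
           stats::setNames(names(codes), vapply(IUPAC_SPLIT, function(p)
             paste0(p[2], p[1]), "")))
  out
})

#' Merge two bases into an IUPAC code
#'
#' Position-wise merge of two allele bases into the diploid consensus symbol:
#' identical bases map to themselves, any unordered pair of distinct bases to
#' the corresponding two-allele ambiguity code (e.g. G + T -> K).
#'
#' @param a,b character vectors of single bases (A/C/G/T), recycled to a
#'   common length.
#' @return character vector of IUPAC codes.
#' @seealso [iupac_split()]
#' @export
#' @examples
#' iupac_merge("G", "T")                 # "K"
#' iupac_merge(c("A", "C"), c("A", "T")) # "A" "Y"
iupac_merge <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(a), n); b <- rep_len(toupper(b), n)
  bad <- !(a %in% IUPAC_BASES) | !(b %in% IUPAC_BASES)
  if (any(bad)) stopf("iupac_merge: inputs must be plain A/C/G/T bases")
  unname(IUPAC_MERGE_LOOKUP[paste0(a, b)])
}

#' Split an IUPAC code into its base pair
#'
#' Inverse of [iupac_merge()]: returns the unordered pair of bases encoded by
#' a (possibly ambiguous) consensus symbol. Plain bases return two copies of
#' themselves, so `iupac_split()` always describes a diploid site.
#'
#' @param code single character: one of A,C,G,T,R,Y,S,W,K,M.
#' @return character vector of length 2 (sorted).
#' @export
#' @examples
#' iupac_split("Y") # "C" "T"
#' iupac_split("A") # "A" "A"
iupac_split <- function(code) {
  code <- toupper(code)
  if (length(code) != 1L || is.na(match(code, IUPAC_CODES)))
    stopf("iupac_split: '%s' is not a two-allele IUPAC code", code)
  IUPAC_SPLIT[[code]]
}

## TRUE where the consensus symbol is compatible with the given reference
## base (i.e. the base is one of the symbol's alleles). Vectorised.
iupac_compatible <- function(code, base) {
  mapply(function(cd, bs) {
    p <- IUPAC_SPLIT[[cd]]
    !is.null(p) && bs %in% p
  }, code, base, USE.NAMES = FALSE)
}

## Fast vectorised variant used by the aligner: precomputed membership matrix.
IUPAC_COMPAT_MATRIX <- local({
  m <- matrix(FALSE, length(IUPAC_CODES), 4,
              dimnames = list(IUPAC_CODES, IUPAC_BASES))
  for (cd in IUPAC_CODES) m[cd, unique(IUPAC_SPLIT[[cd]])] <- TRUE
  m
})

iupac_compat_fast <- function(code_vec, base_vec) {
  i <- match(code_vec, IUPAC_CODES)
  j <- match(base_vec, IUPAC_BASES)
  ok <- !is.na(i) & !is.na(j)
  out <- logical(length(code_vec))
  out[ok] <- IUPAC_COMPAT_MATRIX[cbind(i[ok], j[ok])]
  out
}
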