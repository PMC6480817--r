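#' Round half away from zero
#'
#' Decimal rounding with ties going up, as used for reported allele and
#' genotype-combination frequencies (e.g. 1/54 reports as 0.019, 22/34 as
#' 0.647). Base R's `round()` rounds half to even and would report 0.018.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 3).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(1 / 54, 3)   # 0.019
#' round_half_up(22 / 34, 3)  # 0.647
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a stream seed from a master seed; keeps the result a valid
## 32-bit integer whatever the stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647L)
}

## Split a sequence string into a character vector of single bases.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_acgt <- function(s) !grepl("[^ACGT]", s)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
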