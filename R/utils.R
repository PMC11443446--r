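`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base [round()] rounds half to even; cohort percentages are conventionally
#' printed with half rounded up (7/30 = 23.333... -> 23.33, 1/6 -> 16.67).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(c(0.125, 0.135), 2)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `expr` under a fixed RNG seed when one is given; otherwise use the
## ambient RNG stream. `expr` is a promise, forced inside with_seed so that
## draws land in the seeded stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## md5 of an R object via its canonical JSON serialization (config hashing).
hashObject <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

abortIf <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
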