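#' @keywords internal
#' @useDynLib mupnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run expr under a temporary RNG seed when seed is non-NULL; otherwise use the
# current RNG stream.
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up in magnitude (so 5.85
#' becomes 5.9), matching the convention used when printing accuracy
#' increments in clinical tables. Base [round()] uses round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
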