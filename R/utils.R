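#' Round half up
#'
#' Rounds to `digits` decimals with ties going away from zero (half-up),
#' the convention used for every one-decimal summary the package reports
#' (base R `round()` uses banker's rounding, which would report e.g. a
#' 11.75 mean as 11.7 instead of 11.8).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' One-decimal percentage
#'
#' `100 * num / den` rounded half-up to one decimal; the format used by the
#' QC report retention fields and carrier-frequency summaries.
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @return percentage on the 0-100 scale with one decimal.
#' @export
pct1 <- function(num, den) {
  stopifnot(den > 0)
  round_half_up(100 * num / den, 1)
}

# shared stop() with a consistent prefix so tests can match on class
ycm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ycm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
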