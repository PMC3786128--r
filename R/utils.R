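#' Round half away from zero
#'
#' Rounding used for all reported percentages. `base::round()` rounds half to
#' even ("banker's rounding"), which does not reproduce conventional
#' feasibility-report percentages such as 62.5 -> 63; this rounds halves up.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(62.5)   # 63
#' round_half_up(0.625, 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny nudge guards against binary representation of exact halves (e.g. 2.675)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage of a count over a denominator
#'
#' Computes `100 * num / den` rounded half-up to `digits` decimals. A zero
#' denominator yields `NA_real_` (undefined), never 0 or 100.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1, the convention for flow
#'   percentages; acceptability and retention tables use 0).
#' @return numeric percentage, or `NA_real_` when `den == 0`.
#' @export
pct <- function(num, den, digits = 1) {
  if (length(den) == 1L && (is.na(den) || den == 0)) return(NA_real_)
  out <- round_half_up(100 * num / den, digits)
  out[den == 0] <- NA_real_
  out
}

# stop() with a classed condition so callers/tests can distinguish error kinds
esbi_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "esbi_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

#' Generate a URL-safe random linkage identifier
#'
#' Linkage identifiers tie a participant's electronic responses to paper
#' records and allow interrupted sessions to be resumed. Callers may supply
#' their own opaque strings; this utility draws random ones from a URL-safe
#' alphabet.
#'
#' @param n number of identifiers.
#' @param length characters per identifier (default 10).
#' @return character vector of identifiers.
#' @export
generate_linkage_id <- function(n = 1, length = 10) {
  alphabet <- c(letters, LETTERS, 0:9, "-", "_")
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, length, replace = TRUE), collapse = "")
  }, character(1))
}
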