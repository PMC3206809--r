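#' Round half away from zero
#'
#' Display rounding used for reporting efficacy indices: exact halves round
#' away from zero (2.25 -> 2.3, -0.25 -> -0.3), unlike [round()]'s
#' round-half-even. Internal pipeline values are never rounded; this is for
#' matching printed tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_out(c(6.2565, -0.288), 1)
#' @export
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared validation helper
stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single number."))
  }
  if (positive && x <= 0) {
    abort(paste0("`", name, "` must be positive."))
  }
  invisible(x)
}
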