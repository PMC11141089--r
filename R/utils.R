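#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used when
#' comparing against values printed in photometric tables), as opposed to
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(309.57, 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar validators --------------------------------------------------------

stop_melanophot <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "melanophot_error")))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_melanophot(sprintf("`%s` must be a single finite number", name),
                    "melanophot_validation_error")
  if (strict && x <= lower)
    stop_melanophot(sprintf("`%s` must be > %g", name, lower),
                    "melanophot_validation_error")
  if (!strict && x < lower)
    stop_melanophot(sprintf("`%s` must be >= %g", name, lower),
                    "melanophot_validation_error")
  invisible(x)
}
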