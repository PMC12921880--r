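#' Round half away from zero
#'
#' Commercial ("half up") rounding as used when reporting toxic units and
#' EC50 values: halves are rounded away from zero rather than to the nearest
#' even digit as in [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(6.55, 1) # 6.6, where round() would give 6.5 or 6.6
#' @export
round_half_away <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Shared argument checks ------------------------------------------------

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", name))
  }
  invisible(x)
}

check_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
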