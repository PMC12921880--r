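#' FOCUS-style chi-squared error assessment
#'
#' Goodness-of-fit construction used in environmental-fate kinetics: the
#' observed-vs-predicted residual sum of squares is scaled by an assumed
#' relative measurement error (a percentage of the mean observed
#' concentration) and compared with the 0.95 quantile of the chi-squared
#' distribution at `df = n - n_params`. The scaled error is the smallest
#' measurement-error percentage at which that test would pass.
#'
#' @param observed,predicted Numeric vectors of equal length (mg/L),
#'   typically per-time replicate means.
#' @param n_params Number of fitted model parameters.
#' @param err_pct Assumed measurement-error percentage used for
#'   `chi2_calc` (default 15, the conventional starting point).
#' @param alpha Significance level of the test (default 0.05).
#' @return A one-row tibble: `ssr`, `chi2_calc`, `scaled_error_pct`, `df`,
#'   `n_params`, `err_pct`, `chi2_crit` (the tabulated quantile) and
#'   `chi2_pass` (`chi2_calc < chi2_crit`).
#' @details `chi2_calc = sum((o - p)^2) / (err_pct/100 * mean(o))^2` and
#'   `scaled_error_pct = 100/mean(o) * sqrt(ssr / q)` with
#'   `q = qchisq(1 - alpha, df)`. By construction, re-evaluating
#'   `chi2_calc` at `err_pct = scaled_error_pct` returns exactly `q`.
#' @export
focus_error <- function(observed, predicted, n_params, err_pct = 15,
                        alpha = 0.05) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.")
  }
  n <- length(observed)
  df <- n - n_params
  if (df < 1) abort("Degrees of freedom n - n_params must be >= 1.")
  if (err_pct <= 0) abort("`err_pct` must be > 0.")
  obar <- mean(observed)
  if (obar == 0) abort("Mean observed concentration is zero.")
  ssr <- sum((observed - predicted)^2)
  q <- qchisq(1 - alpha, df)
  chi2_calc <- ssr / (err_pct / 100 * obar)^2
  scaled <- 100 / obar * sqrt(ssr / q)
  tibble::tibble(
    ssr = ssr, chi2_calc = chi2_calc, scaled_error_pct = scaled,
    df = df, n_params = n_params, err_pct = err_pct,
    chi2_crit = q, chi2_pass = chi2_calc < q
  )
}

#' Coefficient of determination of a kinetic fit
#'
#' `R^2 = 1 - SSR / SStot` with the total sum of squares taken about the
#' observed mean. Returns `NA` (with a warning) when the observations have
#' zero variance, where the statistic is undefined.
#'
#' @inheritParams focus_error
#' @return A single numeric value in `(-Inf, 1]`, or `NA`.
#' @export
goodness_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    abort("`observed` and `predicted` must be equal-length vectors of >= 2.")
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    warn("Observed values have zero variance; R^2 is undefined.")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / sstot
}
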