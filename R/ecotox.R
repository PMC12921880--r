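#' Luminescence control correction factor
#'
#' Drift of the test bacteria's light output over the 15-minute contact
#' time, estimated from toxicant-free control cuvettes as the mean of
#' `i15 / i0`. Sample inhibition is then judged against `f * i0`, the light
#' a healthy suspension would have emitted.
#'
#' @param controls A data frame of control readings with numeric columns
#'   `i0` (> 0) and `i15` (>= 0).
#' @return The scalar correction factor `f`.
#' @export
correction_factor <- function(controls) {
  if (!is.data.frame(controls) || nrow(controls) == 0) {
    abort("`controls` must be a data frame with at least one row.")
  }
  if (!all(c("i0", "i15") %in% names(controls))) {
    abort("`controls` needs columns `i0` and `i15`.")
  }
  if (any(controls$i0 <= 0) || any(controls$i15 < 0)) {
    abort("Control readings must satisfy i0 > 0 and i15 >= 0.")
  }
  mean(controls$i15 / controls$i0)
}

#' Inhibition and gamma for a luminescence dilution series
#'
#' Standard Microtox-style construction: the inhibition of each cuvette is
#' `H = 100 * (f*i0 - i15) / (f*i0)` (% of expected light lost) and the
#' effect ratio is `gamma = H / (100 - H)` (lost light over remaining
#' light). Records with `H <= 0` (no inhibition, or stimulation) or
#' `H >= 100` (total quench) carry no information for the log-log
#' regression and are flagged unusable.
#'
#' @param records A data frame with numeric columns `dilution_pct`
#'   (in (0, 100]), `i0` (> 0) and `i15` (>= 0).
#' @param f Control correction factor, `> 0` (see [correction_factor()]).
#' @return The input tibble with columns `H`, `gamma` and logical `usable`
#'   appended.
#' @export
inhibition_and_gamma <- function(records, f) {
  check_scalar_num(f, "f")
  if (f <= 0) abort("`f` must be > 0.")
  if (!is.data.frame(records) ||
      !all(c("dilution_pct", "i0", "i15") %in% names(records))) {
    abort("`records` needs columns `dilution_pct`, `i0`, `i15`.")
  }
  if (any(records$i0 <= 0)) abort("All i0 readings must be > 0.")
  if (any(records$i15 < 0)) abort("i15 readings must be >= 0.")
  if (any(records$dilution_pct <= 0 | records$dilution_pct > 100)) {
    abort("Dilutions must lie in (0, 100] % v/v.")
  }
  expected <- f * records$i0
  H <- 100 * (expected - records$i15) / expected
  out <- tibble::as_tibble(records)
  out$H <- H
  out$gamma <- ifelse(H > 0 & H < 100, H / (100 - H), NA_real_)
  out$usable <- H > 0 & H < 100
  out
}

#' EC50 by gamma regression
#'
#' Least squares of `log10(gamma)` on `log10(dilution)` over the usable
#' records; the EC50 (% v/v) is the dilution where gamma = 1, i.e.
#' `10^(-intercept / slope)`.
#'
#' @inheritParams inhibition_and_gamma
#' @return An object of class `microtox_fit`: `ec50` (% v/v), `tu`
#'   (unrounded 100/EC50), `hazard_class`, `regression_slope`,
#'   `regression_intercept`, `n_usable`, `flags` and the per-dilution
#'   `data` (with `H`, `gamma`, `usable`).
#' @examples
#' rec <- gen_microtox(ec50_true = 50, cv = 0, seed = 1)
#' fit <- microtox(rec)
#' fit$ec50_mean
#' @export
ec50_gamma_regression <- function(records, f) {
  g <- inhibition_and_gamma(records, f)
  use <- g[g$usable, ]
  if (nrow(use) == 0) abort("No usable inhibition (all H <= 0 or >= 100).")
  if (length(unique(use$dilution_pct)) < 2) {
    abort("At least 2 distinct usable dilutions are required.")
  }
  reg <- lm(log10(gamma) ~ log10(dilution_pct), data = use)
  slope <- coef(reg)[[2]]; intercept <- coef(reg)[[1]]
  flags <- character()
  if (slope <= 0) {
    flags <- "non_monotone_response"
    ec50 <- NA_real_
  } else {
    ec50 <- 10^(-intercept / slope)
  }
  tu <- if (is.na(ec50)) NA_real_ else 100 / ec50
  structure(
    list(ec50 = ec50, tu = tu,
         hazard_class = if (is.na(tu)) NA_character_ else classify_persoone(tu),
         regression_slope = slope, regression_intercept = intercept,
         n_usable = nrow(use), flags = flags, data = g),
    class = "microtox_fit"
  )
}

#' Toxic units
#'
#' `TU = 100 / EC50` with the EC50 in % v/v, reported (by default) rounded
#' half-away-from-zero to one decimal, the convention of acute-toxicity
#' tables. Pass `digits = NULL` for the unrounded value.
#'
#' @param ec50 EC50 in % v/v, `> 0`. Vectorised.
#' @param digits Decimal places for reporting (default 1); `NULL` to skip
#'   rounding.
#' @return Toxic units.
#' @examples
#' toxic_units(15.2) # 6.6
#' @export
toxic_units <- function(ec50, digits = 1) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) abort("`ec50` must be > 0.")
  tu <- 100 / ec50
  if (is.null(digits)) tu else round_half_away(tu, digits)
}

#' Persoone hazard classification of acute toxicity
#'
#' Toxic-unit bands of the Persoone hazard scheme for wastewater:
#' below 0.4 TU no acute toxicity, 0.4-1 slight, 1-10 acute, 10-100 high,
#' and 100 TU or more very high acute toxicity (lower bound inclusive).
#'
#' @param tu Toxic units, `>= 0`. Vectorised.
#' @return Character vector of hazard-class labels.
#' @examples
#' classify_persoone(c(6.6, 10.5, 14.3))
#' @export
classify_persoone <- function(tu) {
  if (any(!is.finite(tu)) || any(tu < 0)) abort("`tu` must be >= 0.")
  cut(tu, breaks = c(-Inf, 0.4, 1, 10, 100, Inf), right = FALSE,
      labels = c("no acute toxicity", "slight acute toxicity",
                 "acute toxicity", "high acute toxicity",
                 "very high acute toxicity")) |>
    as.character()
}

#' Run the full Microtox-style assay
#'
#' Splits a luminescence table into control and sample records, derives the
#' control correction factor, fits the gamma regression per replicate, and
#' reports EC50 and TU as mean and standard deviation across replicates
#' with the hazard class of the mean TU.
#'
#' @param data A data frame with columns `role` (`"sample"` or
#'   `"control"`), `dilution_pct` (samples only; controls may hold `NA`),
#'   `i0`, `i15` and optionally `replicate` (defaults to a single
#'   replicate). Controls are shared across replicates unless they carry a
#'   `replicate` label.
#' @return A one-row tibble: `ec50_mean`, `ec50_sd`, `tu_mean`, `tu_sd`
#'   (TU per replicate rounded to 1 decimal before averaging is NOT done;
#'   means use unrounded values, then the reported means are rounded to 1
#'   decimal), `hazard_class`, `n_replicates`. The per-replicate fits are
#'   attached as the `"fits"` attribute.
#' @export
microtox <- function(data) {
  if (!is.data.frame(data) || !"role" %in% names(data)) {
    abort("`data` must be a data frame with a `role` column.")
  }
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  controls <- data[data$role == "control", ]
  samples <- data[data$role == "sample", ]
  if (nrow(controls) == 0) abort("No control records (role == 'control').")
  if (nrow(samples) == 0) abort("No sample records (role == 'sample').")

  fits <- lapply(split(samples, samples$replicate), function(rep_records) {
    ctl <- controls[controls$replicate %in% rep_records$replicate |
                      !"replicate" %in% names(controls), ]
    if (nrow(ctl) == 0) ctl <- controls
    f <- correction_factor(ctl)
    ec50_gamma_regression(rep_records, f)
  })
  ec50s <- vapply(fits, `[[`, numeric(1), "ec50")
  tus <- 100 / ec50s
  tu_mean <- mean(tus)
  out <- tibble::tibble(
    ec50_mean = round_half_away(mean(ec50s), 1),
    ec50_sd = if (length(ec50s) > 1) round_half_away(sd(ec50s), 1) else NA_real_,
    tu_mean = round_half_away(tu_mean, 1),
    tu_sd = if (length(tus) > 1) round_half_away(sd(tus), 1) else NA_real_,
    hazard_class = classify_persoone(tu_mean),
    n_replicates = length(fits)
  )
  attr(out, "fits") <- fits
  out
}

#' @method print microtox_fit
#' @export
print.microtox_fit <- function(x, ...) {
  cat("<microtox_fit> log10(gamma) ~ log10(dilution)\n")
  cat(sprintf("  slope = %.4g, intercept = %.4g (n usable = %d)\n",
              x$regression_slope, x$regression_intercept, x$n_usable))
  cat(sprintf("  EC50 = %.4g %% v/v, TU = %.4g, class: %s\n",
              x$ec50, x$tu, x$hazard_class))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidiers for Microtox fits
#'
#' @param x A `microtox_fit`.
#' @param ... Unused.
#' @return A tibble; `glance()` gives the one-row EC50/TU summary.
#' @method tidy microtox_fit
#' @export
tidy.microtox_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$regression_slope, x$regression_intercept))
}

#' @rdname tidy.microtox_fit
#' @method glance microtox_fit
#' @export
glance.microtox_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, tu = x$tu, hazard_class = x$hazard_class,
                 n_usable = x$n_usable)
}

#' Plot a Microtox gamma regression
#'
#' @param object A `microtox_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot microtox_fit
#' @export
autoplot.microtox_fit <- function(object, ...) {
  use <- object$data[object$data$usable, ]
  ggplot2::ggplot(use, ggplot2::aes(log10(.data$dilution_pct),
                                    log10(.data$gamma))) +
    ggplot2::geom_abline(slope = object$regression_slope,
                         intercept = object$regression_intercept,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 dilution (% v/v)", y = "log10 gamma",
                  title = sprintf("EC50 = %.3g%% v/v", object$ec50)) +
    ggplot2::theme_minimal()
}
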