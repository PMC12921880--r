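#' @title Fit first-order degradation models to a concentration time series
#'
#' @description `fit_sfo()` fits the simple first-order model
#' `M_t = M0 * exp(-k t)`; `fit_hs()` fits the biphasic hockey-stick model
#' (fast rate `k1` until the breakpoint `tb`, slow rate `k2 <= k1` after),
#' both by bounded least squares with multiple starts. `fit_kinetics()` fits
#' several models at once and `select_model()` picks the best one by the
#' FOCUS scaled error.
#'
#' @details Replicated measurements at the same time are averaged before
#' fitting (the FOCUS convention); predictions and goodness-of-fit
#' statistics refer to these per-time means. Rate constants are started
#' from a log-linear regression of the positive concentrations; the
#' hockey-stick breakpoint is started on a grid of interior observed times,
#' plus a start at the SFO solution (so the nested model can never fit
#' worse). The FOCUS chi-squared assessment uses `err_pct` (default 15%)
#' and a 0.05 significance level; see [focus_error()].
#'
#' @param data A data frame with numeric columns `time_days` and
#'   `concentration_mg_per_L` (an optional `replicate` column is allowed and
#'   ignored beyond averaging). Times must include 0 and span at least 4
#'   distinct values (5 for the hockey-stick model).
#' @param err_pct Measurement-error percentage for the chi-squared
#'   statistic (default 15).
#' @return An object of class `kinetic_fit`: a list with `model_id`
#'   (`"SFO"` or `"HS"`), `par` (named estimates, mg/L and 1/day), `dt50`
#'   (days, possibly `Inf`), `data` (tibble of per-time observed and
#'   predicted means), `stats` (one-row tibble from [focus_error()] plus
#'   `r2`), `convergence` (0 for success) and `flags` (character).
#' @examples
#' ser <- gen_degradation(model = "sfo", k = 0.5, sd = 0, seed = 1)
#' fit <- fit_sfo(ser)
#' glance(fit)
#' @seealso [predict_sfo()], [predict_hs()], [dt50_sfo()], [dt50_hs()]
#' @export
fit_sfo <- function(data, err_pct = 15) {
  ser <- validate_degradation(data, min_times = 4)
  start <- loglin_start(ser$time, ser$conc)
  starts <- list(c(start$m0, start$k),
                 c(start$m0, max(start$k * 2, 1e-3)),
                 c(start$m0, start$k / 2))
  obj <- function(p) sum((ser$conc - predict_sfo(p[1], p[2], ser$time))^2)
  best <- multistart_optim(obj, starts,
                           lower = c(1e-10, 0),
                           upper = c(max(ser$conc) * 1e3 + 1, 1e3))
  par <- c(m0_hat = best$par[1], k_hat = snap_zero(best$par[2]))
  pred <- predict_sfo(par[["m0_hat"]], par[["k_hat"]], ser$time)
  new_kinetic_fit("SFO", par,
                  dt50 = dt50_sfo(par[["k_hat"]]),
                  time = ser$time, observed = ser$conc, predicted = pred,
                  n_params = 2, err_pct = err_pct,
                  convergence = best$convergence)
}

#' @rdname fit_sfo
#' @export
fit_hs <- function(data, err_pct = 15) {
  ser <- validate_degradation(data, min_times = 5)
  t <- ser$time; y <- ser$conc
  trange <- range(t)
  interior <- t[t > trange[1] & t < trange[2]]

  # parameterised as (m0, k1, r, tb) with k2 = r * k1 so k1 >= k2 >= 0 always
  obj <- function(p) {
    sum((y - predict_hs(p[1], p[2], p[3] * p[2], p[4], t))^2)
  }
  starts <- lapply(interior, function(tb) {
    s1 <- loglin_start(t[t <= tb], y[t <= tb])
    s2 <- loglin_start(t[t >= tb], y[t >= tb])
    k1 <- max(s1$k, 1e-4)
    r <- min(max(s2$k / k1, 0), 1)
    c(s1$m0, k1, r, tb)
  })
  # SFO-collapse start: guarantees HS never fits worse than SFO
  sfo <- fit_sfo(data, err_pct = err_pct)
  starts <- c(starts, list(c(sfo$par[["m0_hat"]], max(sfo$par[["k_hat"]], 1e-8),
                             1, mean(trange))))
  eps <- 1e-8 * diff(trange)
  best <- multistart_optim(obj, starts,
                           lower = c(1e-10, 0, 0, trange[1] + eps),
                           upper = c(max(y) * 1e3 + 1, 1e3, 1, trange[2] - eps))
  p <- best$par
  par <- c(m0_hat = p[1], k1_hat = snap_zero(p[2]),
           k2_hat = snap_zero(p[3] * p[2]), tb_hat = p[4])
  pred <- predict_hs(par[["m0_hat"]], par[["k1_hat"]], par[["k2_hat"]],
                     par[["tb_hat"]], t)
  flags <- character()
  if (min(par[["tb_hat"]] - trange[1], trange[2] - par[["tb_hat"]]) <
      1e-3 * diff(trange)) {
    flags <- "tb_at_boundary"
  }
  new_kinetic_fit("HS", par,
                  dt50 = dt50_hs(par[["k1_hat"]], par[["k2_hat"]],
                                 par[["tb_hat"]]),
                  time = t, observed = y, predicted = pred,
                  n_params = 4, err_pct = err_pct,
                  convergence = best$convergence, flags = flags)
}

#' @rdname fit_sfo
#' @param models Character vector of model ids to fit, among `"sfo"`, `"hs"`.
#' @return `fit_kinetics()` returns a named list of `kinetic_fit` objects.
#' @export
fit_kinetics <- function(data, models = c("sfo", "hs"), err_pct = 15) {
  models <- match.arg(tolower(models), c("sfo", "hs"), several.ok = TRUE)
  fits <- lapply(models, function(m) {
    switch(m, sfo = fit_sfo(data, err_pct), hs = fit_hs(data, err_pct))
  })
  setNames(fits, toupper(models))
}

#' Select the best kinetic model by FOCUS scaled error
#'
#' Returns the fit with the smallest scaled error percentage; ties are
#' broken in favour of the model with fewer parameters.
#'
#' @param fits A (possibly named) list of `kinetic_fit` objects.
#' @return The selected `kinetic_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  if (length(fits) == 0) abort("`fits` must contain at least one fit.")
  stopifnot(all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  err <- vapply(fits, function(f) f$stats$scaled_error_pct, numeric(1))
  npar <- vapply(fits, function(f) f$stats$n_params, numeric(1))
  fits[[order(err, npar)[1]]]
}

# Internal helpers ------------------------------------------------------

validate_degradation <- function(data, min_times) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("time_days", "concentration_mg_per_L")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  t <- data$time_days; y <- data$concentration_mg_per_L
  if (!is.numeric(t) || !is.numeric(y) || anyNA(t) || anyNA(y)) {
    abort("time_days and concentration_mg_per_L must be numeric, no NA.")
  }
  if (any(t < 0) || any(y < 0)) abort("Times and concentrations must be >= 0.")
  agg <- dplyr::summarise(dplyr::group_by(tibble::tibble(time = t, conc = y),
                                          .data$time),
                          conc = mean(.data$conc), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$time)
  if (nrow(agg) < min_times) {
    abort(sprintf("At least %d distinct time points are required.", min_times))
  }
  if (min(agg$time) != 0) abort("The series must include time 0.")
  if (all(agg$conc == 0)) abort("All concentrations are zero; nothing to fit.")
  agg
}

# rate constants indistinguishable from zero at double precision are
# reported as zero, so flat series get DT50 = Inf rather than 1e17 days
snap_zero <- function(k, tol = 1e-10) if (k < tol) 0 else k

# slope/intercept of log(conc) ~ time over positive observations
loglin_start <- function(t, y) {
  ok <- y > 0
  if (sum(ok) >= 2 && length(unique(t[ok])) >= 2) {
    co <- coef(lm(log(y[ok]) ~ t[ok]))
    list(m0 = exp(co[[1]]), k = max(-co[[2]], 0))
  } else {
    list(m0 = max(y, 1e-6), k = 1)
  }
}

multistart_optim <- function(obj, starts, lower, upper) {
  runs <- lapply(starts, function(s) {
    s <- pmin(pmax(s, lower), upper)
    tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e1, maxit = 500)),
      error = function(e) NULL
    )
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) abort("Least-squares optimisation failed to run.")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  # code 52 ("abnormal termination in lnsrch") routinely means the line
  # search cannot improve a solution already at machine precision; only a
  # hit iteration cap is worth a warning
  if (best$convergence == 1) {
    warn("Optimiser hit the iteration limit; estimates may be unconverged.")
  }
  best
}

new_kinetic_fit <- function(model_id, par, dt50, time, observed, predicted,
                            n_params, err_pct, convergence,
                            flags = character()) {
  stats <- focus_error(observed, predicted, n_params = n_params,
                       err_pct = err_pct)
  stats$r2 <- goodness_r2(observed, predicted)
  if (!is.finite(dt50)) flags <- c(flags, "dt50_infinite")
  structure(
    list(model_id = model_id, par = par, dt50 = dt50,
         data = tibble::tibble(time_days = time, observed = observed,
                               predicted = predicted),
         stats = stats, convergence = convergence, flags = flags),
    class = "kinetic_fit"
  )
}

#' @method print kinetic_fit
#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s model\n", x$model_id))
  cat("  parameters: ",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  DT50 = %.4g days%s\n", x$dt50,
              if (!is.finite(x$dt50)) " (half-decline not reached)" else ""))
  cat(sprintf("  SSR = %.4g, R2 = %.4f, chi2 = %.3g (err %.3g%%), scaled error = %.3g%%\n",
              x$stats$ssr, x$stats$r2, x$stats$chi2_calc, x$stats$err_pct,
              x$stats$scaled_error_pct))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidiers for kinetic fits
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model summary (DT50 and the FOCUS fit statistics).
#'
#' @param x A `kinetic_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.kinetic_fit
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model_id = x$model_id, dt50 = x$dt50),
                   x$stats)
}

#' Plot a kinetic fit
#'
#' Observed per-time mean concentrations with the fitted decay curve.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_days = seq(min(object$data$time_days), max(object$data$time_days),
                    length.out = 200)
  )
  grid$predicted <- predict_kinetic(object, grid$time_days)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_days, .data$observed)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$predicted), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (days)", y = "Concentration (mg/L)",
                  title = sprintf("%s fit (DT50 = %.3g d)", object$model_id,
                                  object$dt50)) +
    ggplot2::theme_minimal()
}

#' Predict from a fitted kinetic model
#'
#' @param object A `kinetic_fit`.
#' @param t Times (days) at which to predict.
#' @return Predicted concentrations (mg/L).
#' @export
predict_kinetic <- function(object, t) {
  stopifnot(inherits(object, "kinetic_fit"))
  p <- object$par
  switch(object$model_id,
         SFO = predict_sfo(p[["m0_hat"]], p[["k_hat"]], t),
         HS = predict_hs(p[["m0_hat"]], p[["k1_hat"]], p[["k2_hat"]],
                         p[["tb_hat"]], t),
         abort("Unknown model id."))
}
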