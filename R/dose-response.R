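#' Viability from optical density
#'
#' Growth of a treated culture relative to the untreated control,
#' `100 * OD_treated / OD_control`. Values above 100% (growth stimulation)
#' are allowed.
#'
#' @param od_treated OD600 of the treated culture(s), `>= 0`. Vectorised.
#' @param od_control OD600 of the control culture(s), `> 0`.
#' @return Viability in percent.
#' @export
viability_from_od <- function(od_treated, od_control) {
  if (any(!is.finite(od_control)) || any(od_control <= 0)) {
    abort("`od_control` must be > 0.")
  }
  check_nonneg(od_treated, "od_treated")
  100 * od_treated / od_control
}

#' Fit the quadratic log-dose viability model
#'
#' Ordinary least squares of viability (%) on the log-dose and its square:
#' `y = a * log(C)^2 + b * log(C) + c`, the classical second-order
#' polynomial description of growth-inhibition curves. The fitted curve is
#' inverted at y = 50 to obtain the IC50 (see [ic50_from_quadratic()]),
#' which is attached to the returned object.
#'
#' @param data A data frame with column `concentration_mg_per_L` (> 0) and
#'   either `viability_pct` or both `od600_treated` and `od600_control`
#'   (viability is then computed with [viability_from_od()]). Duplicate
#'   measurements are fitted as individual points, not averaged.
#' @param log_base Base of the dose logarithm (default 10).
#' @return An object of class `quad_dose_fit`: coefficients `a`, `b`, `c`,
#'   `r2` (`NA` with a flag when viability is constant), `ic50` (mg/L, `NA`
#'   when the curve never crosses 50%), `ic50_flag` (one of `"ok"`,
#'   `"extrapolated"`, `"not_attained"`), `dose_range` (log-dose interval
#'   observed), `log_base` and the model `data`.
#' @examples
#' dd <- gen_dose_response(sd = 0, seed = 1)
#' fit <- fit_quadratic_logdose(dd)
#' glance(fit)
#' @export
fit_quadratic_logdose <- function(data, log_base = 10) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!"concentration_mg_per_L" %in% names(data)) {
    abort("Missing column `concentration_mg_per_L`.")
  }
  conc <- data$concentration_mg_per_L
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("Concentrations must be finite and > 0 (their log is taken).")
  }
  if (length(unique(conc)) < 4) {
    abort("At least 4 distinct concentrations are required.")
  }
  if ("viability_pct" %in% names(data)) {
    viab <- data$viability_pct
  } else if (all(c("od600_treated", "od600_control") %in% names(data))) {
    viab <- viability_from_od(data$od600_treated, data$od600_control)
  } else {
    abort("Provide `viability_pct` or `od600_treated` + `od600_control`.")
  }
  check_nonneg(viab, "viability")

  u <- log(conc, base = log_base)
  fit <- lm(viab ~ I(u^2) + u)
  co <- coef(fit)
  if (anyNA(co)) abort("Singular design: cannot fit the quadratic model.")
  a <- co[["I(u^2)"]]; b <- co[["u"]]; cc <- co[["(Intercept)"]]
  sstot <- sum((viab - mean(viab))^2)
  flags <- character()
  if (sstot == 0) {
    r2 <- NA_real_
    flags <- "constant_viability"
  } else {
    r2 <- 1 - sum(fit$residuals^2) / sstot
  }
  dose_range <- range(u)
  obj <- structure(
    list(a = a, b = b, c = cc, r2 = r2, dose_range = dose_range,
         log_base = log_base, flags = flags,
         data = tibble::tibble(concentration_mg_per_L = conc,
                               log_dose = u, viability_pct = viab)),
    class = "quad_dose_fit"
  )
  inv <- ic50_from_quadratic(obj)
  obj$ic50 <- inv$ic50
  obj$ic50_flag <- inv$flag
  obj
}

#' Invert a quadratic log-dose fit at 50% viability
#'
#' Solves `a u^2 + b u + c = 50` for the log-dose `u` and back-transforms.
#' Among real roots, roots inside the observed dose range (extended by 0.3
#' log units) are preferred; if two qualify, the root on the declining limb
#' of the curve (`2 a u + b < 0`) is taken, since the IC50 is defined where
#' viability falls through 50%. A root outside the tested range is still
#' returned but flagged `"extrapolated"`; no real crossing gives
#' `ic50 = NA` with flag `"not_attained"`.
#'
#' @param fit A `quad_dose_fit`, or a list with elements `a`, `b`, `c`.
#' @param dose_range Log-dose interval of the tested doses (two numbers);
#'   defaults to the fitted object's range.
#' @param log_base Base of the dose logarithm (taken from the fit if
#'   available, else 10).
#' @param tol Tolerance (log units) by which `dose_range` is extended
#'   before a root counts as in-range (default 0.3).
#' @return A list with `ic50` (mg/L or `NA`), `log_ic50`, and `flag`.
#' @export
ic50_from_quadratic <- function(fit, dose_range = NULL, log_base = NULL,
                                tol = 0.3) {
  a <- fit$a; b <- fit$b; cc <- fit$c
  log_base <- log_base %||% fit$log_base %||% 10
  dose_range <- dose_range %||% fit$dose_range
  if (is.null(dose_range)) abort("`dose_range` is required.")

  not_attained <- list(ic50 = NA_real_, log_ic50 = NA_real_,
                       flag = "not_attained")
  roots <- if (a == 0) {
    if (b == 0) numeric() else (50 - cc) / b
  } else {
    disc <- b^2 - 4 * a * (cc - 50)
    if (disc < 0) numeric() else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[is.finite(roots)]
  if (length(roots) == 0) return(not_attained)

  in_range <- roots >= dose_range[1] - tol & roots <= dose_range[2] + tol
  pick_decreasing <- function(r) {
    if (length(r) == 1) return(r)
    slope <- 2 * a * r + b
    dec <- r[slope < 0]
    if (length(dec)) dec[1] else r[1]
  }
  if (any(in_range)) {
    u <- pick_decreasing(roots[in_range])
    flag <- "ok"
  } else {
    u <- pick_decreasing(roots)
    flag <- "extrapolated"
  }
  list(ic50 = log_base^u, log_ic50 = u, flag = flag)
}

#' @method print quad_dose_fit
#' @export
print.quad_dose_fit <- function(x, ...) {
  cat("<quad_dose_fit> viability = a*log(C)^2 + b*log(C) + c\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g (log base %g), R2 = %s\n",
              x$a, x$b, x$c, x$log_base,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  cat(sprintf("  IC50 = %s mg/L [%s]\n",
              ifelse(is.na(x$ic50), "NA", sprintf("%.4g", x$ic50)),
              x$ic50_flag))
  invisible(x)
}

#' Tidiers for quadratic dose-response fits
#'
#' @param x A `quad_dose_fit`.
#' @param ... Unused.
#' @return A tibble: `tidy()` has one row per coefficient, `glance()` one
#'   row with `r2`, `ic50` and its flag.
#' @method tidy quad_dose_fit
#' @export
tidy.quad_dose_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname tidy.quad_dose_fit
#' @method glance quad_dose_fit
#' @export
glance.quad_dose_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, ic50 = x$ic50, ic50_flag = x$ic50_flag,
                 log_base = x$log_base,
                 n = nrow(x$data))
}

#' Plot a quadratic dose-response fit
#'
#' Viability against log dose with the fitted parabola, the 50% line and
#' the IC50 (when attained).
#'
#' @param object A `quad_dose_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quad_dose_fit
#' @export
autoplot.quad_dose_fit <- function(object, ...) {
  rng <- range(object$data$log_dose)
  grid <- tibble::tibble(log_dose = seq(rng[1], rng[2], length.out = 200))
  grid$viability_pct <- object$a * grid$log_dose^2 +
    object$b * grid$log_dose + object$c
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$log_dose, .data$viability_pct)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("log%g dose (mg/L)", object$log_base),
                  y = "Viability (%)") +
    ggplot2::theme_minimal()
  if (!is.na(object$ic50)) {
    p <- p + ggplot2::geom_vline(xintercept = log(object$ic50,
                                                  base = object$log_base),
                                 colour = "firebrick", linetype = "dotted")
  }
  p
}
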