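#' Simple first-order (SFO) decay curve
#'
#' Predicted residual concentration under single first-order kinetics,
#' `M_t = M0 * exp(-k * t)`.
#'
#' @param m0 Initial concentration (mg/L), `>= 0`.
#' @param k First-order rate constant (1/day), `>= 0`.
#' @param t Time (days), vectorised, `>= 0`.
#' @return Predicted concentration (mg/L), same length as `t`.
#' @examples
#' predict_sfo(10, log(2), 1) # one half-life: 5 mg/L
#' @family kinetic models
#' @export
predict_sfo <- function(m0, k, t) {
  check_scalar_num(m0, "m0"); check_scalar_num(k, "k")
  check_nonneg(m0, "m0"); check_nonneg(k, "k"); check_nonneg(t, "t")
  m0 * exp(-k * t)
}

#' Hockey-stick (biphasic first-order) decay curve
#'
#' Piecewise first-order decay: fast rate `k1` up to the breakpoint `tb`,
#' then slower rate `k2`; continuous at `tb`:
#' `M_t = M0 * exp(-k1 * t)` for `t <= tb`, and
#' `M_t = M0 * exp(-k1 * tb) * exp(-k2 * (t - tb))` for `t > tb`.
#'
#' @param m0 Initial concentration (mg/L).
#' @param k1,k2 Rate constants for the fast and slow phase (1/day).
#' @param tb Breakpoint time (days).
#' @inheritParams predict_sfo
#' @return Predicted concentration (mg/L), same length as `t`.
#' @family kinetic models
#' @export
predict_hs <- function(m0, k1, k2, tb, t) {
  for (nm in c("m0", "k1", "k2", "tb")) check_scalar_num(get(nm), nm)
  check_nonneg(c(m0, k1, k2, tb), "m0/k1/k2/tb"); check_nonneg(t, "t")
  ifelse(t <= tb,
         m0 * exp(-k1 * t),
         m0 * exp(-k1 * tb) * exp(-k2 * (t - tb)))
}

#' Half-life (DT50) of the SFO model
#'
#' `DT50 = ln(2) / k`. A zero rate constant means the concentration never
#' declines; the half-life is then reported as `Inf` rather than an error.
#'
#' @param k First-order rate constant (1/day), `>= 0`.
#' @return DT50 in days (`Inf` when `k = 0`).
#' @family kinetic models
#' @export
dt50_sfo <- function(k) {
  check_scalar_num(k, "k"); check_nonneg(k, "k")
  if (k == 0) return(Inf)
  log(2) / k
}

#' Half-life (DT50) of the hockey-stick model
#'
#' If half-decline happens within the fast phase (`ln(2)/k1 <= tb`) the SFO
#' formula applies; otherwise the residual decline is carried by the slow
#' phase: `DT50 = tb + (ln(2) - k1 * tb) / k2`. When the slow phase is flat
#' (`k2 = 0`) and the fast phase did not reach 50%, the half-life is `Inf`.
#'
#' @param k1,k2 Fast- and slow-phase rate constants (1/day).
#' @param tb Breakpoint time (days).
#' @return DT50 in days (`Inf` when half-decline is never reached).
#' @family kinetic models
#' @export
dt50_hs <- function(k1, k2, tb) {
  for (nm in c("k1", "k2", "tb")) check_scalar_num(get(nm), nm)
  check_nonneg(c(k1, k2, tb), "k1/k2/tb")
  if (k1 == 0) return(Inf)
  fast <- log(2) / k1
  if (fast <= tb) return(fast)
  if (k2 == 0) return(Inf)
  tb + (log(2) - k1 * tb) / k2
}
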