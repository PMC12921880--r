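# Independent oracles used across tests.

# DT50 by bisection on the model curve itself, independent of the closed
# forms in dt50_sfo()/dt50_hs(). Returns Inf when half-decline is never
# reached within `upper` days.
bisect_dt50 <- function(predict_fn, m0, upper = 1e6, tol = 1e-12) {
  f <- function(t) predict_fn(t) - m0 / 2
  if (f(upper) > 0) return(Inf)
  uniroot(f, c(0, upper), tol = tol)$root
}

# Gaussian-noise degradation replicate for recovery studies
noisy_sfo_series <- function(seed, m0 = 10, k = 0.33, sd = 0.2) {
  gen_degradation(model = "sfo", m0 = m0, k = k, sd = sd, seed = seed)
}
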