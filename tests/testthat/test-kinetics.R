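test_that("SFO and hockey-stick curves evaluate their closed forms", {
  expect_equal(predict_sfo(10, 0, 5), 10)
  expect_equal(predict_sfo(10, log(2), 1), 5)
  expect_equal(predict_sfo(10, 0.33, 2.3), 10 * exp(-0.33 * 2.3))

  expect_equal(predict_hs(10, 1.05, 0.002, 1, 0), 10)
  expect_equal(predict_hs(10, 1.05, 0.002, 1, 1), 10 * exp(-1.05))
  # continuity at the breakpoint
  expect_equal(predict_hs(10, 1.05, 0.002, 1, 1 + 1e-12),
               predict_hs(10, 1.05, 0.002, 1, 1), tolerance = 1e-9)
  expect_error(predict_sfo(-1, 0.1, 1), "non-negative")
  expect_error(predict_hs(10, -0.1, 0.002, 1, 1), "non-negative")
})

test_that("hockey-stick with equal rates collapses to SFO on a dense grid", {
  t <- seq(0, 30, length.out = 301)
  for (k in c(0.05, 0.5, 2)) {
    expect_equal(predict_hs(10, k, k, 3, t), predict_sfo(10, k, t))
  }
})

test_that("DT50 closed forms match their definitions and flag no-decline", {
  expect_equal(dt50_sfo(log(2)), 1)
  expect_equal(dt50_sfo(1.75), log(2) / 1.75)
  expect_identical(dt50_sfo(0), Inf)

  expect_equal(dt50_hs(log(2), 0.001, 2), 1)       # fast phase suffices
  expect_equal(dt50_hs(0.1, log(2), 1), 1 + (log(2) - 0.1) / log(2))
  expect_identical(dt50_hs(0.1, 0, 1), Inf)        # plateau above 50%
  expect_identical(dt50_hs(0, 0.5, 1), Inf)
})

test_that("DT50 closed forms agree with bisection on randomized parameters", {
  set.seed(71)
  for (i in 1:60) {
    k <- runif(1, 0.01, 3)
    d <- dt50_sfo(k)
    expect_equal(d, bisect_dt50(function(t) predict_sfo(10, k, t), 10),
                 tolerance = 1e-9)
    k1 <- runif(1, 0.05, 3); k2 <- runif(1, 0, 1) * k1; tb <- runif(1, 0.1, 10)
    d <- dt50_hs(k1, k2, tb)
    oracle <- bisect_dt50(function(t) predict_hs(10, k1, k2, tb, t), 10)
    if (is.finite(d)) {
      expect_equal(d, oracle, tolerance = 1e-9)
      expect_equal(predict_hs(10, k1, k2, tb, d), 5, tolerance = 1e-8)
    } else {
      expect_identical(oracle, Inf)
    }
  }
})

test_that("FOCUS chi-squared matches a hand-summed oracle and is self-consistent", {
  o <- c(10, 8, 6, 4, 2); p <- c(9.5, 8.2, 6.1, 3.8, 2.4)
  # hand-summed: SSR = .25+.04+.01+.04+.16 = 0.5, mean(o) = 6
  st <- focus_error(o, p, n_params = 2, err_pct = 15)
  expect_equal(st$ssr, 0.5)
  expect_equal(st$chi2_calc, 0.5 / (0.15 * 6)^2)
  expect_equal(st$df, 3)

  # evaluating at the scaled error returns exactly the tabulated quantile
  st2 <- focus_error(o, p, n_params = 2, err_pct = st$scaled_error_pct)
  expect_equal(st2$chi2_calc, qchisq(0.95, 3), tolerance = 1e-9)

  perfect <- focus_error(o, o, n_params = 2)
  expect_equal(perfect$chi2_calc, 0)
  expect_equal(perfect$scaled_error_pct, 0)

  expect_error(focus_error(o, p, n_params = 5), "freedom")
  expect_error(focus_error(c(0, 0, 0, 0), c(0, 0, 0, 0), 2), "zero")
})

test_that("scaled error is monotone non-decreasing in SSR at fixed design", {
  o <- c(10, 8, 6, 4, 2)
  errs <- sapply(seq(0, 1, by = 0.1), function(shift) {
    focus_error(o, o + shift, n_params = 2)$scaled_error_pct
  })
  expect_true(all(diff(errs) >= 0))
})

test_that("R-squared matches direct arithmetic and flags zero variance", {
  expect_equal(goodness_r2(c(10, 5, 2), c(10, 5, 2)), 1)
  expect_equal(goodness_r2(c(10, 5, 2), rep(mean(c(10, 5, 2)), 3)), 0)
  expect_equal(goodness_r2(c(10, 5, 2), c(9, 6, 2)),
               1 - 2 / (sum((c(10, 5, 2) - 17 / 3)^2)))
  expect_warning(r2 <- goodness_r2(c(5, 5, 5), c(5, 5, 4)), "undefined")
  expect_true(is.na(r2))
})

test_that("noiseless series are recovered to tight tolerances", {
  ser <- tibble::tibble(time_days = c(0, 1, 2, 5, 7, 14),
                        concentration_mg_per_L = predict_sfo(10, 0.5, c(0, 1, 2, 5, 7, 14)))
  fit <- fit_sfo(ser)
  expect_equal(fit$par[["k_hat"]], 0.5, tolerance = 1e-6)
  expect_equal(fit$par[["m0_hat"]], 10, tolerance = 1e-6)
  expect_equal(fit$dt50, log(2) / 0.5, tolerance = 1e-6)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-9)

  serh <- gen_degradation(model = "hs", sd = 0, seed = 1)
  fith <- fit_hs(serh)
  truth <- c(m0_hat = 10, k1_hat = 1.05, k2_hat = 0.002, tb_hat = 1)
  expect_equal(fith$par, truth, tolerance = 1e-4)
})

test_that("degenerate series are handled: no decay, all zero, short input", {
  flat <- tibble::tibble(time_days = c(0, 1, 2, 5, 7),
                         concentration_mg_per_L = rep(10, 5))
  fit <- suppressWarnings(fit_sfo(flat))
  expect_lt(fit$par[["k_hat"]], 1e-6)
  expect_identical(fit$dt50, Inf)
  expect_true("dt50_infinite" %in% fit$flags)

  zero <- tibble::tibble(time_days = c(0, 1, 2, 5),
                         concentration_mg_per_L = rep(0, 4))
  expect_error(fit_sfo(zero), "zero")
  expect_error(fit_sfo(tibble::tibble(time_days = c(0, 1, 2),
                                      concentration_mg_per_L = c(3, 2, 1))),
               "distinct time points")
  expect_error(fit_sfo(tibble::tibble(time_days = c(1, 2, 5, 7),
                                      concentration_mg_per_L = c(9, 7, 3, 1))),
               "time 0")
})

test_that("replicate measurements are averaged per time before fitting", {
  times <- c(0, 1, 2, 5, 7)
  truth <- predict_sfo(10, 0.4, times)
  dup <- tibble::tibble(
    time_days = rep(times, each = 2),
    concentration_mg_per_L = rep(truth, each = 2) + rep(c(-0.5, 0.5), 5)
  )
  fit <- fit_sfo(dup)
  expect_equal(nrow(fit$data), length(times))
  expect_equal(fit$data$observed, truth)  # +/-0.5 replicates average out
  expect_equal(fit$par[["k_hat"]], 0.4, tolerance = 1e-6)
})

test_that("HS nests SFO: its SSR never exceeds the SFO SSR", {
  for (seed in 1:5) {
    ser <- noisy_sfo_series(seed)
    s <- fit_sfo(ser); h <- fit_hs(ser)
    expect_lte(h$stats$ssr, s$stats$ssr + 1e-10)
  }
})

test_that("model selection minimises scaled error with a parsimony tie-break", {
  ser <- gen_degradation(model = "hs", sd = 0.1, seed = 3)
  fits <- fit_kinetics(ser)
  best <- select_model(fits)
  errs <- sapply(fits, function(f) f$stats$scaled_error_pct)
  expect_equal(best$stats$scaled_error_pct, min(errs))

  # tie: equal scaled error -> fewer parameters wins
  mock <- function(model, err, npar) {
    structure(list(model_id = model,
                   stats = tibble::tibble(scaled_error_pct = err,
                                          n_params = npar)),
              class = "kinetic_fit")
  }
  expect_equal(select_model(list(mock("HS", 2, 4), mock("SFO", 2, 2)))$model_id,
               "SFO")
  expect_equal(select_model(list(mock("SFO", 3.9, 2), mock("HS", 6, 4)))$model_id,
               "SFO")
  expect_equal(select_model(list(mock("HS", 1, 4)))$model_id, "HS")
  expect_error(select_model(list()), "at least one")
})

test_that("kinetic fit accessors: tidy, glance, predict, plot", {
  fit <- fit_sfo(gen_degradation(model = "sfo", sd = 0, seed = 1))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("m0_hat", "k_hat"))
  gl <- glance(fit)
  expect_equal(gl$model_id, "SFO")
  expect_true(all(c("dt50", "chi2_calc", "scaled_error_pct", "r2") %in% names(gl)))
  expect_equal(predict_kinetic(fit, 0), fit$par[["m0_hat"]])
  expect_s3_class(autoplot(fit), "ggplot")
})
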