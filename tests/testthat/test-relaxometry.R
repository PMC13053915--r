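# Relaxation fitting: monoexponential decays, R2eff and NOE estimators,
# and flat-versus-two-site dispersion model selection.

test_that("monoexponential fit recovers exact rates and is scale invariant", {
  delays <- seq(0.02, 1.2, length.out = 8)
  y <- 3.2 * exp(-1.2 * delays)
  f <- fit_monoexponential(decay_series(1, delays, y, 0.01))
  expect_equal(f$rate$value, 1.2, tolerance = 1e-6)
  expect_equal(f$i0$value, 3.2, tolerance = 1e-6)
  f2 <- fit_monoexponential(decay_series(1, delays, 50 * y, 0.01))
  expect_equal(f2$rate$value, f$rate$value, tolerance = 1e-8)
  # constant intensities: rate ~ 0
  f3 <- fit_monoexponential(decay_series(1, delays, rep(2, 8), 0.01))
  expect_lt(abs(f3$rate$value), 1e-6)
  expect_error(decay_series(1, c(0.1, 0.2, 0.3), c(1, 2, 3), 0.01),
               "4 distinct delays")
  expect_error(
    fit_monoexponential(decay_series(1, delays, c(1, 2, -1, -1, -1, -1,
                                                  -2, -3), 0.01)),
    "insufficient")
})

test_that("monoexponential fit methods behave like a model object", {
  delays <- seq(0.02, 1.2, length.out = 8)
  f <- fit_monoexponential(decay_series(4, delays,
                                        2 * exp(-3 * delays), 0.01))
  expect_named(coef(f), c("i0", "rate"))
  expect_equal(predict(f, 0), 2, tolerance = 1e-5)
  expect_equal(unname(residuals(f)), rep(0, 8), tolerance = 1e-6)
  expect_output(print(f), "Monoexponential")
})

test_that("compute_r2eff value and propagated sigma follow the formulas", {
  expect_equal(compute_r2eff(1, 1, 0.04, 0.01, 0.01)$value, 0)
  est <- compute_r2eff(0.5, 1, 0.04, 0.01, 0.01)
  expect_equal(est$value, log(2) / 0.04, tolerance = 1e-9)
  expect_equal(est$sigma, 25 * sqrt((0.01 / 0.5)^2 + 0.01^2),
               tolerance = 1e-12)
  expect_error(compute_r2eff(-0.1, 1, 0.04, 0.01, 0.01), "undefined rate")
})

test_that("hetNOE ratio and first-order error propagation", {
  expect_equal(compute_hetnoe(1, 1, 0.01, 0.01)$value, 1)
  est <- compute_hetnoe(0.8, 1.0, 0.01, 0.01)
  expect_equal(est$value, 0.8)
  expect_equal(est$sigma, 0.0128, tolerance = 1e-3)
  # flexible tails: negative saturated intensity is legitimate
  expect_equal(compute_hetnoe(-0.3, 1.0, 0.01, 0.01)$value, -0.3)
  expect_true(any(attr(compute_hetnoe(0.05, 0.02, 0.01, 0.01),
                       "unreliable")))
})

test_that("dispersion fitting: flat curves stay flat, exact curves fit", {
  sch <- cpmg_schedule()
  flat <- simulate_dispersion(exchange_params(0, 0, 0, 11), sch, 0)
  f <- fit_dispersion(flat)
  expect_identical(f$model, "flat")
  expect_identical(f$rex$value, 0)
  expect_gt(f$rex$sigma, 0)
  truth <- exchange_params(0.03, 1500, 500, 10)
  cu <- simulate_dispersion(truth, sch, 0)
  f2 <- fit_dispersion(cu)
  expect_identical(f2$model, "two_site")
  expect_gt(f2$rex$value, 0)
  expect_equal(f2$rex$value, model_rex(truth, sch), tolerance = 0.02)
  expect_equal(estimate_rex(f2)$value, f2$rex$value)
  expect_equal(estimate_rex(f)$value, 0)
  # consistency: Rex of the fit equals model_rex of the fitted parameters
  expect_equal(f2$rex$value, model_rex(f2$params, sch), tolerance = 1e-9)
})

test_that("flat-model selection controls false dispersion on noisy flat curves", {
  sch <- cpmg_schedule()
  p <- exchange_params(0, 0, 0, 12)
  picked_flat <- vapply(seq_len(60), function(i) {
    f <- fit_dispersion(simulate_dispersion(p, sch, 0.015,
                                            rng_seed = 900 + i))
    if (f$model == "two_site") expect_gte(f$rex$value, 0)
    f$model == "flat"
  }, logical(1))
  expect_gte(mean(picked_flat), 0.9)
})

test_that("dispersion fit methods: coef, predict, summary", {
  sch <- cpmg_schedule()
  truth <- exchange_params(0.03, 1500, 500, 10)
  f <- fit_dispersion(simulate_dispersion(truth, sch, 0))
  expect_named(coef(f), c("k_ex", "p_b", "delta_omega", "r2_0"))
  pr <- predict(f, c(25, 2000))
  expect_equal(pr[1] - pr[2], f$rex$value, tolerance = 1e-9)
  s <- summary(f)
  expect_identical(s$model, "two_site")
  expect_output(print(s), "two_site")
})
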