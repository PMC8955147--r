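test_that("polyexponential UIR evaluates correctly", {
  u1 <- uir_model(A = 2, lambda = 0.1)
  expect_equal(uir_evaluate(u1, 0), 2)
  u2 <- uir_model(A = c(1, 3), lambda = c(0.5, 0.05))
  expect_lt(uir_evaluate(u2, 1e5), 1e-10)
  # half-life: A = 1, lambda = 0.5 at t = ln(2)/0.5 gives 0.5
  u3 <- uir_model(A = 1, lambda = 0.5)
  expect_equal(uir_evaluate(u3, log(2) / 0.5), 0.5, tolerance = 1e-12)
  expect_error(uir_model(A = 1, lambda = 0), "positive")
  expect_error(uir_model(A = 1, lambda = -0.1), "positive")
})

test_that("input rate from linear release is constant with exact mass balance", {
  prof <- tibble::tibble(time_min = seq(0, 10), released_pct = 10 * seq(0, 10))
  rates <- input_rate_from_release(prof, dose_mg = 1, f_bio = 1, dt = 0.1)
  # derivative of linear release: dose * k0 / 100 = 0.1 mg/min
  expect_equal(rates$rate_mg_per_min, rep(0.1, 100), tolerance = 1e-9)
  expect_equal(sum(rates$rate_mg_per_min) * 0.1, 1, tolerance = 1e-12)
})

test_that("mass balance holds on a nano-emulsion-like profile (1.46 mg dose)", {
  prof <- simulate_release(preset = "nano_emulsion_like", noise_sd = 0)
  rates <- input_rate_from_release(prof, dose_mg = 1.46, dt = 0.01)
  released_last <- prof$released_pct[which.max(prof$time_min)] / 100
  expect_equal(sum(rates$rate_mg_per_min) * 0.01, 1.46 * released_last,
               tolerance = 0.005 * 1.46)
})

test_that("instantaneous release collapses to a single-bin rate of dose/dt", {
  prof <- tibble::tibble(time_min = c(0, 0.01), released_pct = c(0, 100))
  rates <- input_rate_from_release(prof, dose_mg = 2, dt = 0.01)
  expect_equal(nrow(rates), 1)
  expect_equal(rates$rate_mg_per_min, 2 / 0.01, tolerance = 1e-9)
})

test_that("non-monotone release beyond tolerance is rejected", {
  bad <- tibble::tibble(time_min = c(0, 2, 4, 6), released_pct = c(0, 50, 45, 80))
  expect_error(input_rate_from_release(bad, dose_mg = 1), "decreases")
  # a small analytical dip (< 2%) is flattened, not an error
  ok <- tibble::tibble(time_min = c(0, 2, 4, 6), released_pct = c(0, 50, 49, 80))
  expect_no_error(input_rate_from_release(ok, dose_mg = 1, dt = 0.1))
})

test_that("bolus input reproduces the UIR scaled by dose", {
  uir <- uir_model(A = c(5, 2), lambda = c(0.2, 0.02))
  dt <- 0.01
  D <- 3
  rates <- tibble::tibble(time_min = dt, rate_mg_per_min = D / dt)
  attr(rates, "dt") <- dt
  prof <- convolve_profiles(rates, uir)
  expected <- D * uir_evaluate(uir, prof$time_min - dt)
  expect_lt(max(abs(prof$concentration - expected)) / max(expected), 1e-9)
})

test_that("constant-rate input matches the analytic one-exponential solution", {
  A <- 4
  lambda <- 0.05
  R <- 0.2
  T_end <- 10
  dt <- 0.01
  uir <- uir_model(A = A, lambda = lambda)
  rates <- tibble::tibble(time_min = seq(dt, T_end, by = dt),
                          rate_mg_per_min = R)
  attr(rates, "dt") <- dt
  prof <- convolve_profiles(rates, uir)
  upto <- prof$time_min <= T_end
  truth <- zero_order_plasma(prof$time_min[upto], R, A, lambda, T_end)
  rel_err <- max(abs(prof$concentration[upto] - truth)) / max(truth)
  expect_lt(rel_err, 0.01)
  # long-time plateau R * A / lambda is approached before input ends
  long <- convolve_profiles(
    {r <- tibble::tibble(time_min = seq(dt, 400, by = dt),
                         rate_mg_per_min = R); attr(r, "dt") <- dt; r}, uir)
  c_ss <- R * A / lambda
  at_end <- long$concentration[which.min(abs(long$time_min - 400))]
  expect_equal(at_end, c_ss, tolerance = 0.01)
})

test_that("convolution is linear in dose and in UIR coefficients, and causal", {
  prof <- simulate_release(preset = "nano_emulsion_like", noise_sd = 0)
  uir <- placeholder_uir()
  p1 <- predict_plasma(prof, dose_mg = 1, uir = uir, dt = 0.05)
  p2 <- predict_plasma(prof, dose_mg = 2, uir = uir, dt = 0.05)
  expect_equal(2 * p1$metrics$cmax, p2$metrics$cmax, tolerance = 1e-12)
  expect_equal(p1$metrics$tmax_min, p2$metrics$tmax_min)
  # doubling the UIR coefficients doubles the concentrations
  uir2 <- uir_model(A = 2 * uir$A, lambda = uir$lambda)
  p3 <- predict_plasma(prof, dose_mg = 1, uir = uir2, dt = 0.05)
  expect_equal(2 * p1$profile$concentration, p3$profile$concentration,
               tolerance = 1e-12)
  # causality: delaying the input rate by delta delays the output by delta
  dt <- 0.05
  k <- 20  # delta = 1 min
  rates <- input_rate_from_release(prof, dose_mg = 1, dt = dt)
  r_shift <- tibble::tibble(
    time_min = seq_len(nrow(rates) + k) * dt,
    rate_mg_per_min = c(rep(0, k), rates$rate_mg_per_min))
  attr(r_shift, "dt") <- dt
  c0 <- convolve_profiles(rates, uir)
  cs <- convolve_profiles(r_shift, uir)
  expect_lt(max(cs$concentration[seq_len(k)]),
            1e-12 * max(cs$concentration))
  n <- min(nrow(c0), nrow(cs) - k)
  expect_equal(cs$concentration[k + seq_len(n)],
               c0$concentration[seq_len(n)], tolerance = 1e-9)
})

test_that("PK metrics report cmax, earliest tmax, and trapezoidal AUC", {
  m <- pk_metrics(tibble::tibble(time_min = c(0, 1, 2),
                                 concentration = c(0, 5, 3)))
  expect_equal(m$cmax, 5)
  expect_equal(m$tmax_min, 1)
  expect_equal(m$auc_0_last, 0 + 5 / 2 + (5 + 3) / 2)  # trapezoids
  # tie at the maximum: earliest time wins
  tie <- pk_metrics(tibble::tibble(time_min = 0:3,
                                   concentration = c(0, 7, 7, 1)))
  expect_equal(tie$tmax_min, 1)
  expect_warning(z <- pk_metrics(tibble::tibble(time_min = 0:2,
                                                concentration = c(0, 0, 0))),
                 "all-zero")
  expect_equal(z$cmax, 0)
  expect_equal(z$tmax_min, 0)
})

test_that("AUC conservation: AUC_C = f_bio * dose * released_frac * AUC_u within 1%", {
  prof <- simulate_release(preset = "nano_emulsion_like", noise_sd = 0)
  uir <- placeholder_uir()
  pred <- predict_plasma(prof, dose_mg = 1.46, uir = uir, f_bio = 1, dt = 0.01)
  released_last <- prof$released_pct[which.max(prof$time_min)] / 100
  expected_auc <- 1.46 * released_last * sum(uir$A / uir$lambda)
  expect_equal(pred$metrics$auc_0_last, expected_auc,
               tolerance = 0.01)
})

test_that("cmax converges monotonically under dt refinement", {
  prof <- simulate_release(preset = "nano_emulsion_like", noise_sd = 0)
  uir <- placeholder_uir()
  cmax <- vapply(c(0.08, 0.04, 0.02, 0.01), function(dt) {
    predict_plasma(prof, dose_mg = 1.46, uir = uir, dt = dt)$metrics$cmax
  }, numeric(1))
  # reference at the finest step
  ref <- predict_plasma(prof, dose_mg = 1.46, uir = uir,
                        dt = 0.005)$metrics$cmax
  errs <- abs(cmax - ref)
  expect_true(all(diff(errs) <= 1e-12))
  # halving dt from 0.02 to 0.01 moves cmax by < 0.5%
  expect_lt(abs(cmax[4] - cmax[3]) / cmax[4], 0.005)
})
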