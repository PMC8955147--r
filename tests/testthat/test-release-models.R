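test_that("model catalogue lists the nine models in canonical order with valid bounds", {
  cat9 <- release_models()
  expect_equal(cat9$model_id, c(
    "zero_order", "first_order", "higuchi", "korsmeyer_peppas",
    "hixson_crowell", "hopfenberg", "baker_lonsdale", "peppas_sahlin",
    "weibull"))
  expect_true(all(cat9$n_params >= 1))
  expect_equal(cat9$n_params, lengths(cat9$param_names))
  purrr::walk2(cat9$lower, cat9$upper, ~ expect_true(all(.x < .y)))
})

test_that("closed-form evaluation matches elementary cases", {
  expect_equal(evaluate_release("zero_order", 10, 0), 0)
  expect_equal(evaluate_release("zero_order", 10, 4), 40)
  # first-order asymptote
  expect_gt(evaluate_release("first_order", 0.3, 100), 99.99)
  # Weibull(beta = 1, Ti = 0, alpha = 1/k1) is exactly first order
  t <- c(0, 0.5, 2, 7)
  expect_equal(evaluate_release("weibull", c(1 / 0.3, 1, 0), t),
               evaluate_release("first_order", 0.3, t))
  # Korsmeyer-Peppas with n = 0.5 reduces to Higuchi
  expect_equal(evaluate_release("korsmeyer_peppas", c(5, 0.5), 4), 10)
  expect_equal(evaluate_release("higuchi", 5, 4), 10)
})

test_that("reduction identities hold across a time grid", {
  t <- seq(0, 8, by = 0.25)
  # KP(n = 1) == zero order
  expect_equal(evaluate_release("korsmeyer_peppas", c(6, 1), t),
               evaluate_release("zero_order", 6, t), tolerance = 1e-12)
  # Peppas-Sahlin(k2 = 0) == KP with m = n
  expect_equal(evaluate_release("peppas_sahlin", c(9, 0, 0.6), t),
               evaluate_release("korsmeyer_peppas", c(9, 0.6), t),
               tolerance = 1e-12)
  # Hopfenberg(n = 3) == Hixson-Crowell
  expect_equal(evaluate_release("hopfenberg", c(0.04, 3), t),
               evaluate_release("hixson_crowell", 0.04, t),
               tolerance = 1e-12)
})

test_that("erosion models clamp to exactly 100 once fully eroded, Weibull lags", {
  expect_equal(evaluate_release("hixson_crowell", 0.1, c(10, 12, 50)),
               c(100, 100, 100))
  expect_equal(evaluate_release("hopfenberg", c(0.2, 2), c(5, 6)), c(100, 100))
  expect_equal(evaluate_release("weibull", c(3, 1.5, 2), c(0, 1, 2)),
               c(0, 0, 0))
  expect_gt(evaluate_release("weibull", c(3, 1.5, 2), 3), 0)
})

test_that("Baker-Lonsdale release solves the implicit equation", {
  # boundary conventions
  expect_equal(baker_lonsdale_release(0.05, 0), 0)
  expect_equal(baker_lonsdale_release(0.05, 10), 100)  # kBL * t = 0.5
  # interior solution vs independent bisection oracle
  f <- baker_lonsdale_release(0.01, 10)
  expect_equal(f, bl_bisect(0.1), tolerance = 1e-8)
  expect_lt(abs(bl_lhs(f) - 0.1), 1e-9)
  # round trip across times: recompute kBL * t from the left side
  kbl <- 0.02
  t <- c(0.5, 2, 5, 12, 20)
  f_t <- baker_lonsdale_release(kbl, t)
  expect_equal(bl_lhs(f_t), pmin(kbl * t, 0.5), tolerance = 1e-9)
})

test_that("all models are bounded in [0, 100] and nondecreasing for positive parameters", {
  set.seed(42)
  t <- sort(c(0, runif(40, 0, 30)))
  draws <- list(
    zero_order = function() runif(1, 0.5, 30),
    first_order = function() runif(1, 0.01, 2),
    higuchi = function() runif(1, 1, 60),
    korsmeyer_peppas = function() c(runif(1, 1, 40), runif(1, 0.2, 1.5)),
    hixson_crowell = function() runif(1, 0.01, 0.5),
    hopfenberg = function() c(runif(1, 0.01, 0.5), runif(1, 1, 4)),
    baker_lonsdale = function() runif(1, 0.001, 0.1),
    peppas_sahlin = function() c(runif(1, 0, 30), runif(1, 0, 10),
                                 runif(1, 0.2, 0.9)),
    weibull = function() c(runif(1, 1, 50), runif(1, 0.3, 3), runif(1, 0, 5))
  )
  for (m in names(draws)) {
    for (rep in 1:5) {
      f <- evaluate_release(m, draws[[m]](), t)
      expect_true(all(f >= 0 & f <= 100), label = paste(m, "bounded"))
      expect_true(all(diff(f) >= -1e-9), label = paste(m, "monotone"))
    }
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(evaluate_release("nonsense", 1, 1), "unknown release model")
  expect_error(evaluate_release("weibull", c(1, 2), 1), "expects 3 parameter")
  expect_error(evaluate_release("zero_order", 5, -1), "nonnegative")
  expect_error(baker_lonsdale_release(-0.1, 1), "positive")
  expect_error(baker_lonsdale_release(0, 1), "positive")
})
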