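# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (no uniroot, no evaluate_release) so that they
# can serve as cross-checks.

# Baker-Lonsdale left-hand side
bl_lhs <- function(f) 1.5 * (1 - (1 - f / 100)^(2 / 3)) - f / 100

# Solve bl_lhs(F) = target by plain interval bisection on [0, 100].
bl_bisect <- function(target, iters = 60) {
  lo <- 0
  hi <- 100
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (bl_lhs(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Analytic plasma concentration for a constant input rate R (mass/min) on
# (0, T] convolved with a one-exponential UIR A * exp(-lambda t):
#   t <= T: C(t) = (R A / lambda) (1 - exp(-lambda t))
zero_order_plasma <- function(t, R, A, lambda, T_end) {
  ifelse(t <= T_end,
         R * A / lambda * (1 - exp(-lambda * t)),
         R * A / lambda * (exp(lambda * T_end) - 1) * exp(-lambda * t))
}

# The 8-point dissolution sampling grid used throughout
grid8 <- c(0, 1.5, 3, 4.5, 6, 7.5, 9, 13.5)

# Generating parameter sets used in recovery tests: values chosen so the
# model stays strictly inside (0, 100) on the positive grid points (no
# clamping) except the erosion models, which are allowed to complete.
recovery_cases <- function() {
  list(
    zero_order = c(k0 = 7),
    first_order = c(k1 = 0.25),
    higuchi = c(kH = 22),
    korsmeyer_peppas = c(kKP = 14, n = 0.75),
    hixson_crowell = c(kHC = 0.05),
    hopfenberg = c(kHB = 0.06, n = 2),
    baker_lonsdale = c(kBL = 0.025),
    peppas_sahlin = c(k1 = 15, k2 = 2, m = 0.4),
    weibull = c(alpha = 12, beta = 1.4, Ti = 0)
  )
}
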