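#' Catalogue of empirical drug-release models
#'
#' Nine closed-form (or, for Baker-Lonsdale, implicit) empirical models that
#' describe cumulative percent drug released `F(t)` from a matrix as a
#' function of time in minutes. These are the standard single-phase release
#' laws used to characterise dissolution profiles of fast-dissolving dosage
#' forms; the exponent of the Korsmeyer-Peppas power law classifies the
#' transport mechanism, the Weibull shape parameter distinguishes
#' exponential from sigmoidal release, and the Hopfenberg / Hixson-Crowell
#' forms describe surface-erosion-limited release.
#'
#' @details
#' The available models, their equations (`F` in percent, `t` in minutes)
#' and parameters are:
#'
#' | `model_id`         | equation                                               | parameters |
#' |--------------------|--------------------------------------------------------|------------|
#' | `zero_order`       | `F = k0 * t`                                           | `k0` (%/min) |
#' | `first_order`      | `F = 100 * (1 - exp(-k1 * t))`                         | `k1` (1/min) |
#' | `higuchi`          | `F = kH * sqrt(t)`                                     | `kH` (%/min^0.5) |
#' | `korsmeyer_peppas` | `F = kKP * t^n`                                        | `kKP` (%/min^n), `n` (-) |
#' | `hixson_crowell`   | `F = 100 * (1 - (1 - kHC * t)^3)`                      | `kHC` (1/min) |
#' | `hopfenberg`       | `F = 100 * (1 - (1 - kHB * t)^n)`                      | `kHB` (1/min), `n` (-) |
#' | `baker_lonsdale`   | `3/2 * (1 - (1 - F/100)^(2/3)) - F/100 = kBL * t`      | `kBL` (1/min) |
#' | `peppas_sahlin`    | `F = k1 * t^m + k2 * t^(2m)`                           | `k1` (%/min^m), `k2` (%/min^2m), `m` (-) |
#' | `weibull`          | `F = 100 * (1 - exp(-((t - Ti)^beta) / alpha))`        | `alpha` (min^beta), `beta` (-), `Ti` (min) |
#'
#' Conventions: all model values are clamped to `[0, 100]`. For the erosion
#' models (`hixson_crowell`, `hopfenberg`) times with `k * t >= 1` return
#' exactly 100 (the matrix is fully eroded; the raw form is undefined
#' there). For `baker_lonsdale` the left-hand side attains its maximum 1/2
#' at `F = 100`, so `kBL * t >= 0.5` returns 100. For `weibull`, times
#' `t <= Ti` (the lag) return 0. The Hopfenberg exponent `n` is treated as
#' a continuous parameter `>= 1` rather than being restricted to the
#' slab/cylinder/sphere integers 1, 2, 3, because fitted release data
#' rarely identify the geometry.
#'
#' @return A tibble with one row per model: `model_id`, `n_params`,
#'   `param_names` (list column of character vectors), `param_units`
#'   (list column), `lower` and `upper` (list columns of numeric bound
#'   vectors).
#' @seealso [evaluate_release()], [fit_release()], [rank_release_models()]
#' @export
#' @examples
#' release_models()
release_models <- function() {
  specs <- release_model_specs()
  tibble::tibble(
    model_id    = names(specs),
    n_params    = purrr::map_int(specs, ~ length(.x$param_names)),
    param_names = purrr::map(specs, "param_names"),
    param_units = purrr::map(specs, "param_units"),
    lower       = purrr::map(specs, "lower"),
    upper       = purrr::map(specs, "upper")
  )
}

# Internal registry. Bounds are generous boxes used by the bounded
# least-squares fitter; rate constants in 1/min or %/min^n as appropriate.
release_model_specs <- function() {
  list(
    zero_order = list(
      param_names = "k0",
      param_units = "%/min",
      lower = 1e-6, upper = 1e3
    ),
    first_order = list(
      param_names = "k1",
      param_units = "1/min",
      lower = 1e-6, upper = 50
    ),
    higuchi = list(
      param_names = "kH",
      param_units = "%/min^0.5",
      lower = 1e-6, upper = 1e3
    ),
    korsmeyer_peppas = list(
      param_names = c("kKP", "n"),
      param_units = c("%/min^n", "-"),
      lower = c(1e-6, 0.05), upper = c(1e3, 4)
    ),
    hixson_crowell = list(
      param_names = "kHC",
      param_units = "1/min",
      lower = 1e-6, upper = 50
    ),
    hopfenberg = list(
      param_names = c("kHB", "n"),
      param_units = c("1/min", "-"),
      lower = c(1e-6, 1), upper = c(50, 20)
    ),
    baker_lonsdale = list(
      param_names = "kBL",
      param_units = "1/min",
      lower = 1e-8, upper = 10
    ),
    peppas_sahlin = list(
      param_names = c("k1", "k2", "m"),
      param_units = c("%/min^m", "%/min^2m", "-"),
      lower = c(0, 0, 0.05), upper = c(1e3, 1e3, 2)
    ),
    weibull = list(
      param_names = c("alpha", "beta", "Ti"),
      param_units = c("min^beta", "-", "min"),
      lower = c(1e-6, 0.05, 0), upper = c(1e8, 10, 60)
    )
  )
}

release_model_ids <- function() names(release_model_specs())

check_model_id <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1 ||
      !model_id %in% release_model_ids()) {
    stop("unknown release model id: ", paste(model_id, collapse = ", "),
         ". Known models: ", paste(release_model_ids(), collapse = ", "),
         call. = FALSE)
  }
  model_id
}

check_params <- function(model_id, params) {
  spec <- release_model_specs()[[model_id]]
  params <- as.numeric(params)
  if (length(params) != length(spec$param_names)) {
    stop(sprintf("model '%s' expects %d parameter(s) (%s), got %d",
                 model_id, length(spec$param_names),
                 paste(spec$param_names, collapse = ", "), length(params)),
         call. = FALSE)
  }
  if (any(!is.finite(params))) {
    stop("parameters must be finite", call. = FALSE)
  }
  names(params) <- spec$param_names
  params
}

check_times <- function(times) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and nonnegative (minutes)", call. = FALSE)
  }
  times
}

#' Evaluate an empirical release model
#'
#' Computes cumulative percent released `F(t)` for one of the nine
#' empirical release models at the given times.
#'
#' @param model_id One of the ids listed by [release_models()].
#' @param params Numeric vector of model parameters, in the order given by
#'   `release_models()$param_names` for that model.
#' @param times Numeric vector of times in minutes (nonnegative).
#' @return Numeric vector of percent released, clamped to `[0, 100]`.
#' @export
#' @examples
#' evaluate_release("first_order", 0.3, c(0, 2, 5, 100))
#' evaluate_release("weibull", c(1 / 0.3, 1, 0), c(0, 2, 5))
evaluate_release <- function(model_id, params, times) {
  check_model_id(model_id)
  p <- check_params(model_id, params)
  t <- check_times(times)
  f <- switch(model_id,
    zero_order = p[["k0"]] * t,
    first_order = 100 * (1 - exp(-p[["k1"]] * t)),
    higuchi = p[["kH"]] * sqrt(t),
    korsmeyer_peppas = p[["kKP"]] * t^p[["n"]],
    hixson_crowell = erosion_release(p[["kHC"]], 3, t),
    hopfenberg = erosion_release(p[["kHB"]], p[["n"]], t),
    baker_lonsdale = baker_lonsdale_release(p[["kBL"]], t),
    peppas_sahlin = p[["k1"]] * t^p[["m"]] + p[["k2"]] * t^(2 * p[["m"]]),
    weibull = weibull_release(p[["alpha"]], p[["beta"]], p[["Ti"]], t)
  )
  pmin(pmax(f, 0), 100)
}

# F = 100 * (1 - (1 - k t)^n); fully eroded (F = 100) once k t >= 1.
erosion_release <- function(k, n, t) {
  core <- 1 - k * t
  ifelse(core <= 0, 100, 100 * (1 - core^n))
}

# Lag-time Weibull; t <= Ti returns 0.
weibull_release <- function(alpha, beta, ti, t) {
  ifelse(t <= ti, 0, 100 * (1 - exp(-((t - ti)^beta) / alpha)))
}

#' Baker-Lonsdale release by bracketed root finding
#'
#' The Baker-Lonsdale model for diffusion from a spherical matrix is
#' implicit in `F`: `3/2 * (1 - (1 - F/100)^(2/3)) - F/100 = kBL * t`.
#' The left-hand side increases monotonically from 0 at `F = 0` to its
#' maximum 1/2 at `F = 100`, so for `kBL * t >= 0.5` release is complete
#' and `F = 100` is returned; otherwise `F` is solved on `[0, 100]` by
#' [stats::uniroot()] to an absolute tolerance below 1e-9.
#'
#' @param kbl Rate constant in 1/min; must be positive.
#' @param times Numeric vector of times in minutes.
#' @return Numeric vector of percent released.
#' @export
#' @examples
#' baker_lonsdale_release(0.01, c(0, 5, 10, 50))
baker_lonsdale_release <- function(kbl, times) {
  if (!is.numeric(kbl) || length(kbl) != 1 || !is.finite(kbl) || kbl <= 0) {
    stop("kbl must be a single positive number", call. = FALSE)
  }
  t <- check_times(times)
  lhs <- function(f) 1.5 * (1 - (1 - f / 100)^(2 / 3)) - f / 100
  vapply(t, function(ti) {
    target <- kbl * ti
    if (target <= 0) return(0)
    if (target >= 0.5) return(100)
    stats::uniroot(function(f) lhs(f) - target,
                   interval = c(0, 100),
                   tol = 1e-12, maxiter = 2000L)$root
  }, numeric(1))
}
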