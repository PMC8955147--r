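#' Standard dissolution sampling grid
#'
#' The 8-point sampling schedule of a fast-dissolving buccal film
#' dissolution experiment: 0, 1.5, 3, 4.5, 6, 7.5, 9 and 13.5 minutes.
#'
#' @return Numeric vector of times in minutes.
#' @export
dissolution_grid <- function() c(0, 1.5, 3, 4.5, 6, 7.5, 9, 13.5)

#' Release-profile presets for the two solubilisation arms
#'
#' Two canned generating models emulating the measured release behaviour
#' of the study arms:
#' \describe{
#'   \item{`nano_emulsion_like`}{Hopfenberg, `kHB = 0.132` 1/min,
#'     `n = 1.05`: about 80% released at 6 min and >= 98% at 7.5 min
#'     (complete release by 9 min), the fast nano-emulsion arm.}
#'   \item{`cosolvency_like`}{Weibull, `alpha = 1965`, `beta = 3.5`,
#'     `Ti = 0`: about 80% at 10 min and near-complete release by 13 min,
#'     the slower co-solvency arm.}
#' }
#'
#' @param preset Preset name.
#' @return List with `model_id` and `params`.
#' @export
release_preset <- function(preset = c("nano_emulsion_like", "cosolvency_like")) {
  preset <- match.arg(preset)
  switch(preset,
    nano_emulsion_like = list(model_id = "hopfenberg",
                              params = c(kHB = 0.132, n = 1.05)),
    cosolvency_like = list(model_id = "weibull",
                           params = c(alpha = 1965, beta = 3.5, Ti = 0))
  )
}

#' Simulate a dissolution profile
#'
#' Evaluates a release model on a time grid and adds independent Gaussian
#' noise (in percent points), clamped to `[0, 105]` to mimic analytical
#' overshoot limits. With a fixed `seed` the output is bitwise
#' reproducible; the global random state is untouched.
#'
#' @param model_id,params Generating model and parameters (see
#'   [release_models()]); ignored when `preset` is given.
#' @param preset Optional preset name (see [release_preset()]).
#' @param times Sampling grid in minutes; defaults to [dissolution_grid()].
#' @param noise_sd Gaussian noise SD in percent points (default 1).
#' @param seed Optional integer seed.
#' @param label Arm label stored in the `label` column.
#' @return Tibble with `time_min`, `released_pct`, `label`.
#' @export
#' @examples
#' simulate_release(preset = "nano_emulsion_like", noise_sd = 0)
simulate_release <- function(model_id = NULL, params = NULL, preset = NULL,
                             times = dissolution_grid(), noise_sd = 1,
                             seed = NULL, label = NULL) {
  if (!is.null(preset)) {
    gen <- release_preset(preset)
    model_id <- gen$model_id
    params <- gen$params
    if (is.null(label)) label <- preset
  }
  if (is.null(model_id) || is.null(params)) {
    stop("supply either a preset or model_id + params", call. = FALSE)
  }
  if (is.null(label)) label <- model_id
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  f <- evaluate_release(model_id, params, times)
  noisy <- function() {
    if (noise_sd > 0) {
      y <- f + stats::rnorm(length(f), sd = noise_sd)
      # t = 0 stays exactly 0: the blank sample contains no drug
      y[times == 0] <- 0
      pmin(pmax(y, 0), 105)
    } else {
      f
    }
  }
  y <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
  tibble::tibble(time_min = times, released_pct = y, label = label)
}

#' Simulate a Franz-cell permeation series
#'
#' Generates receptor-chamber concentrations whose corrected cumulative
#' permeated amount follows `Q(t) = max(0, jss_true * (t - lag) / 60)`
#' ug/cm^2 — a lag phase followed by a linear steady-state segment. The
#' target Q is inverted through the sampling-replacement correction
#' (`C_n = (A * Q_n - V_s * sum_{i<n} C_i) / V_r`), so round-tripping the
#' noise-free series through [cumulative_permeated()] and
#' [steady_state_flux()] recovers `jss_true` exactly. Gaussian noise (in
#' ug/mL) is then added to the concentrations.
#'
#' @param jss_true True steady-state flux (ug cm^-2 h^-1), >= 0.
#' @param lag_min Lag time before permeation starts (minutes).
#' @param times Sampling times in minutes.
#' @param geometry A [franz_cell()].
#' @param noise_sd Concentration noise SD in ug/mL (default 0.01).
#' @param seed Optional integer seed.
#' @return Tibble with `time_min` and `receptor_conc_ug_per_ml`.
#' @export
#' @examples
#' simulate_permeation(jss_true = 0.121, lag_min = 120, noise_sd = 0)
simulate_permeation <- function(jss_true, lag_min = 120,
                                times = seq(0, 480, by = 30),
                                geometry = franz_cell(), noise_sd = 0.01,
                                seed = NULL) {
  if (!is.numeric(jss_true) || jss_true < 0) {
    stop("jss_true must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(geometry, "franz_cell"))
  times <- sort(unique(as.numeric(times)))
  q_target <- pmax(0, jss_true * (times - lag_min) / 60)
  conc <- numeric(length(times))
  prior <- 0
  for (i in seq_along(times)) {
    conc[i] <- (geometry$diffusion_area_cm2 * q_target[i] -
                  geometry$sample_volume_ml * prior) /
      geometry$receptor_volume_ml
    conc[i] <- max(conc[i], 0)
    prior <- prior + conc[i]
  }
  noisy <- function() pmax(conc + stats::rnorm(length(conc), sd = noise_sd), 0)
  y <- if (noise_sd > 0) {
    if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
  } else {
    conc
  }
  tibble::tibble(time_min = times, receptor_conc_ug_per_ml = y)
}

#' Placeholder unit impulse response for pipeline testing
#'
#' A documented two-exponential disposition kernel with plausible scale
#' for a rapidly distributed, lipophilic steroid given intravenously —
#' distribution half-life about 5 min, elimination half-life about 46 min.
#' It is a synthetic stand-in flagged `non_paper = TRUE`: predictions made
#' with it exercise the convolution machinery but are not literature-based
#' plasma predictions. Supply your own [uir_model()] fitted to
#' intravenous data for real use.
#'
#' @return A [uir_model()] with two terms, `A` in ng/mL per mg dose.
#' @export
#' @examples
#' placeholder_uir()
placeholder_uir <- function() {
  uir_model(A = c(600, 150), lambda = c(0.15, 0.015),
            dose_unit = "mg", concentration_unit = "ng/mL",
            non_paper = TRUE)
}
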