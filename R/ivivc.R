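#' Polyexponential unit impulse response (UIR)
#'
#' Constructs the convolution kernel `u(t) = sum(A_i * exp(-lambda_i * t))`
#' describing the plasma concentration-time course that follows a unit
#' intravenous dose. The coefficients `A_i` carry units of concentration
#' per unit dose (e.g. ng/mL per mg) and the rates `lambda_i` are in
#' 1/min. The predicted plasma profile inherits the UIR's concentration
#' unit; no rescaling is performed.
#'
#' @param A Numeric vector of coefficients (concentration per unit dose).
#' @param lambda Numeric vector of positive rates (1/min), same length.
#' @param dose_unit,concentration_unit Unit labels carried into outputs.
#' @param non_paper Logical metadata flag marking parameter sets that are
#'   synthetic placeholders rather than literature values.
#' @return An object of class `uir_model`.
#' @seealso [uir_evaluate()], [predict_plasma()], [placeholder_uir()]
#' @export
#' @examples
#' uir_model(A = c(2, 1), lambda = c(0.1, 0.01))
uir_model <- function(A, lambda, dose_unit = "mg",
                      concentration_unit = "ng/mL", non_paper = FALSE) {
  A <- as.numeric(A)
  lambda <- as.numeric(lambda)
  if (length(A) == 0 || length(A) != length(lambda)) {
    stop("A and lambda must be nonempty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(A)) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("all lambda must be positive and all coefficients finite",
         call. = FALSE)
  }
  u <- structure(
    list(A = A, lambda = lambda, dose_unit = dose_unit,
         concentration_unit = concentration_unit, non_paper = isTRUE(non_paper)),
    class = "uir_model")
  probe <- uir_evaluate(u, seq(0, 10 / min(lambda), length.out = 512))
  if (any(probe < 0)) {
    stop("UIR must be nonnegative on t >= 0 for these coefficients",
         call. = FALSE)
  }
  u
}

#' @export
print.uir_model <- function(x, ...) {
  cat(sprintf("<uir_model: %d exponential term(s)%s>\n", length(x$A),
              if (x$non_paper) ", placeholder (non-literature)" else ""))
  cat(sprintf("  u(t) [%s per %s] = %s\n", x$concentration_unit, x$dose_unit,
              paste(sprintf("%.4g*exp(-%.4g t)", x$A, x$lambda),
                    collapse = " + ")))
  invisible(x)
}

#' Evaluate a unit impulse response
#'
#' @param uir A [uir_model()].
#' @param times Nonnegative times in minutes.
#' @return Concentrations per unit dose at `times`.
#' @export
uir_evaluate <- function(uir, times) {
  stopifnot(inherits(uir, "uir_model"))
  t <- check_times(times)
  colSums(uir$A * exp(-outer(uir$lambda, t)))
}

# AUC of u from 0 to infinity: sum(A_i / lambda_i)
uir_auc <- function(uir) sum(uir$A / uir$lambda)

#' Systemic input rate from a dissolution profile
#'
#' Converts cumulative percent released into the drug input rate `I(t)`
#' (mass per minute entering the systemic circulation) on a uniform time
#' grid. The cumulative absorbed mass
#' `M(t) = f_bio * dose_mg * F(t) / 100` is interpolated with a monotone
#' shape-preserving piecewise cubic (Fritsch-Carlson, via
#' [stats::splinefun()] `method = "monoH.FC"`) — an ordinary cubic spline
#' can overshoot 100% and create negative rates — then differentiated by
#' forward differences over each bin. Any residual negative rate is
#' clamped to zero. Because forward differences telescope, the mass
#' balance `sum(rate) * dt = M(t_last)` holds to numerical precision.
#'
#' @param data Dissolution profile data frame (`time_min`, `released_pct`).
#' @param dose_mg Drug mass represented by 100% release, in mg.
#' @param f_bio Bioavailability fraction in (0, 1]; default 1 (complete
#'   buccal absorption).
#' @param dt Grid step in minutes (default 0.01).
#' @return Tibble with `time_min` (bin right edges `dt, 2*dt, ...`) and
#'   `rate_mg_per_min`, with attributes `dose_mg`, `f_bio`, `dt`.
#' @export
#' @examples
#' prof <- tibble::tibble(time_min = 0:10, released_pct = 10 * (0:10))
#' rates <- input_rate_from_release(prof, dose_mg = 1, dt = 0.1)
#' sum(rates$rate_mg_per_min) * 0.1  # = 1 mg
input_rate_from_release <- function(data, dose_mg, f_bio = 1, dt = 0.01) {
  prof <- check_profile(data)
  if (!is.numeric(dose_mg) || dose_mg <= 0) {
    stop("dose_mg must be positive", call. = FALSE)
  }
  if (!is.numeric(f_bio) || f_bio <= 0 || f_bio > 1) {
    stop("f_bio must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)

  t_obs <- prof$time_min
  f_obs <- prof$released_pct
  dips <- diff(f_obs)
  if (any(dips < -2)) {
    stop("cumulative release decreases by more than 2% between time points",
         call. = FALSE)
  }
  # small analytical dips are flattened to keep the cumulative curve monotone
  f_mono <- cummax(f_obs)
  if (min(diff(t_obs)) < dt) {
    warning("dt is larger than the smallest observation gap", call. = FALSE)
  }
  if (t_obs[1] > 0) {
    t_obs <- c(0, t_obs)
    f_mono <- c(0, f_mono)
  }

  m_of_t <- stats::splinefun(t_obs, f_bio * dose_mg * f_mono / 100,
                             method = "monoH.FC")
  t_end <- max(t_obs)
  n <- ceiling(t_end / dt - 1e-9)
  edges <- seq(0, by = dt, length.out = n + 1)
  m <- m_of_t(pmin(edges, t_end))
  rate <- pmax(diff(m), 0) / dt
  # mass already released at t = 0 enters as a first-bin bolus
  if (m[1] > 0) rate[1] <- rate[1] + m[1] / dt

  out <- tibble::tibble(time_min = edges[-1], rate_mg_per_min = rate)
  attr(out, "dose_mg") <- dose_mg
  attr(out, "f_bio") <- f_bio
  attr(out, "dt") <- dt
  out
}

#' Convolve an input rate with a unit impulse response
#'
#' Discretises `C(t) = integral_0^t I(x) u(t - x) dx` as the left-rectangle
#' sum `C[k] = sum_{j <= k} I[j] * u((k - j) * dt) * dt` on the uniform
#' input grid — the discrete convolution, scaled by `dt`. The output grid
#' extends beyond the last input time until the concentration has fallen
#' below 0.1% of its maximum (or `horizon_min` is reached), so the full
#' disposition tail is captured. The result is linear in both the dose and
#' the UIR coefficients.
#'
#' @param rates Input-rate tibble from [input_rate_from_release()], or any
#'   data frame with uniformly spaced `time_min` and `rate_mg_per_min`.
#' @param uir A [uir_model()].
#' @param horizon_min Optional hard cap on the output horizon (minutes).
#' @return Tibble `time_min`, `concentration` (UIR's concentration unit),
#'   with attributes `dt` and `concentration_unit`.
#' @export
convolve_profiles <- function(rates, uir, horizon_min = NULL) {
  stopifnot(inherits(uir, "uir_model"))
  if (!is.data.frame(rates) || nrow(rates) == 0) {
    stop("rates must be a nonempty data frame", call. = FALSE)
  }
  need <- c("time_min", "rate_mg_per_min")
  if (!all(need %in% names(rates))) {
    stop("rates needs columns time_min and rate_mg_per_min", call. = FALSE)
  }
  t_in <- rates$time_min
  r <- rates$rate_mg_per_min
  dt <- attr(rates, "dt")
  if (is.null(dt)) dt <- stats::median(diff(c(0, t_in)))
  if (length(t_in) > 1 &&
      max(abs(diff(t_in) - dt)) > 1e-8 * max(dt, 1)) {
    stop("input rate grid must be uniform", call. = FALSE)
  }

  # horizon: input end plus time for the slowest UIR mode to decay ~1e-4
  tail_min <- log(1e4) / min(uir$lambda)
  horizon <- max(t_in) + tail_min
  if (!is.null(horizon_min)) horizon <- min(horizon, horizon_min)
  n_out <- ceiling(horizon / dt)

  u <- uir_evaluate(uir, (seq_len(n_out) - 1) * dt)
  r_pad <- c(r, rep(0, n_out - length(r)))
  # C[k] = dt * sum_j r[j] u[k - j]; full linear convolution via FFT
  conv <- stats::convolve(r_pad, rev(u), type = "open")[seq_len(n_out)] * dt
  conv <- pmax(conv, 0)
  times <- seq_len(n_out) * dt

  # truncate once the tail has fallen below 0.1% of Cmax
  cmax <- max(conv)
  k_max <- which.max(conv)
  below <- which(conv < 1e-3 * cmax & seq_along(conv) > k_max)
  keep <- if (length(below) > 0) seq_len(below[1]) else seq_len(n_out)

  out <- tibble::tibble(time_min = times[keep], concentration = conv[keep])
  attr(out, "dt") <- dt
  attr(out, "concentration_unit") <- uir$concentration_unit
  out
}

#' Peak and exposure metrics of a plasma profile
#'
#' @param profile Data frame with `time_min` and `concentration`.
#' @return One-row tibble: `cmax`, `tmax_min` (earliest time attaining the
#'   maximum), `auc_0_last` (trapezoidal, concentration x min).
#' @export
#' @examples
#' pk_metrics(tibble::tibble(time_min = c(0, 1, 2), concentration = c(0, 5, 3)))
pk_metrics <- function(profile) {
  if (!is.data.frame(profile) || nrow(profile) == 0) {
    stop("profile must be a nonempty data frame", call. = FALSE)
  }
  t <- profile$time_min
  c_t <- profile$concentration
  if (all(c_t == 0)) {
    warning("all-zero plasma profile", call. = FALSE)
    return(tibble::tibble(cmax = 0, tmax_min = 0, auc_0_last = 0))
  }
  k <- which.max(c_t)  # which.max returns the earliest maximum
  auc <- sum(diff(t) * (utils::head(c_t, -1) + utils::tail(c_t, -1)) / 2)
  tibble::tibble(cmax = c_t[k], tmax_min = t[k], auc_0_last = auc)
}

#' Predict the in-vivo plasma profile from in-vitro release
#'
#' End-to-end in-vitro/in-vivo convolution: the dissolution profile is
#' converted to a systemic input rate ([input_rate_from_release()]),
#' convolved with the unit impulse response ([convolve_profiles()]), and
#' summarised ([pk_metrics()]). With complete release the conservation law
#' `AUC_C = f_bio * dose * AUC_u` holds up to discretisation error.
#'
#' @inheritParams input_rate_from_release
#' @param uir A [uir_model()].
#' @param horizon_min Optional output horizon cap (minutes).
#' @return An object of class `plasma_prediction`; `tidy()` returns the
#'   predicted concentration-time tibble, `glance()` the PK metrics with
#'   dose and settings.
#' @export
#' @examples
#' prof <- simulate_release(preset = "nano_emulsion_like", noise_sd = 0)
#' pred <- predict_plasma(prof, dose_mg = 1.46, uir = placeholder_uir(), dt = 0.05)
#' generics::glance(pred)
predict_plasma <- function(data, dose_mg, uir, f_bio = 1, dt = 0.01,
                           horizon_min = NULL) {
  rates <- input_rate_from_release(data, dose_mg = dose_mg, f_bio = f_bio,
                                   dt = dt)
  profile <- convolve_profiles(rates, uir, horizon_min = horizon_min)
  metrics <- pk_metrics(profile)
  structure(
    list(profile = profile, metrics = metrics, rates = rates, uir = uir,
         dose_mg = dose_mg, f_bio = f_bio, dt = dt),
    class = "plasma_prediction")
}

#' @export
print.plasma_prediction <- function(x, ...) {
  cat("<plasma_prediction>\n")
  cat(sprintf("  dose %.4g %s, bioavailability %.0f%%, dt = %g min\n",
              x$dose_mg, x$uir$dose_unit, 100 * x$f_bio, x$dt))
  cat(sprintf("  Cmax = %.4g %s at Tmax = %.4g min; AUC(0-last) = %.4g %s*min\n",
              x$metrics$cmax, x$uir$concentration_unit, x$metrics$tmax_min,
              x$metrics$auc_0_last, x$uir$concentration_unit))
  invisible(x)
}

#' @rdname predict_plasma
#' @param x A `plasma_prediction`.
#' @param ... Unused.
#' @method tidy plasma_prediction
#' @export
tidy.plasma_prediction <- function(x, ...) x$profile

#' @rdname predict_plasma
#' @method glance plasma_prediction
#' @export
glance.plasma_prediction <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(dose_mg = x$dose_mg, f_bio = x$f_bio, dt = x$dt,
                   concentration_unit = x$uir$concentration_unit)
  )
}
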