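#' Franz diffusion-cell geometry
#'
#' @param diffusion_area_cm2 Exposed tissue area (cm^2).
#' @param receptor_volume_ml Receptor chamber volume (mL).
#' @param sample_volume_ml Volume withdrawn (and replaced) at each sampling
#'   point (mL). Zero disables the sampling-replacement correction.
#' @return A `franz_cell` list.
#' @export
#' @examples
#' franz_cell()  # the common 2.54 cm2 / 5.2 mL / 1 mL configuration
franz_cell <- function(diffusion_area_cm2 = 2.54, receptor_volume_ml = 5.2,
                       sample_volume_ml = 1) {
  if (diffusion_area_cm2 <= 0 || receptor_volume_ml <= 0 ||
      sample_volume_ml < 0) {
    stop("area and receptor volume must be positive; sample volume >= 0",
         call. = FALSE)
  }
  if (sample_volume_ml > receptor_volume_ml) {
    stop("sample volume cannot exceed receptor volume", call. = FALSE)
  }
  structure(list(diffusion_area_cm2 = diffusion_area_cm2,
                 receptor_volume_ml = receptor_volume_ml,
                 sample_volume_ml = sample_volume_ml),
            class = "franz_cell")
}

check_permeation <- function(data) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with columns time_min and receptor_conc_ug_per_ml",
         call. = FALSE)
  }
  need <- c("time_min", "receptor_conc_ug_per_ml")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(data), .data$time_min)
  if (anyDuplicated(out$time_min)) {
    stop("duplicated sampling times", call. = FALSE)
  }
  if (any(out$receptor_conc_ug_per_ml < 0)) {
    stop("receptor concentrations must be nonnegative", call. = FALSE)
  }
  out
}

#' Cumulative permeated amount per unit area
#'
#' Converts measured receptor-chamber concentrations into cumulative drug
#' permeated per unit diffusion area, correcting for the mass removed by
#' sampling with replacement. With receptor volume `V_r`, sample volume
#' `V_s` and area `A`, the standard correction is
#' `Q_n = (V_r * C_n + V_s * sum_{i<n} C_i) / A` (micrograms per cm^2):
#' each earlier withdrawal removed `V_s * C_i` of drug that must be added
#' back. With `V_s = 0` this reduces to the naive `V_r * C_n / A`.
#'
#' @param data Data frame with `time_min` and `receptor_conc_ug_per_ml`.
#' @param geometry A [franz_cell()].
#' @return The input tibble with an added `cumulative_q_ug_per_cm2` column.
#' @export
#' @examples
#' d <- tibble::tibble(time_min = c(60, 120), receptor_conc_ug_per_ml = c(1, 1))
#' cumulative_permeated(d, franz_cell())
cumulative_permeated <- function(data, geometry = franz_cell()) {
  stopifnot(inherits(geometry, "franz_cell"))
  ser <- check_permeation(data)
  conc <- ser$receptor_conc_ug_per_ml
  prior <- dplyr::lag(cumsum(conc), default = 0)
  q <- (geometry$receptor_volume_ml * conc +
          geometry$sample_volume_ml * prior) / geometry$diffusion_area_cm2
  dplyr::mutate(ser, cumulative_q_ug_per_cm2 = q)
}

#' Steady-state flux from the linear portion of a permeation curve
#'
#' Ordinary least-squares slope of cumulative permeated amount versus time
#' over a stated window (closed interval, endpoints included), converted
#' to per-hour units. The window defaults to 360-480 minutes, the late
#' linear phase of a buccal permeation experiment.
#'
#' @param data Either the output of [cumulative_permeated()] or a raw
#'   concentration table (in which case `geometry` is used to compute Q).
#' @param window Length-2 numeric, window start and end in minutes.
#' @param geometry A [franz_cell()], used when `cumulative_q_ug_per_cm2`
#'   is absent.
#' @return An object of class `flux_fit`; `glance()` gives a one-row
#'   tibble with `jss_ug_cm2_h`, `window_start_min`, `window_end_min`,
#'   `r_squared`, `n_points`.
#' @export
#' @examples
#' d <- tibble::tibble(time_min = seq(0, 480, 60),
#'                     receptor_conc_ug_per_ml = NA)
#' q <- 0.002017 * d$time_min
#' flux <- steady_state_flux(
#'   dplyr::mutate(d, cumulative_q_ug_per_cm2 = q), window = c(360, 480))
#' generics::glance(flux)
steady_state_flux <- function(data, window = c(360, 480),
                              geometry = franz_cell()) {
  if (!is.numeric(window) || length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(start, end) minutes with start < end",
         call. = FALSE)
  }
  if (!"cumulative_q_ug_per_cm2" %in% names(data)) {
    data <- cumulative_permeated(data, geometry)
  }
  inw <- data$time_min >= window[1] & data$time_min <= window[2]
  if (sum(inw) < 2) {
    stop(sprintf("need at least 2 points inside window [%g, %g] min, found %d",
                 window[1], window[2], sum(inw)), call. = FALSE)
  }
  sub <- data[inw, , drop = FALSE]
  fit <- stats::lm(cumulative_q_ug_per_cm2 ~ time_min, data = sub)
  slope_per_min <- stats::coef(fit)[["time_min"]]
  r2 <- if (stats::var(sub$cumulative_q_ug_per_cm2) == 0) {
    1  # perfectly flat window: slope 0 fits exactly
  } else {
    summary(fit)$r.squared
  }
  structure(
    list(jss_ug_cm2_h = slope_per_min * 60, window = window,
         r_squared = r2, n_points = sum(inw), lm = fit, data = sub),
    class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf(
    "<flux_fit> Jss = %.4g ug cm-2 h-1 over [%g, %g] min (R2 = %.4f, n = %d)\n",
    x$jss_ug_cm2_h, x$window[1], x$window[2], x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname steady_state_flux
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(
    jss_ug_cm2_h = x$jss_ug_cm2_h,
    window_start_min = x$window[1], window_end_min = x$window[2],
    r_squared = x$r_squared, n_points = x$n_points
  )
}

#' @rdname steady_state_flux
#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept_ug_cm2", "slope_ug_cm2_min"),
    estimate = unname(stats::coef(x$lm))
  )
}

#' Apparent permeability coefficient
#'
#' `Papp = Jss / Cd`, where `Jss` is the steady-state flux and `Cd` the
#' initial drug concentration in the donor compartment. The donor
#' concentration must be supplied explicitly (its definition — loaded dose
#' over wetting volume, or otherwise — is a study-level choice).
#'
#' @param jss_ug_cm2_h Steady-state flux (ug cm^-2 h^-1), or a `flux_fit`.
#' @param cd_ug_per_cm3 Initial donor concentration (ug/cm^3 = ug/mL).
#' @return Apparent permeability in cm/h.
#' @export
#' @examples
#' apparent_permeability(0.121, cd_ug_per_cm3 = 1460 / 0.4)
apparent_permeability <- function(jss_ug_cm2_h, cd_ug_per_cm3) {
  if (inherits(jss_ug_cm2_h, "flux_fit")) {
    jss_ug_cm2_h <- jss_ug_cm2_h$jss_ug_cm2_h
  }
  if (!is.numeric(cd_ug_per_cm3) || length(cd_ug_per_cm3) != 1 ||
      cd_ug_per_cm3 <= 0) {
    stop("cd_ug_per_cm3 must be a single positive number", call. = FALSE)
  }
  jss_ug_cm2_h / cd_ug_per_cm3
}
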