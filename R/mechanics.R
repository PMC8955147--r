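#' Tensile strength of film specimens
#'
#' Tensile strength is the force at break divided by the specimen's
#' cross-sectional area; with force in newtons and area in mm^2 the result
#' is in MPa (N/mm^2 = MPa).
#'
#' @param data Data frame with columns `f_max_n` (force at break, N) and
#'   `cross_section_mm2` (cross-sectional area, mm^2).
#' @return The input tibble with an added `tensile_strength_mpa` column.
#' @export
#' @examples
#' tensile_strength(tibble::tibble(f_max_n = 1, cross_section_mm2 = 2))
tensile_strength <- function(data) {
  need <- c("f_max_n", "cross_section_mm2")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(data$cross_section_mm2 <= 0)) {
    stop("cross_section_mm2 must be positive", call. = FALSE)
  }
  if (any(data$f_max_n < 0)) {
    stop("f_max_n must be nonnegative", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                tensile_strength_mpa = .data$f_max_n / .data$cross_section_mm2)
}

#' Percent elongation at break
#'
#' The standard definition: extension at break over initial gauge length,
#' times 100. Scale-invariant under consistent unit rescaling.
#'
#' @param data Data frame with columns `extension_at_break_mm` and
#'   `initial_length_mm`.
#' @return The input tibble with an added `elongation_pct` column.
#' @export
#' @examples
#' percent_elongation(tibble::tibble(extension_at_break_mm = 1.105,
#'                                   initial_length_mm = 10))
percent_elongation <- function(data) {
  need <- c("extension_at_break_mm", "initial_length_mm")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(data$initial_length_mm <= 0)) {
    stop("initial_length_mm must be positive", call. = FALSE)
  }
  if (any(data$extension_at_break_mm < 0)) {
    stop("extension_at_break_mm must be nonnegative", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                elongation_pct = 100 * .data$extension_at_break_mm /
                  .data$initial_length_mm)
}

#' Group summary (mean +/- SD) of film quality metrics
#'
#' Per-group means and standard deviations for any numeric film metrics
#' (thickness, weight, drug content, tensile strength, elongation, ...),
#' the form in which film-characterisation tables are reported.
#'
#' @param data Data frame of per-specimen measurements.
#' @param group Column (tidy-eval) identifying the film group/arm.
#' @return Tibble in long form: group, `metric`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(arm = rep(c("a", "b"), each = 3),
#'                     thickness_mm = c(0.13, 0.14, 0.15, 0.15, 0.16, 0.16))
#' film_summary(d, arm)
film_summary <- function(data, group) {
  tibble::as_tibble(data) |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(dplyr::across(
      dplyr::where(is.numeric),
      list(mean = ~ mean(.x, na.rm = TRUE),
           sd = ~ stats::sd(.x, na.rm = TRUE),
           n = ~ sum(!is.na(.x))),
      .names = "{.col}@{.fn}"), .groups = "drop") |>
    tidyr::pivot_longer(dplyr::contains("@"),
                        names_to = c("metric", ".value"), names_sep = "@")
}
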