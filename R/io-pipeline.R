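#' Read a dissolution profile from CSV
#'
#' Expects unit-bearing headers `time_min` and `released_pct`, optionally
#' `replicate` and `label`. Rows are sorted by time (with a warning if the
#' file was out of order); duplicated time points (within one replicate)
#' are an error.
#'
#' @param path Path to a CSV file (decimal point, comma separator).
#' @return A validated dissolution-profile tibble.
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_min", "released_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(raw[[col]])))))
      stop(sprintf("%s: non-numeric value in column '%s' (row %s)",
                   path, col, paste(utils::head(bad, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  key <- if ("replicate" %in% names(raw)) {
    paste(raw$replicate, raw$time_min)
  } else {
    raw$time_min
  }
  if (anyDuplicated(key)) {
    stop(path, ": duplicated time point at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  if (is.unsorted(raw$time_min, strictly = FALSE) &&
      !"replicate" %in% names(raw)) {
    warning(path, ": rows were not sorted by time; sorting", call. = FALSE)
  }
  check_profile(raw)
}

#' Read a permeation series from CSV
#'
#' Expects headers `time_min` and `receptor_conc_ug_per_ml`.
#'
#' @inheritParams read_release_csv
#' @return A validated permeation tibble.
#' @export
read_permeation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_permeation(raw)
}

#' Read / write a unit-impulse-response configuration
#'
#' The JSON layout is
#' `{"terms": [{"A": ..., "lambda_per_min": ...}, ...],
#'   "dose_unit": "mg", "concentration_unit": "ng/mL",
#'   "non_paper": false}`.
#'
#' @param path JSON (or YAML, by extension) file path.
#' @return `read_uir_json()`: a [uir_model()]. `write_uir_json()`: the
#'   path, invisibly.
#' @export
read_uir_json <- function(path) {
  if (!file.exists(path)) stop("UIR config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML UIR configs requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  terms <- cfg$terms
  if (is.null(terms)) stop(path, ": no 'terms' entry", call. = FALSE)
  if (is.data.frame(terms)) {
    A <- terms$A
    lambda <- terms$lambda_per_min
  } else {
    A <- purrr::map_dbl(terms, "A")
    lambda <- purrr::map_dbl(terms, "lambda_per_min")
  }
  uir_model(A = A, lambda = lambda,
            dose_unit = cfg$dose_unit %||% "mg",
            concentration_unit = cfg$concentration_unit %||% "ng/mL",
            non_paper = isTRUE(cfg$non_paper))
}

#' @rdname read_uir_json
#' @param uir A [uir_model()].
#' @export
write_uir_json <- function(uir, path) {
  stopifnot(inherits(uir, "uir_model"))
  jsonlite::write_json(
    list(terms = purrr::map2(uir$A, uir$lambda,
                             ~ list(A = .x, lambda_per_min = .y)),
         dose_unit = uir$dose_unit,
         concentration_unit = uir$concentration_unit,
         non_paper = uir$non_paper),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis configuration for the film pipeline
#'
#' Bundles the inputs and settings of a full run. Defaults follow the
#' buccal-film use case: a 1.46 mg loaded dose, complete (100%) buccal
#' bioavailability, a 0.01 min convolution step and a 360-480 min flux
#' window.
#'
#' @param release Dissolution profile (tibble or CSV path). Optional.
#' @param permeation Permeation series (tibble or CSV path). Optional.
#' @param uir A [uir_model()] or path to its JSON/YAML config. Required
#'   for plasma prediction.
#' @param dose_mg Loaded dose represented by 100% release.
#' @param f_bio Bioavailability fraction.
#' @param dt Convolution grid step (minutes).
#' @param flux_window Length-2 minutes, flux regression window.
#' @param cd_ug_per_cm3 Optional initial donor concentration for apparent
#'   permeability.
#' @param geometry A [franz_cell()].
#' @param models Release models to fit (default all nine).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(release = NULL, permeation = NULL, uir = NULL,
                            dose_mg = 1.46, f_bio = 1, dt = 0.01,
                            flux_window = c(360, 480), cd_ug_per_cm3 = NULL,
                            geometry = franz_cell(),
                            models = release_model_ids()) {
  if (is.character(release)) release <- read_release_csv(release)
  if (is.character(permeation)) permeation <- read_permeation_csv(permeation)
  if (is.character(uir)) uir <- read_uir_json(uir)
  if (!is.null(uir) && !inherits(uir, "uir_model")) {
    stop("uir must be a uir_model or a config path", call. = FALSE)
  }
  structure(
    list(release = release, permeation = permeation, uir = uir,
         dose_mg = dose_mg, f_bio = f_bio, dt = dt,
         flux_window = flux_window, cd_ug_per_cm3 = cd_ug_per_cm3,
         geometry = geometry, models = models),
    class = "analysis_config")
}

#' Run the full film analysis pipeline
#'
#' Executes, for whichever inputs the configuration supplies:
#' release-model fitting and ranking; convolution-based plasma prediction
#' (requires a UIR); and permeation flux / apparent permeability analysis.
#'
#' @param config An [analysis_config()].
#' @param quiet Suppress stage messages.
#' @return A `film_results` list with elements `ranking`,
#'   `plasma` (a `plasma_prediction`), `flux` (a `flux_fit`),
#'   `papp_cm_h`, and `meta` (conventions in force).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message(...)
  results <- list(ranking = NULL, plasma = NULL, flux = NULL,
                  papp_cm_h = NULL)

  if (!is.null(config$release)) {
    say("fitting ", length(config$models), " release models")
    results$ranking <- tryCatch(
      rank_release_models(config$release, models = config$models),
      error = function(e) stop("release-fitting stage failed: ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(config$uir)) {
      say("predicting plasma profile by convolution (dt = ",
          config$dt, " min)")
      results$plasma <- tryCatch(
        predict_plasma(config$release, dose_mg = config$dose_mg,
                       uir = config$uir, f_bio = config$f_bio,
                       dt = config$dt),
        error = function(e) stop("convolution stage failed: ",
                                 conditionMessage(e), call. = FALSE))
    }
  }

  if (!is.null(config$permeation)) {
    say("estimating steady-state flux over [",
        config$flux_window[1], ", ", config$flux_window[2], "] min")
    results$flux <- tryCatch(
      steady_state_flux(config$permeation, window = config$flux_window,
                        geometry = config$geometry),
      error = function(e) stop("permeation stage failed: ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(config$cd_ug_per_cm3)) {
      results$papp_cm_h <- apparent_permeability(results$flux,
                                                 config$cd_ug_per_cm3)
    }
  }

  results$meta <- list(
    package_version = as.character(utils::packageVersion("filmkin")),
    aic_convention = "n*log(SSE/n) + 2p (least-squares form)",
    rmse_convention = "sqrt(SSE/(n - p)) (df-corrected)",
    convolution = "left-rectangle discretisation on uniform grid",
    dose_mg = config$dose_mg, f_bio = config$f_bio, dt = config$dt,
    flux_window = config$flux_window
  )
  class(results) <- "film_results"
  results
}

#' Write a results bundle to disk
#'
#' Emits up to five plain-text artifacts in `outdir`: the model-comparison
#' table (`model_comparison.csv`), fitted parameters (`fit_parameters.csv`),
#' predicted plasma profile (`plasma_profile.csv`), PK metrics
#' (`pk_metrics.json`), flux results (`flux.json`) and run metadata with
#' the statistical conventions in force (`run_metadata.json`).
#'
#' @param results A `film_results` bundle from [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, outdir) {
  stopifnot(inherits(results, "film_results"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  written <- character(0)
  emit <- function(name) {
    written <<- c(written, file.path(outdir, name))
    file.path(outdir, name)
  }

  if (!is.null(results$ranking)) {
    readr::write_csv(tibble::as_tibble(results$ranking),
                     emit("model_comparison.csv"))
    params <- purrr::map_dfr(attr(results$ranking, "fits"), tidy.release_fit)
    readr::write_csv(params, emit("fit_parameters.csv"))
  }
  if (!is.null(results$plasma)) {
    readr::write_csv(results$plasma$profile, emit("plasma_profile.csv"))
    jsonlite::write_json(
      as.list(glance.plasma_prediction(results$plasma)),
      emit("pk_metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$flux)) {
    flux <- as.list(glance.flux_fit(results$flux))
    flux$papp_cm_h <- results$papp_cm_h
    jsonlite::write_json(flux, emit("flux.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(results$meta, emit("run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(written)
}
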