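#' Goodness-of-fit statistics for a fitted release model
#'
#' Computes the goodness-of-fit triplet used to compare release models:
#' adjusted R-squared, root mean square error, and the Akaike information
#' criterion, together with SSE and plain R-squared.
#'
#' @details
#' Conventions (frozen; changing any of these is a breaking change):
#' \itemize{
#'   \item `SSE = sum((observed - predicted)^2)`
#'   \item `R2 = 1 - SSE / SST`, `SST` about the observed mean
#'   \item `adj R2 = 1 - (1 - R2) * (n - 1) / (n - p - 1)`
#'   \item `RMSE = sqrt(SSE / (n - p))` (degrees-of-freedom corrected)
#'   \item `AIC = n * log(SSE / n) + 2 * p` (least-squares form, as used by
#'     common dissolution-fitting software)
#' }
#' where `n` is the number of observations and `p = n_params`. A perfect
#' fit (`SSE = 0`) makes the least-squares AIC diverge; it is reported as
#' `-Inf` with a warning. Constant observations (`SST = 0`) leave R-squared
#' undefined and raise an error, as does `n <= p + 1` (adjusted R-squared
#' denominator).
#'
#' @param observed,predicted Numeric vectors of equal length (percent
#'   released).
#' @param n_params Number of fitted model parameters.
#' @return A one-row tibble: `sse`, `r2`, `r2_adjusted`, `rmse`, `aic`,
#'   `n_obs`, `n_params`.
#' @export
#' @examples
#' release_gof(observed = c(1, 2, 3), predicted = c(0, 3, 3), n_params = 1)
release_gof <- function(observed, predicted, n_params) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  n <- length(observed)
  p <- as.integer(n_params)
  if (length(predicted) != n) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (n < p + 2) {
    stop(sprintf(
      "need at least n_params + 2 = %d observations for adjusted R2, got %d",
      p + 2, n), call. = FALSE)
  }
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("observations are constant: R2 is undefined (SST = 0)", call. = FALSE)
  }
  r2 <- 1 - sse / sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  rmse <- sqrt(sse / (n - p))
  if (sse == 0) {
    warning("SSE = 0: least-squares AIC is -Inf", call. = FALSE)
    aic <- -Inf
  } else {
    aic <- n * log(sse / n) + 2 * p
  }
  tibble::tibble(
    sse = sse, r2 = r2, r2_adjusted = r2_adj, rmse = rmse, aic = aic,
    n_obs = n, n_params = p
  )
}

check_profile <- function(data) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with columns time_min and released_pct",
         call. = FALSE)
  }
  need <- c("time_min", "released_pct")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  if ("replicate" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(released_pct = mean(.data$released_pct), .groups = "drop")
  }
  out <- dplyr::arrange(out, .data$time_min)
  t <- out$time_min
  f <- out$released_pct
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time_min must be finite and nonnegative", call. = FALSE)
  }
  if (anyDuplicated(t)) {
    stop("duplicated time points in profile", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f < 0) || any(f > 110)) {
    stop("released_pct must lie in [0, 110] (percent of dose)", call. = FALSE)
  }
  if (any(f > 100)) {
    warning("released_pct exceeds 100% at some times (analytical overshoot)",
            call. = FALSE)
  }
  out
}

#' Deterministic starting values for release-model fitting
#'
#' Builds the multi-start grid used by [fit_release()]: a data-driven
#' heuristic guess (endpoint slope for zero order, log-log regression for
#' the power-law models, double-log linearisation for Weibull, terminal
#' first-order rate, etc.) followed by a fixed grid of fallback starts.
#' The same profile always yields the same guesses.
#'
#' @param data Dissolution profile data frame with columns `time_min` and
#'   `released_pct`.
#' @param model_id One of the ids listed by [release_models()].
#' @return A list of numeric parameter vectors (at least 8), each a valid
#'   start within the model's bounds.
#' @export
initial_guesses <- function(data, model_id) {
  check_model_id(model_id)
  prof <- check_profile(data)
  spec <- release_model_specs()[[model_id]]
  lo <- spec$lower
  hi <- spec$upper
  mid <- (lo + hi) / 2

  t <- prof$time_min
  f <- prof$released_pct
  pos <- t > 0 & f > 0 & f < 100
  tp <- t[pos]
  fp <- f[pos]

  # heuristic head guess per model; fall back to bound midpoints
  head_guess <- tryCatch({
    if (length(tp) < 2) stop("too few positive points")
    switch(model_id,
      zero_order = f[which.max(t)] / max(t),
      first_order = {
        # terminal log-linear slope of remaining fraction
        rem <- 1 - fp / 100
        ok <- rem > 1e-6
        if (sum(ok) < 2) stop("no interior points")
        -stats::coef(stats::lm(log(rem[ok]) ~ tp[ok] + 0))[[1]]
      },
      higuchi = {
        stats::coef(stats::lm(fp ~ sqrt(tp) + 0))[[1]]
      },
      korsmeyer_peppas = {
        cf <- stats::coef(stats::lm(log(fp) ~ log(tp)))
        c(exp(cf[[1]]), cf[[2]])
      },
      hixson_crowell = {
        cube <- 1 - (1 - fp / 100)^(1 / 3)
        stats::coef(stats::lm(cube ~ tp + 0))[[1]]
      },
      hopfenberg = {
        # n = 1 start with first-order-like erosion rate
        c(max(fp / 100 / tp), 1.5)
      },
      baker_lonsdale = {
        lhs <- 1.5 * (1 - (1 - fp / 100)^(2 / 3)) - fp / 100
        stats::coef(stats::lm(lhs ~ tp + 0))[[1]]
      },
      peppas_sahlin = {
        # separable least squares: the model is linear in (k1, k2) given m,
        # so profile m over a grid and solve each conditional LS problem
        purrr::map(seq(0.1, 1.2, by = 0.1), function(m) {
          X <- cbind(tp^m, tp^(2 * m))
          k <- tryCatch(stats::coef(stats::lm.fit(X, fp)),
                        error = function(e) c(1, 1))
          c(max(k[1], 0), max(k[2], 0), m)
        })
      },
      weibull = {
        # double-log linearisation: log(-log(1 - F/100)) = beta log t - log alpha
        inner <- 1 - fp / 100
        ok <- inner > 1e-8
        if (sum(ok) < 2) stop("no interior points")
        cf <- stats::coef(stats::lm(log(-log(inner[ok])) ~ log(tp[ok])))
        c(exp(-cf[[1]]), cf[[2]], 0)
      }
    )
  }, error = function(e) mid)
  if (!is.list(head_guess)) head_guess <- list(head_guess)
  head_guess <- purrr::map(head_guess,
                           ~ pmin(pmax(as.numeric(.x), lo), hi))

  # fixed fallback grid: scaled bound-midpoint variants, deterministic
  scales <- c(1, 0.1, 0.5, 2, 10, 0.02, 5, 0.2)
  grid <- purrr::map(scales, function(s) pmin(pmax(mid * s, lo), hi))
  c(head_guess, grid)
}

#' Fit an empirical release model to a dissolution profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) minimising the sum of squared residuals between
#' observed and model percent released, with deterministic multi-start
#' from [initial_guesses()]; the start achieving the lowest SSE wins.
#' Replicate profiles (a `replicate` column) are averaged per time point
#' before fitting; the `t = 0, F = 0` point is retained.
#'
#' @param data Dissolution profile: a data frame with columns `time_min`,
#'   `released_pct` and optionally `replicate`.
#' @param model_id One of the ids listed by [release_models()].
#' @param start Optional numeric vector used as an additional first start.
#' @return An object of class `release_fit` with [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods; `tidy()` returns the fitted
#'   parameters, `glance()` the goodness-of-fit row.
#' @seealso [rank_release_models()], [release_gof()]
#' @export
#' @examples
#' grid <- c(0, 1.5, 3, 4.5, 6, 7.5, 9, 13.5)
#' prof <- tibble::tibble(time_min = grid,
#'                        released_pct = evaluate_release("zero_order", 7, grid))
#' fit <- fit_release(prof, "zero_order")
#' generics::tidy(fit)
#' generics::glance(fit)
fit_release <- function(data, model_id, start = NULL) {
  check_model_id(model_id)
  prof <- check_profile(data)
  spec <- release_model_specs()[[model_id]]
  p <- length(spec$param_names)
  if (nrow(prof) < p + 2) {
    stop(sprintf(
      "profile has %d points; fitting '%s' (%d parameters) needs at least %d",
      nrow(prof), model_id, p, p + 2), call. = FALSE)
  }

  obs <- prof$released_pct
  t <- prof$time_min
  residual_fun <- function(par) evaluate_release(model_id, par, t) - obs

  starts <- initial_guesses(prof, model_id)
  if (!is.null(start)) {
    starts <- c(list(pmin(pmax(as.numeric(start), spec$lower), spec$upper)),
                starts)
  }

  best <- NULL
  best_sse <- Inf
  n_used <- 0L
  for (s in starts) {
    n_used <- n_used + 1L
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = spec$lower, upper = spec$upper, fn = residual_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse
      best <- res
    }
  }

  if (is.null(best)) {
    fit <- list(
      model_id = model_id, params = rep(NA_real_, p),
      param_names = spec$param_names, converged = FALSE,
      n_restarts_used = n_used,
      gof = tibble::tibble(sse = Inf, r2 = NA_real_, r2_adjusted = NA_real_,
                           rmse = Inf, aic = Inf, n_obs = nrow(prof),
                           n_params = p),
      data = prof
    )
    class(fit) <- "release_fit"
    return(fit)
  }

  par <- as.numeric(best$par)
  names(par) <- spec$param_names
  pred <- evaluate_release(model_id, par, t)
  gof <- suppressWarnings(release_gof(obs, pred, p))
  converged <- best$info %in% 1:4 &&
    all(par >= spec$lower - 1e-12) && all(par <= spec$upper + 1e-12)

  fit <- list(
    model_id = model_id, params = par, param_names = spec$param_names,
    param_units = spec$param_units, converged = converged,
    n_restarts_used = n_used, gof = gof, data = prof,
    fitted = pred
  )
  class(fit) <- "release_fit"
  fit
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit: %s>\n", x$model_id))
  cat("  parameters: ",
      paste(sprintf("%s = %.6g", x$param_names, x$params), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  adj R2 = %.4f, RMSE = %.4f, AIC = %.4f (n = %d)\n",
              x$gof$r2_adjusted, x$gof$rmse, x$gof$aic, x$gof$n_obs))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_release
#' @param x A `release_fit` object.
#' @param ... Unused.
#' @method tidy release_fit
#' @export
tidy.release_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    term = x$param_names,
    estimate = unname(x$params),
    unit = if (is.null(x$param_units)) NA_character_ else x$param_units
  )
}

#' @rdname fit_release
#' @method glance release_fit
#' @export
glance.release_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model_id = x$model_id, converged = x$converged),
    x$gof
  )
}

#' Predicted release curve from a fitted model
#'
#' @param object A `release_fit`.
#' @param times Optional times (minutes); defaults to a fine grid over the
#'   fitted data range.
#' @param ... Unused.
#' @return Tibble with `time_min` and `released_pct`.
#' @export
predict.release_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- seq(min(object$data$time_min), max(object$data$time_min),
                 length.out = 200)
  }
  tibble::tibble(
    time_min = times,
    released_pct = evaluate_release(object$model_id, object$params, times)
  )
}

#' Fit and rank all (or a subset of) release models
#'
#' Fits each requested model to the profile with [fit_release()] and
#' returns the model-comparison table (one row per model with adjusted
#' R-squared, RMSE and AIC), sorted by the chosen criterion: ascending
#' AIC or RMSE, descending adjusted R-squared. Since all models are fitted
#' once, re-ranking by another criterion is a pure re-sort of the table.
#'
#' @inheritParams fit_release
#' @param models Character vector of model ids (default: all nine).
#' @param criterion `"aic"` (default), `"r2_adjusted"`, or `"rmse"`.
#' @return An object of class `release_ranking`: a tibble with columns
#'   `rank`, `model_id`, `r2_adjusted`, `rmse`, `aic`, `sse`, `converged`,
#'   `n_params`, plus a `fits` attribute holding the `release_fit` objects.
#' @export
#' @examples
#' grid <- c(0, 1.5, 3, 4.5, 6, 7.5, 9, 13.5)
#' prof <- tibble::tibble(time_min = grid,
#'                        released_pct = evaluate_release("higuchi", 25, grid))
#' rank_release_models(prof, models = c("zero_order", "higuchi", "first_order"))
rank_release_models <- function(data, models = release_model_ids(),
                                criterion = c("aic", "r2_adjusted", "rmse")) {
  criterion <- match.arg(criterion)
  models <- vapply(models, check_model_id, character(1))
  if (length(models) < 2) {
    stop("need at least two models to rank", call. = FALSE)
  }
  prof <- check_profile(data)

  fits <- purrr::map(models, function(m) {
    tryCatch(suppressWarnings(fit_release(prof, m)), error = function(e) NULL)
  })
  names(fits) <- models
  ok <- !purrr::map_lgl(fits, is.null)
  if (sum(ok) < 2) {
    stop("fewer than two models could be fitted to this profile",
         call. = FALSE)
  }
  fits <- fits[ok]

  tab <- purrr::map_dfr(fits, glance.release_fit)
  tab <- dplyr::select(tab, "model_id", "converged", "n_params",
                       "sse", "r2_adjusted", "rmse", "aic")
  ord <- switch(criterion,
    aic = order(tab$aic),
    rmse = order(tab$rmse),
    r2_adjusted = order(-tab$r2_adjusted)
  )
  tab <- tab[ord, , drop = FALSE]
  tab <- dplyr::mutate(tab, rank = dplyr::row_number(), .before = 1)
  attr(tab, "fits") <- fits
  attr(tab, "criterion") <- criterion
  class(tab) <- c("release_ranking", class(tab))
  tab
}

#' Re-sort an existing ranking by another criterion (no refitting)
#'
#' @param ranking A `release_ranking` from [rank_release_models()].
#' @param criterion `"aic"`, `"r2_adjusted"`, or `"rmse"`.
#' @return A `release_ranking` sorted by the new criterion.
#' @export
rerank <- function(ranking, criterion = c("aic", "r2_adjusted", "rmse")) {
  stopifnot(inherits(ranking, "release_ranking"))
  criterion <- match.arg(criterion)
  fits <- attr(ranking, "fits")
  tab <- tibble::as_tibble(ranking)
  tab$rank <- NULL
  ord <- switch(criterion,
    aic = order(tab$aic),
    rmse = order(tab$rmse),
    r2_adjusted = order(-tab$r2_adjusted)
  )
  tab <- tab[ord, , drop = FALSE]
  tab <- dplyr::mutate(tab, rank = dplyr::row_number(), .before = 1)
  attr(tab, "fits") <- fits
  attr(tab, "criterion") <- criterion
  class(tab) <- c("release_ranking", class(tab))
  tab
}
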