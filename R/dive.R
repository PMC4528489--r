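#' Discrepancy: mean percentage error of a fit on its own curve
#'
#' Mean over curve points of `100 |S(x; theta) - s| / s`: how well the model
#' reproduces the rarefaction data it was fitted to.
#'
#' @param fit A converged [fit_model()] result.
#' @param curve The [build_curve()] object the fit was computed on.
#' @param model The [curve_model()].
#' @return Mean percentage error (>= 0).
#' @export
score_discrepancy <- function(fit, curve, model) {
  stopifnot(inherits(fit, "model_fit"), inherits(curve, "rarefaction_curve"))
  if (!isTRUE(fit$converged)) stop_validation("fit has not converged")
  pred <- model$S(curve$x, fit$par)
  mean(100 * abs(pred - curve$s) / curve$s)
}

#' Accuracy: percentage error of a subsample fit at the full sample size
#'
#' Evaluates a model fitted only to a subsample's rarefaction curve at the
#' full sample size and scores it against the observed full-sample richness:
#' `100 |S(N_full; theta_sub) - S_obs_full| / S_obs_full`. This is the
#' out-of-sample criterion: the full curve has no influence on the subsample
#' fit's parameters.
#'
#' @param subsample_fit A converged fit on a subsample curve.
#' @param full_curve The full-data [build_curve()] object.
#' @param model The [curve_model()].
#' @return Percentage error (>= 0), symmetric in the sign of the error.
#' @export
score_accuracy <- function(subsample_fit, full_curve, model) {
  stopifnot(inherits(subsample_fit, "model_fit"),
            inherits(full_curve, "rarefaction_curve"))
  if (!isTRUE(subsample_fit$converged)) stop_validation("fit has not converged")
  pred <- model$S(full_curve$N_full, subsample_fit$par)
  100 * abs(pred - full_curve$S_obs) / full_curve$S_obs
}

#' Similarity: normalized area between subsample and full-data fits
#'
#' `integral |S_sub(x) - S_full(x)| dx / integral S_full(x) dx` over
#' `[1, N_full]`, by the trapezoid rule on a log-spaced grid. Dimensionless
#' and zero iff the two fitted curves coincide; the area in the numerator is
#' symmetric in the two fits, the normalization is always by the full-data
#' fit.
#'
#' @param subsample_fit,full_fit Converged [fit_model()] results.
#' @param sub_model,full_model Their [curve_model()]s.
#' @param x_max Upper integration limit (defaults to the full fit's `N_full`).
#' @param grid_size Number of log-spaced grid points (default 200).
#' @return Normalized area (>= 0).
#' @export
score_similarity <- function(subsample_fit, full_fit, sub_model, full_model,
                             x_max = NULL, grid_size = 200) {
  stopifnot(inherits(subsample_fit, "model_fit"), inherits(full_fit, "model_fit"))
  if (!isTRUE(subsample_fit$converged) || !isTRUE(full_fit$converged)) {
    stop_validation("fits have not converged")
  }
  x_max <- x_max %||% full_fit$N_full
  grid <- exp(seq(0, log(x_max), length.out = grid_size))
  s_sub <- sub_model$S(grid, subsample_fit$par)
  s_full <- full_model$S(grid, full_fit$par)
  trapz <- function(y) sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
  denom <- trapz(abs(s_full))
  if (denom == 0) return(0)
  trapz(abs(s_sub - s_full)) / denom
}

#' Configuration for the curve-extrapolation estimator
#'
#' @param target_population_size Population size `N_pop` to extrapolate to
#'   (e.g. total T cells in peripheral blood); must be `>= N` of the data.
#' @param subsample_fractions Nested subsample fractions in (0, 1) used for
#'   the out-of-sample criteria (default 0.5, a single nested subsample).
#' @param n_curve_points Rarefaction grid size (default 50).
#' @param top_k Number of best-ranked models aggregated (default 5).
#' @param aggregation `"geometric_mean"` (default; extrapolated estimates can
#'   span orders of magnitude) or `"median"`.
#' @param n_restarts Restarts per model fit (default 10).
#' @param curvature_threshold Under-sampling guard threshold on the full
#'   curve's [curvature()] (default 0.1).
#' @param force Proceed despite a curvature below the threshold.
#' @param registry Model registry (default [default_registry()]).
#' @param seed RNG seed.
#' @return List of class `dive_config`.
#' @export
dive_config <- function(target_population_size,
                        subsample_fractions = 0.5,
                        n_curve_points = 50,
                        top_k = 5,
                        aggregation = c("geometric_mean", "median"),
                        n_restarts = 10,
                        curvature_threshold = 0.1,
                        force = FALSE,
                        registry = default_registry(),
                        seed = 0) {
  if (any(subsample_fractions <= 0) || any(subsample_fractions >= 1)) {
    stop_validation("subsample_fractions must lie strictly in (0, 1)")
  }
  if (!is_count_scalar(top_k) || top_k < 1) {
    stop_validation("top_k must be a positive integer")
  }
  structure(list(target_population_size = target_population_size,
                 subsample_fractions = sort(subsample_fractions),
                 n_curve_points = n_curve_points,
                 top_k = as.integer(top_k),
                 aggregation = match.arg(aggregation),
                 n_restarts = n_restarts,
                 curvature_threshold = curvature_threshold,
                 force = isTRUE(force),
                 registry = registry,
                 seed = seed),
            class = "dive_config")
}

#' DivE: species richness by scored rarefaction-curve extrapolation
#'
#' Fits every model in the registry to the full-sample rarefaction curve and
#' to nested-subsample curves, scores each model on four criteria --
#' discrepancy (fit to its own data), accuracy (subsample fit's prediction of
#' the full-sample richness), similarity (area between subsample and full
#' fits), and plausibility (`S' >= 0`, `S'' <= 0` over the whole extrapolation
#' range `[1, N_pop]`, a hard filter) -- ranks the survivors by the sum of
#' their three criterion ranks, and aggregates the top `top_k` full-data fits
#' evaluated at the target population size. Per-model predictions are clamped
#' at `N_pop` (richness cannot exceed individuals) and the aggregate is
#' floored at `S_obs` with a warning if the floor binds.
#'
#' Selection rewards models that predict rarefaction data they were not
#' fitted to, which is what makes the estimate stable against sample size;
#' an under-sampling guard refuses near-linear rarefaction curves (see
#' [curvature()]) unless `force = TRUE`.
#'
#' @param data An [abundance_vector()].
#' @param config A [dive_config()]; alternatively pass
#'   `target_population_size` etc. via `...`.
#' @param ... Arguments forwarded to [dive_config()] when `config` is `NULL`.
#' @return Object of class `dive_result`: list with `estimate` (a
#'   [diversity_estimate()]) and `scorecards` (one row per model: criteria,
#'   plausibility, combined rank, prediction at `N_pop`, aggregation flag).
#' @examples
#' \donttest{
#' pop <- make_population("zipf", S_true = 200, params = list(exponent = 1))
#' av <- draw_sample(pop, 2000, seed = 1)
#' res <- dive_estimate(av, target_population_size = 1e5, seed = 1)
#' res$estimate
#' }
#' @export
dive_estimate <- function(data, config = NULL, ...) {
  stopifnot(inherits(data, "abundance_vector"))
  if (is.null(config)) config <- dive_config(...)
  stopifnot(inherits(config, "dive_config"))
  N_pop <- config$target_population_size
  if (is.null(N_pop) || !is.numeric(N_pop) || N_pop < data$N) {
    stop_validation("target_population_size must be >= N = %d", data$N)
  }
  full_curve <- build_curve(data, config$n_curve_points)
  attr(full_curve, "id") <- "full"
  curv <- curvature(full_curve)
  warnings <- character()
  if (curv < config$curvature_threshold) {
    msg <- sprintf(paste("rarefaction curve is close to linear (curvature",
                         "%.3f < %.3f): sample too shallow for reliable",
                         "extrapolation"), curv, config$curvature_threshold)
    if (!config$force) {
      stop(errorCondition(msg, class = c("clonodiv_undersampling_error",
                                         "clonodiv_estimation_error",
                                         "clonodiv_error")))
    }
    warnings <- c(warnings, msg)
  }

  subs <- nested_subsamples(data, config$subsample_fractions,
                            seed = derive_seed(config$seed, 1L))
  sub_curves <- lapply(seq_along(subs), function(i) {
    cu <- build_curve(subs[[i]], config$n_curve_points)
    attr(cu, "id") <- sprintf("subsample_%g", config$subsample_fractions[i])
    cu
  })

  registry <- config$registry
  cards <- lapply(seq_along(registry), function(mi) {
    model <- registry[[mi]]
    full_fit <- fit_model(model, full_curve, config$n_restarts,
                          seed = derive_seed(config$seed, 100L + mi))
    sub_fits <- lapply(seq_along(sub_curves), function(ci) {
      fit_model(model, sub_curves[[ci]], config$n_restarts,
                seed = derive_seed(config$seed, 100L + mi + 1000L * ci))
    })
    fits <- c(list(full_fit), sub_fits)
    if (!all(vapply(fits, `[[`, TRUE, "converged"))) {
      return(list(model = model$name, plausible = FALSE,
                  reason = "fit did not converge",
                  discrepancy = NA_real_, accuracy = NA_real_,
                  similarity = NA_real_, prediction = NA_real_))
    }
    plausible <- all(vapply(fits, check_plausibility, TRUE,
                            model = model, x_max = N_pop))
    disc <- mean(c(score_discrepancy(full_fit, full_curve, model),
                   vapply(seq_along(sub_fits), function(ci) {
                     score_discrepancy(sub_fits[[ci]], sub_curves[[ci]], model)
                   }, numeric(1))))
    acc <- mean(vapply(sub_fits, score_accuracy, numeric(1),
                       full_curve = full_curve, model = model))
    sim <- mean(vapply(sub_fits, score_similarity, numeric(1),
                       full_fit = full_fit, sub_model = model,
                       full_model = model))
    pred <- min(model$S(N_pop, full_fit$par), N_pop)
    list(model = model$name, plausible = plausible,
         reason = if (plausible) "" else "implausible over [1, N_pop]",
         discrepancy = disc, accuracy = acc, similarity = sim,
         prediction = pred)
  })

  sc <- data.frame(
    model = vapply(cards, `[[`, "", "model"),
    discrepancy = vapply(cards, `[[`, 0, "discrepancy"),
    accuracy = vapply(cards, `[[`, 0, "accuracy"),
    similarity = vapply(cards, `[[`, 0, "similarity"),
    plausible = vapply(cards, `[[`, TRUE, "plausible"),
    reason = vapply(cards, `[[`, "", "reason"),
    prediction = vapply(cards, `[[`, 0, "prediction"),
    stringsAsFactors = FALSE)

  ok <- sc$plausible & !is.na(sc$discrepancy)
  if (!any(ok)) {
    stop_estimation("no plausible converged model: %s",
                    paste(sprintf("%s (%s)", sc$model, sc$reason),
                          collapse = "; "))
  }
  sc$combined_rank <- NA_integer_
  r <- rank(sc$discrepancy[ok], ties.method = "min") +
       rank(sc$accuracy[ok], ties.method = "min") +
       rank(sc$similarity[ok], ties.method = "min")
  # ties in the rank sum broken by accuracy, then discrepancy, then name
  ord <- order(r, sc$accuracy[ok], sc$discrepancy[ok], sc$model[ok])
  sc$combined_rank[which(ok)[ord]] <- seq_len(sum(ok))
  sc$aggregated <- !is.na(sc$combined_rank) &
    sc$combined_rank <= min(config$top_k, sum(ok))

  preds <- pmax(sc$prediction[sc$aggregated], 1e-12)
  est <- switch(config$aggregation,
                geometric_mean = exp(mean(log(preds))),
                median = stats::median(preds))
  if (est < data$S_obs) {
    warnings <- c(warnings, sprintf(
      "aggregated extrapolation %.4g below S_obs = %d; floored at S_obs",
      est, data$S_obs))
    est <- data$S_obs
  }
  est <- min(est, N_pop)

  settings <- list(subsample_fractions = config$subsample_fractions,
                   n_curve_points = config$n_curve_points,
                   top_k = config$top_k,
                   aggregation = config$aggregation,
                   n_restarts = config$n_restarts,
                   curvature_threshold = config$curvature_threshold,
                   curvature = curv,
                   models = names(registry),
                   seed = config$seed)
  structure(
    list(estimate = diversity_estimate("dive", est, data$N,
                                       target_population_size = N_pop,
                                       settings = settings,
                                       warnings = warnings),
         scorecards = sc[order(sc$combined_rank, na.last = TRUE), ]),
    class = "dive_result")
}

#' @export
print.dive_result <- function(x, ...) {
  print(x$estimate)
  agg <- x$scorecards[x$scorecards$aggregated, "model"]
  cat("  aggregated models:", paste(agg, collapse = ", "), "\n")
  invisible(x)
}

#' Export DivE scorecards as a delimited table
#'
#' @param result A [dive_estimate()] result.
#' @param path Output path (TSV).
#' @export
export_scorecards <- function(result, path) {
  stopifnot(inherits(result, "dive_result"))
  utils::write.table(result$scorecards, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
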