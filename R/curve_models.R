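#' Define a parametric rarefaction-curve model
#'
#' A candidate accumulation model `S(x; theta)` with analytic first and second
#' derivatives in `x`, box bounds on the parameters, and an initialization
#' recipe mapping a [build_curve()] object to a starting parameter vector.
#' Derivatives are analytic (not numeric) because the plausibility criterion
#' of the curve-extrapolation estimator requires the signs of `S'` and `S''`
#' over extrapolation ranges spanning many orders of magnitude.
#'
#' @param name Model name.
#' @param n_params Number of parameters (2 or 3).
#' @param S,S1,S2 Functions `(x, theta)` returning the model value and its
#'   first and second derivatives with respect to `x`.
#' @param lower,upper Parameter bounds (length `n_params`).
#' @param init Function `(curve)` returning a start vector within bounds.
#' @return An object of class `curve_model`.
#' @export
curve_model <- function(name, n_params, S, S1, S2, lower, upper, init) {
  stopifnot(is.character(name), n_params %in% c(2L, 3L),
            is.function(S), is.function(S1), is.function(S2),
            length(lower) == n_params, length(upper) == n_params,
            is.function(init))
  structure(list(name = name, n_params = as.integer(n_params),
                 S = S, S1 = S1, S2 = S2,
                 lower = lower, upper = upper, init = init),
            class = "curve_model")
}

#' @export
print.curve_model <- function(x, ...) {
  cat(sprintf("<curve_model> %s (%d parameters)\n", x$name, x$n_params))
  invisible(x)
}

# Slope/level heuristics shared by the init recipes. Curves start at
# (1, ~1) and end at (N, S_obs); asymptote guesses scale with S_obs.
init_loglog <- function(curve) {
  fit <- stats::lm(log(pmax(curve$s, 1e-9)) ~ log(curve$x))
  stats::coef(fit)
}

#' Registry of candidate accumulation models
#'
#' Returns the default list of parametric families fitted to rarefaction
#' curves: saturating families with a finite asymptote (Michaelis-Menten,
#' hyperbolic, negative exponential, asymptotic regression, Weibull
#' cumulative, Gompertz, rational, logistic in log-x) and non-saturating
#' families (power, logarithmic, Chapman-Richards with c <= 1 behaving
#' power-like at small x). Criteria-based selection over a spread of curve
#' shapes, rather than any particular family, is what drives the estimator;
#' the registry is a plain named list and callers may extend it with
#' [curve_model()] objects of their own.
#'
#' @return Named list of [curve_model()]s (>= 10 families).
#' @export
default_registry <- function() {
  models <- list(
    # S = a x^b
    curve_model("power", 2L,
      S  = function(x, p) p[1] * x^p[2],
      S1 = function(x, p) p[1] * p[2] * x^(p[2] - 1),
      S2 = function(x, p) p[1] * p[2] * (p[2] - 1) * x^(p[2] - 2),
      lower = c(1e-12, 1e-6), upper = c(Inf, 3),
      init = function(curve) {
        b <- init_loglog(curve)
        c(a = max(exp(b[1]), 1e-9), b = min(max(b[2], 0.05), 1.5))
      }),
    # S = a + b log x
    curve_model("logarithmic", 2L,
      S  = function(x, p) p[1] + p[2] * log(x),
      S1 = function(x, p) p[2] / x,
      S2 = function(x, p) -p[2] / x^2,
      lower = c(-Inf, 0), upper = c(Inf, Inf),
      init = function(curve) {
        co <- stats::coef(stats::lm(curve$s ~ log(curve$x)))
        c(a = co[1], b = max(co[2], 1e-6))
      }),
    # S = a x / (b + x)
    curve_model("michaelis_menten", 2L,
      S  = function(x, p) p[1] * x / (p[2] + x),
      S1 = function(x, p) p[1] * p[2] / (p[2] + x)^2,
      S2 = function(x, p) -2 * p[1] * p[2] / (p[2] + x)^3,
      lower = c(1e-12, 1e-12), upper = c(Inf, Inf),
      init = function(curve) c(a = 2 * curve$S_obs, b = curve$N_full / 2)),
    # S = a (1 - exp(-b x))
    curve_model("neg_exponential", 2L,
      S  = function(x, p) p[1] * (1 - exp(-p[2] * x)),
      S1 = function(x, p) p[1] * p[2] * exp(-p[2] * x),
      S2 = function(x, p) -p[1] * p[2]^2 * exp(-p[2] * x),
      lower = c(1e-12, 1e-15), upper = c(Inf, Inf),
      init = function(curve) c(a = 1.2 * curve$S_obs, b = 2 / curve$N_full)),
    # S = a - b c^x, 0 < c < 1
    curve_model("asymptotic_regression", 3L,
      S  = function(x, p) p[1] - p[2] * exp(x * log(p[3])),
      S1 = function(x, p) -p[2] * log(p[3]) * exp(x * log(p[3])),
      S2 = function(x, p) -p[2] * log(p[3])^2 * exp(x * log(p[3])),
      lower = c(1e-12, 1e-12, 1e-16), upper = c(Inf, Inf, 1 - 1e-12),
      init = function(curve) c(a = 1.2 * curve$S_obs, b = 1.2 * curve$S_obs,
                               c = exp(-3 / curve$N_full))),
    # S = a (1 - exp(-b x^c))
    curve_model("weibull_cumulative", 3L,
      S  = function(x, p) p[1] * (1 - exp(-p[2] * x^p[3])),
      S1 = function(x, p) p[1] * p[2] * p[3] * x^(p[3] - 1) * exp(-p[2] * x^p[3]),
      S2 = function(x, p) {
        u <- p[2] * x^p[3]
        p[1] * p[2] * p[3] * x^(p[3] - 2) * exp(-u) * ((p[3] - 1) - p[3] * u)
      },
      lower = c(1e-12, 1e-15, 1e-6), upper = c(Inf, Inf, 3),
      init = function(curve) c(a = 1.2 * curve$S_obs, b = 2 / curve$N_full^0.7,
                               c = 0.7)),
    # S = a exp(-b exp(-c x)); with u = b exp(-c x): S' = a c u e^-u,
    # S'' = a c^2 u e^-u (u - 1)
    curve_model("gompertz", 3L,
      S  = function(x, p) p[1] * exp(-p[2] * exp(-p[3] * x)),
      S1 = function(x, p) {
        u <- p[2] * exp(-p[3] * x)
        p[1] * p[3] * u * exp(-u)
      },
      S2 = function(x, p) {
        u <- p[2] * exp(-p[3] * x)
        p[1] * p[3]^2 * u * exp(-u) * (u - 1)
      },
      lower = c(1e-12, 1e-12, 1e-15), upper = c(Inf, Inf, Inf),
      init = function(curve) c(a = 1.2 * curve$S_obs, b = 1,
                               c = 3 / curve$N_full)),
    # S = a x / (1 + b x)  (asymptote a / b)
    curve_model("hyperbolic", 2L,
      S  = function(x, p) p[1] * x / (1 + p[2] * x),
      S1 = function(x, p) p[1] / (1 + p[2] * x)^2,
      S2 = function(x, p) -2 * p[1] * p[2] / (1 + p[2] * x)^3,
      lower = c(1e-12, 1e-15), upper = c(Inf, Inf),
      init = function(curve) c(a = 1, b = 1 / (2 * curve$S_obs))),
    # S = (a + b x) / (1 + c x); S' = (b - a c) / (1 + c x)^2
    curve_model("rational", 3L,
      S  = function(x, p) (p[1] + p[2] * x) / (1 + p[3] * x),
      S1 = function(x, p) (p[2] - p[1] * p[3]) / (1 + p[3] * x)^2,
      S2 = function(x, p) -2 * p[3] * (p[2] - p[1] * p[3]) / (1 + p[3] * x)^3,
      lower = c(0, 1e-12, 1e-15), upper = c(Inf, Inf, Inf),
      init = function(curve) c(a = 0.5, b = 1,
                               c = 1 / (2 * curve$S_obs))),
    # logistic in log x: S = a / (1 + (b / x)^c)  (Hill form; b = half-
    # saturation size, c = steepness in log x)
    curve_model("logistic_logx", 3L,
      S  = function(x, p) p[1] / (1 + exp(p[3] * (log(p[2]) - log(x)))),
      S1 = function(x, p) {
        w <- exp(p[3] * (log(p[2]) - log(x)))
        p[1] * p[3] * w / (x * (1 + w)^2)
      },
      S2 = function(x, p) {
        w <- exp(p[3] * (log(p[2]) - log(x)))
        p[1] * p[3] * w * ((p[3] - 1) * w - (p[3] + 1)) / (x^2 * (1 + w)^3)
      },
      lower = c(1e-12, 1e-9, 1e-6), upper = c(Inf, Inf, 20),
      init = function(curve) c(a = 2 * curve$S_obs, b = curve$N_full / 2,
                               c = 0.8)),
    # S = a (1 - exp(-b x))^c
    curve_model("chapman_richards", 3L,
      S  = function(x, p) p[1] * (1 - exp(-p[2] * x))^p[3],
      S1 = function(x, p) {
        w <- exp(-p[2] * x)
        p[1] * p[3] * p[2] * w * (1 - w)^(p[3] - 1)
      },
      S2 = function(x, p) {
        w <- exp(-p[2] * x)
        p[1] * p[3] * p[2]^2 * w * (1 - w)^(p[3] - 2) * (p[3] * w - 1)
      },
      lower = c(1e-12, 1e-15, 1e-6), upper = c(Inf, Inf, 5),
      init = function(curve) c(a = 1.2 * curve$S_obs, b = 2 / curve$N_full,
                               c = 1))
  )
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Fit a curve model by bounded nonlinear least squares
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) of
#' `S(x; theta)` to the points of a rarefaction curve, with box bounds and
#' multiple seeded restarts: the model's initialization recipe plus
#' `n_restarts - 1` log-uniform perturbations of it (factor up to 3 per
#' parameter). The lowest-SSE converged restart wins. Equal weights by
#' default; `weighting = "inv_x"` down-weights the autocorrelated large-x end
#' of the curve by `1/x`.
#'
#' @param model A [curve_model()].
#' @param curve A [build_curve()] result with at least `n_params + 1` points.
#' @param n_restarts Total number of initializations (default 10).
#' @param seed RNG seed for the restart perturbations.
#' @param weighting `"equal"` (default) or `"inv_x"`.
#' @return An object of class `model_fit`: list with `model`, `par`,
#'   `converged`, `sse`, `n_restarts_used`, `fitted_on` (an identifier of the
#'   curve), and the curve's `N_full`.
#' @export
fit_model <- function(model, curve, n_restarts = 10, seed = 0,
                      weighting = c("equal", "inv_x")) {
  stopifnot(inherits(model, "curve_model"), inherits(curve, "rarefaction_curve"))
  weighting <- match.arg(weighting)
  if (length(curve$x) < model$n_params + 1L) {
    stop_validation("curve has %d points; %s needs at least %d",
                    length(curve$x), model$name, model$n_params + 1L)
  }
  w <- switch(weighting, equal = rep(1, length(curve$x)),
              inv_x = 1 / curve$x)
  sw <- sqrt(w)
  resid_fn <- function(p) {
    r <- (model$S(curve$x, p) - curve$s) * sw
    r[!is.finite(r)] <- 1e10
    r
  }
  theta0 <- pmin(pmax(as.numeric(model$init(curve)), model$lower), model$upper)
  starts <- with_seed(seed, {
    c(list(theta0), lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
      fac <- exp(stats::runif(model$n_params, -log(3), log(3)))
      pmin(pmax(theta0 * fac, model$lower), model$upper)
    }))
  })
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = model$lower, upper = model$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4 && all(is.finite(res$par))
    if (!ok) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = res$par, sse = sse)
    }
  }
  structure(
    list(model = model$name,
         par = if (is.null(best)) rep(NA_real_, model$n_params) else best$par,
         converged = !is.null(best),
         sse = if (is.null(best)) NA_real_ else best$sse,
         n_restarts_used = length(starts),
         fitted_on = attr(curve, "id") %||% "curve",
         N_full = curve$N_full),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s on %s: %s, sse = %.4g\n", x$model, x$fitted_on,
              if (x$converged) paste0("theta = (",
                                      paste(signif(x$par, 4), collapse = ", "),
                                      ")") else "not converged",
              x$sse))
  invisible(x)
}

#' Check monotonicity and concavity of a fitted model
#'
#' The plausibility criterion for species-accumulation models: a fitted curve
#' must be non-decreasing (`S'(x) >= 0`) and non-accelerating (`S''(x) <= 0`)
#' everywhere on `[1, x_max]`. Because the fit is ultimately evaluated at an
#' extrapolation target far beyond the data, the check runs on a log-spaced
#' grid covering the full extrapolation range, with a relative tolerance of
#' 1e-9 for numerical noise.
#'
#' @param fit A converged [fit_model()] result.
#' @param model The [curve_model()] the fit belongs to.
#' @param x_max Upper end of the range (the extrapolation target).
#' @param grid_size Number of log-spaced probe points (default 200).
#' @return `TRUE` if plausible over the whole range, else `FALSE`.
#' @export
check_plausibility <- function(fit, model, x_max, grid_size = 200) {
  stopifnot(inherits(fit, "model_fit"), inherits(model, "curve_model"))
  if (!isTRUE(fit$converged)) stop_validation("fit has not converged")
  if (!is.numeric(x_max) || x_max < 1) stop_validation("x_max must be >= 1")
  grid <- exp(seq(0, log(x_max), length.out = grid_size))
  s0 <- model$S(grid, fit$par)
  s1 <- model$S1(grid, fit$par)
  s2 <- model$S2(grid, fit$par)
  if (!all(is.finite(s0)) || !all(is.finite(s1)) || !all(is.finite(s2))) {
    return(FALSE)
  }
  eps <- 1e-9 * pmax(1, abs(s0))
  all(s1 >= -eps) && all(s2 <= eps)
}
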