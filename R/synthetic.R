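#' Generate a synthetic clonotype population
#'
#' Ground-truth populations with known richness `S_true` and a heavy-tailed
#' (or uniform) relative-abundance distribution, emulating clonotype
#' frequency distributions:
#' * `zipf`: `p_i` proportional to `i^-exponent` (`params$exponent`, default 1);
#' * `lognormal`: abundances drawn from a log-normal (`params$sdlog`, default 1);
#' * `exponential`: drawn from an exponential (`params$rate`, default 1);
#' * `gamma`: drawn from a gamma (`params$shape`, default 0.5, `params$rate` 1);
#' * `uniform`: all `p_i = 1/S_true`.
#' Drawn abundances are normalized to sum to one and sorted descending.
#'
#' @param family Distribution family.
#' @param S_true True number of species (>= 1).
#' @param params Named list of family parameters (see above).
#' @param seed RNG seed (used by the stochastic families).
#' @param population_size Optional finite total number of individuals; integer
#'   per-species counts are then derived by largest-remainder rounding of
#'   `population_size * p_i` so they sum exactly to `population_size`.
#' @return Object of class `synthetic_population`: `p` (descending, sums to
#'   1), `S_true`, `family`, `params`, `seed` and, when finite, `counts` and
#'   `population_size`.
#' @examples
#' pop <- make_population("zipf", 1000, params = list(exponent = 1))
#' pop$p[1] / pop$p[2]  # 2
#' @export
make_population <- function(family = c("zipf", "lognormal", "exponential",
                                       "gamma", "uniform"),
                            S_true, params = list(), seed = 0,
                            population_size = NULL) {
  family <- match.arg(family)
  if (!is_count_scalar(S_true) || S_true < 1) {
    stop_validation("S_true must be a positive integer")
  }
  w <- switch(family,
    zipf = {
      expo <- params$exponent %||% 1
      if (!is.numeric(expo) || expo <= 0) {
        stop_validation("zipf exponent must be > 0")
      }
      seq_len(S_true)^(-expo)
    },
    lognormal = {
      sdlog <- params$sdlog %||% 1
      if (sdlog < 0) stop_validation("lognormal sdlog must be >= 0")
      with_seed(seed, stats::rlnorm(S_true, params$meanlog %||% 0, sdlog))
    },
    exponential = {
      rate <- params$rate %||% 1
      if (rate <= 0) stop_validation("exponential rate must be > 0")
      with_seed(seed, stats::rexp(S_true, rate))
    },
    gamma = {
      shape <- params$shape %||% 0.5
      rate <- params$rate %||% 1
      if (shape <= 0 || rate <= 0) stop_validation("gamma shape and rate must be > 0")
      with_seed(seed, stats::rgamma(S_true, shape, rate))
    },
    uniform = rep(1, S_true))
  w <- pmax(w, 1e-300)
  p <- sort(w / sum(w), decreasing = TRUE)
  out <- structure(list(p = p, S_true = S_true, family = family,
                        params = params, seed = seed,
                        population_size = population_size),
                   class = "synthetic_population")
  if (!is.null(population_size)) {
    if (!is_count_scalar(population_size) || population_size < S_true) {
      stop_validation("population_size must be an integer >= S_true")
    }
    out$counts <- largest_remainder_round(p * population_size)
  }
  out
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %s, S_true = %d%s\n", x$family, x$S_true,
              if (!is.null(x$population_size))
                sprintf(", finite population of %g individuals",
                        x$population_size) else " (infinite)"))
  invisible(x)
}

# Round non-negative reals to integers preserving their (integral) total.
largest_remainder_round <- function(x) {
  base <- floor(x)
  short <- round(sum(x)) - sum(base)
  if (short > 0) {
    top <- order(x - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

#' Draw a sample of individuals from a synthetic population
#'
#' Models a blood draw where every individual has the same detection
#' probability: multinomial sampling from the relative abundances (infinite
#' population, the default) or multivariate hypergeometric sampling without
#' replacement from the integer population counts (`finite = TRUE`).
#'
#' @param pop A [make_population()] object.
#' @param n Number of individuals to draw.
#' @param seed RNG seed.
#' @param finite Sample without replacement from the finite population counts
#'   (requires `population_size` in the population).
#' @return An [abundance_vector()] with `N = n`.
#' @export
draw_sample <- function(pop, n, seed = 0, finite = FALSE) {
  stopifnot(inherits(pop, "synthetic_population"))
  if (!is_count_scalar(n) || n < 1) stop_validation("n must be a positive integer")
  counts <- if (finite) {
    if (is.null(pop$counts)) {
      stop_validation("finite sampling needs a population_size in the population")
    }
    if (n > sum(pop$counts)) {
      stop_validation("n = %g exceeds the finite population of %g", n,
                      sum(pop$counts))
    }
    with_seed(seed, rmvhyper(pop$counts, n))
  } else {
    with_seed(seed, as.integer(stats::rmultinom(1L, n, pop$p)))
  }
  keep <- counts > 0L
  abundance_vector(counts[keep], paste0("sp", which(keep)))
}

#' Simulate PCR amplification bias and sequencing
#'
#' One-step PCR model: every input molecule receives an independent
#' log-normal amplification factor (`meanlog 0`, `sdlog sigma`), and
#' `n_reads` sequence reads are then drawn multinomially with probabilities
#' proportional to each species' total amplified mass. `sigma = 0` preserves
#' relative abundances exactly (amplification is unbiased) but still inflates
#' repetition; `sigma > 0` additionally distorts them, producing the false
#' saturation of read-based rarefaction curves: the read curve plateaus far
#' below the true number of clonotypes in the sample. Species may drop out;
#' read counts always sum to `n_reads`.
#'
#' @param data An [abundance_vector()] of molecule (cell) counts.
#' @param sigma Dispersion (sdlog) of the per-molecule amplification factor
#'   (>= 0).
#' @param n_reads Number of sequence reads to draw (>= 1).
#' @param seed RNG seed.
#' @return An [abundance_vector()] of per-species read counts.
#' @export
simulate_pcr <- function(data, sigma, n_reads, seed = 0) {
  stopifnot(inherits(data, "abundance_vector"))
  if (!is.numeric(sigma) || sigma < 0) stop_validation("sigma must be >= 0")
  if (!is_count_scalar(n_reads) || n_reads < 1) {
    stop_validation("n_reads must be a positive integer")
  }
  reads <- with_seed(seed, {
    weight <- if (sigma == 0) {
      as.numeric(data$counts)
    } else {
      factors <- stats::rlnorm(data$N, meanlog = 0, sdlog = sigma)
      as.numeric(rowsum(factors, rep.int(seq_len(data$S_obs), data$counts)))
    }
    as.integer(stats::rmultinom(1L, n_reads, weight / sum(weight)))
  })
  keep <- reads > 0L
  abundance_vector(reads[keep], data$species_ids[keep])
}

#' End-to-end estimator recovery experiment
#'
#' Harness for the three validation modes of the curve-extrapolation
#' estimator, run against synthetic populations with known richness:
#' * `"subsample"`: draw one sample of `n`, estimate its full observed
#'   richness from a `subsample_fraction` subsample (target: full-sample
#'   `S_obs`);
#' * `"independent"`: draw two independent samples of `n`, estimate from the
#'   first the observed richness of the pooled pair (target: `S_obs` of the
#'   union, extrapolating to `2n`);
#' * `"unequal"`: draw samples of `n` and `2n` and compare the two estimates
#'   of the population richness at a common extrapolation target (target:
#'   `S_true`; the report includes the ratio of the two estimates per seed).
#'
#' @param family,S_true,params,population_size Population spec, as
#'   [make_population()].
#' @param n Sample size.
#' @param estimators Character vector of estimator names understood by
#'   [estimate_vs_size()] (incidence estimators are applied via in-silico
#'   replicate splitting; `"dive"` extrapolates to the mode's target size).
#' @param seeds Integer vector, one experiment per seed.
#' @param mode Validation mode (see above).
#' @param subsample_fraction Fraction for `"subsample"` mode (default 0.25).
#' @param replicates In-silico replicates for incidence estimators.
#' @param dive_args Extra arguments for [dive_estimate()].
#' @return Data frame with one row per (estimator, seed, sample): `estimator`,
#'   `seed`, `sample` (mode-specific label), `estimate`, `target`,
#'   `rel_error` (`(estimate - target) / target`), and `ok`/`reason` for
#'   degenerate cases.
#' @export
recovery_experiment <- function(family, S_true, n, estimators, seeds,
                                mode = c("subsample", "independent", "unequal"),
                                params = list(), population_size = NULL,
                                subsample_fraction = 0.25, replicates = 4,
                                dive_args = list()) {
  mode <- match.arg(mode)
  pop <- make_population(family, S_true, params = params,
                         population_size = population_size)
  finite <- !is.null(population_size)
  rows <- list()
  for (seed in seeds) {
    tasks <- switch(mode,
      subsample = {
        full <- draw_sample(pop, n, seed = seed, finite = finite)
        sub <- nested_subsamples(full, subsample_fraction,
                                 seed = derive_seed(seed, 2L))[[1]]
        list(list(label = "subsample", data = sub, target = full$S_obs,
                  extrap_to = full$N))
      },
      independent = {
        s1 <- draw_sample(pop, n, seed = derive_seed(seed, 11L), finite = finite)
        s2 <- draw_sample(pop, n, seed = derive_seed(seed, 12L), finite = finite)
        pooled_S <- length(union(s1$species_ids, s2$species_ids))
        list(list(label = "independent", data = s1, target = pooled_S,
                  extrap_to = s1$N + s2$N))
      },
      unequal = {
        s1 <- draw_sample(pop, n, seed = derive_seed(seed, 21L), finite = finite)
        s2 <- draw_sample(pop, 2L * n, seed = derive_seed(seed, 22L),
                          finite = finite)
        target_pop <- population_size %||% (10L * n)
        list(list(label = "size_n", data = s1, target = S_true,
                  extrap_to = target_pop),
             list(label = "size_2n", data = s2, target = S_true,
                  extrap_to = target_pop))
      })
    for (task in tasks) {
      for (est_name in estimators) {
        fn <- resolve_estimator(
          est_name, data = list(N = task$extrap_to), replicates = replicates,
          seed = derive_seed(seed, 3L), dive_args = dive_args)
        value <- tryCatch(fn(task$data), error = function(e) e)
        bad <- inherits(value, "error")
        if (!bad && inherits(value, "diversity_estimate")) value <- value$estimate
        rows[[length(rows) + 1L]] <- data.frame(
          estimator = est_name, seed = seed, sample = task$label,
          estimate = if (bad) NA_real_ else value,
          target = task$target,
          rel_error = if (bad) NA_real_ else (value - task$target) / task$target,
          ok = !bad,
          reason = if (bad) conditionMessage(value) else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (mode == "unequal") {
    ratio <- with(out, stats::ave(estimate, estimator, seed, FUN = function(v) {
      if (length(v) == 2L && all(is.finite(v))) v[1] / v[2] else NA_real_
    }))
    out$estimate_ratio <- ratio
  }
  attr(out, "mode") <- mode
  attr(out, "population") <- pop
  out
}
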