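#' Exact individual-based rarefaction
#'
#' Expected number of species in a uniform without-replacement subsample of
#' `x` individuals:
#' \deqn{E[S(x)] = S_{obs} - \sum_i \binom{N - N_i}{x} / \binom{N}{x}}
#' the hypergeometric expectation underlying individual-based rarefaction
#' curves. Binomial ratios are computed in log space so that samples of up to
#' ~1e7 individuals do not overflow.
#'
#' @param data An [abundance_vector()].
#' @param x Integer subsample size(s), `1 <= x <= N`. Vectorized.
#' @return Expected species count, one value per element of `x`.
#' @examples
#' av <- abundance_vector(c(A = 2, B = 1))
#' rarefy_exact(av, 2)  # 5/3
#' @export
rarefy_exact <- function(data, x) {
  stopifnot(inherits(data, "abundance_vector"))
  if (length(x) == 0L || !is.numeric(x) || anyNA(x) || any(x != round(x))) {
    stop_validation("x must be integer subsample sizes")
  }
  if (any(x < 1) || any(x > data$N)) {
    stop_validation("x must lie in [1, N = %d]", data$N)
  }
  N <- data$N
  # matrix of log C(N - N_i, x_j) - log C(N, x_j); lchoose() returns -Inf
  # when N - N_i < x_j, i.e. species i is certainly present.
  lmiss <- outer(N - data$counts, x, lchoose)
  lden <- lchoose(N, x)
  p_missing <- exp(sweep(lmiss, 2L, lden, "-"))
  data$S_obs - colSums(p_missing)
}

#' Rarefaction by Monte-Carlo resampling
#'
#' Mean species count over `n_resamples` independent uniform
#' without-replacement subsamples of size `x`. Retained alongside
#' [rarefy_exact()] because the resampling construction generalizes to
#' statistics with no closed form.
#'
#' @inheritParams rarefy_exact
#' @param x Single integer subsample size.
#' @param n_resamples Number of resamples (>= 1).
#' @param seed RNG seed.
#' @return Mean observed species count (numeric scalar).
#' @export
rarefy_resample <- function(data, x, n_resamples = 100, seed = 0) {
  stopifnot(inherits(data, "abundance_vector"))
  if (!is_count_scalar(x) || x < 1 || x > data$N) {
    stop_validation("x must lie in [1, N = %d]", data$N)
  }
  if (!is_count_scalar(n_resamples) || n_resamples < 1) {
    stop_validation("n_resamples must be a positive integer")
  }
  with_seed(seed, {
    mean(vapply(seq_len(n_resamples), function(i) {
      sum(rmvhyper(data$counts, x) > 0)
    }, numeric(1)))
  })
}

# One multivariate hypergeometric draw: `size` individuals without
# replacement from per-species pool sizes `counts`. Sequential conditional
# binomial sampling via rhyper, O(length(counts)).
rmvhyper <- function(counts, size) {
  remaining <- sum(counts)
  out <- integer(length(counts))
  k <- as.integer(size)
  for (i in seq_along(counts)) {
    if (k == 0L) break
    remaining <- remaining - counts[i]
    if (remaining == 0L) {
      out[i] <- k
      k <- 0L
      break
    }
    out[i] <- as.integer(stats::rhyper(1L, counts[i], remaining, k))
    k <- k - out[i]
  }
  out
}

#' Build an individual-based rarefaction curve
#'
#' Evaluates the expected species count on an evenly spaced integer grid of
#' subsample sizes spanning `[1, N]` (endpoints always included, duplicates
#' after rounding removed).
#'
#' @param data An [abundance_vector()].
#' @param n_points Number of grid points (>= 2, <= N); default 50.
#' @param method `"exact"` (hypergeometric expectation, default) or
#'   `"resample"` (Monte-Carlo mean).
#' @param n_resamples Resamples per grid point when `method = "resample"`.
#' @param seed RNG seed (resampling only).
#' @return An object of class `rarefaction_curve`: list with `x`, `s`,
#'   `N_full`, `S_obs`, `method`, and, for resampling, `n_resamples` and
#'   `seed`.
#' @export
build_curve <- function(data, n_points = 50, method = c("exact", "resample"),
                        n_resamples = 100, seed = 0) {
  stopifnot(inherits(data, "abundance_vector"))
  method <- match.arg(method)
  if (data$N < 2L) stop_validation("need N >= 2 to build a curve")
  if (!is_count_scalar(n_points) || n_points < 2L) {
    stop_validation("n_points must be an integer >= 2")
  }
  n_points <- min(n_points, data$N)
  grid <- unique(round(seq(1, data$N, length.out = n_points)))
  s <- switch(method,
    exact = rarefy_exact(data, grid),
    resample = vapply(seq_along(grid), function(i) {
      rarefy_resample(data, grid[i], n_resamples, derive_seed(seed, i))
    }, numeric(1)))
  out <- structure(
    list(x = grid, s = s, N_full = data$N, S_obs = data$S_obs,
         method = method),
    class = "rarefaction_curve")
  if (method == "resample") {
    out$n_resamples <- n_resamples
    out$seed <- seed
  }
  out
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("<rarefaction_curve> %d points (%s), N_full = %g, S_obs = %g\n",
              length(x$x), x$method, x$N_full, x$S_obs))
  invisible(x)
}

#' Uniform without-replacement subsample of an abundance vector
#'
#' Draws `size` individuals uniformly at random without replacement (a
#' multivariate hypergeometric draw over species).
#'
#' @param data An [abundance_vector()].
#' @param size Number of individuals to keep, `1 <= size <= N`.
#' @param seed RNG seed.
#' @return An [abundance_vector()] whose counts sum to `size`.
#' @export
subsample <- function(data, size, seed = 0) {
  stopifnot(inherits(data, "abundance_vector"))
  if (!is_count_scalar(size) || size < 1 || size > data$N) {
    stop_validation("size must lie in [1, N = %d]", data$N)
  }
  if (size == data$N) return(data)
  counts <- with_seed(seed, rmvhyper(data$counts, size))
  keep <- counts > 0L
  abundance_vector(counts[keep], data$species_ids[keep])
}

#' Nested subsamples of an abundance vector
#'
#' Draws subsamples at the given fractions of `N` such that the individuals of
#' each smaller subsample are a subset of every larger one: a single random
#' permutation of the `N` individuals is truncated at each fraction. Memory is
#' O(N); intended for samples up to ~1e6 individuals.
#'
#' @param data An [abundance_vector()].
#' @param fractions Ascending fractions in (0, 1]; the last may be 1.
#' @param seed RNG seed.
#' @return A list of [abundance_vector()]s, one per fraction (the fraction
#'   stored in attribute `fraction`); sizes are `floor(fraction * N)`.
#' @export
nested_subsamples <- function(data, fractions, seed = 0) {
  stopifnot(inherits(data, "abundance_vector"))
  if (length(fractions) == 0L || any(fractions <= 0) || any(fractions > 1)) {
    stop_validation("fractions must lie in (0, 1]")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop_validation("fractions must be strictly ascending")
  }
  sizes <- pmax(1L, floor(fractions * data$N))
  sizes[fractions == 1] <- data$N
  individuals <- rep.int(seq_len(data$S_obs), data$counts)
  perm <- with_seed(seed, sample(individuals, data$N, replace = FALSE))
  lapply(seq_along(sizes), function(i) {
    tab <- tabulate(perm[seq_len(sizes[i])], nbins = data$S_obs)
    keep <- tab > 0L
    av <- abundance_vector(tab[keep], data$species_ids[keep])
    attr(av, "fraction") <- fractions[i]
    av
  })
}
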