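test_that("estimate-vs-size series records every subsample with provenance", {
  av <- zipf_sample(S_true = 200, n = 4000)
  series <- estimate_vs_size(av, "chao1", fractions = seq(0.2, 1, 0.2),
                             seed = 1)
  expect_equal(nrow(series), 5L)
  expect_true(all(diff(series$n) > 0))
  expect_true(all(series$ok))
  expect_true(all(series$estimate >= series$S_obs_sub))
  expect_equal(attr(series, "N_full"), av$N)
  # an estimator that returns S_obs gives a non-decreasing series under nesting
  s_obs_series <- estimate_vs_size(av, function(x) x$S_obs,
                                   fractions = seq(0.2, 1, 0.2), seed = 1)
  expect_true(all(diff(s_obs_series$estimate) >= 0))
  # constant oracle estimator
  const <- estimate_vs_size(av, function(x) 42, fractions = seq(0.2, 1, 0.2),
                            seed = 1)
  expect_true(all(const$estimate == 42))
  expect_error(estimate_vs_size(av, "chao1", fractions = c(0.001, 1)),
               class = "clonodiv_validation_error")
})

test_that("degenerate estimator points are recorded as missing, not dropped", {
  av <- abundance_vector(c(rep(1, 30), 5, 5, 5))
  # good_turing fails on all-singleton small subsamples occasionally; force
  # failure with an estimator that rejects small inputs
  picky <- function(x) {
    if (x$N < 100) stop(errorCondition("too small",
                                       class = "clonodiv_degenerate_error"))
    x$S_obs
  }
  series <- estimate_vs_size(av, picky, fractions = c(0.5, 0.8, 1.0), seed = 0)
  expect_equal(nrow(series), 3L)
  expect_false(all(series$ok))
  expect_match(series$reason[!series$ok], "too small")
})

test_that("bias gradient matches exact lines and scale contracts", {
  mk_series <- function(n, est) {
    df <- data.frame(fraction = n / max(n), n = n, estimate = est,
                     S_obs_sub = 1, ok = TRUE, reason = "",
                     below_full_S_obs = FALSE)
    class(df) <- c("bias_series", class(df))
    attr(df, "estimator") <- "constructed"
    attr(df, "N_full") <- max(n)
    attr(df, "S_obs_full") <- 1
    df
  }
  n <- c(100, 200, 300, 400)
  # constant series: slope 0
  g0 <- suppressWarnings(bias_gradient(mk_series(n, rep(5, 4))))  # perfect fit
  expect_equal(g0$slope_raw, 0, tolerance = 1e-12)
  expect_equal(g0$slope_norm, 0, tolerance = 1e-12)
  # exact line estimate = 2n
  g2 <- suppressWarnings(bias_gradient(mk_series(n, 2 * n)))  # perfect fit
  expect_equal(g2$slope_raw, 2, tolerance = 1e-12)
  expect_equal(g2$r_squared, 1, tolerance = 1e-12)
  # normalized slope invariant to scaling all estimates by 10
  ga <- suppressWarnings(bias_gradient(mk_series(n, 3 + 0.5 * n)))  # perfect fit
  gb <- suppressWarnings(bias_gradient(mk_series(n, 10 * (3 + 0.5 * n))))  # perfect fit
  expect_equal(ga$slope_norm, gb$slope_norm, tolerance = 1e-12)
  expect_error(bias_gradient(mk_series(n[1:2], c(1, 2))),
               class = "clonodiv_validation_error")
})

test_that("the sign test is exact and matches enumeration for n <= 20", {
  expect_equal(sign_binomial_test(rep(1, 14))$p_two_tailed, 2^-13)
  expect_equal(sign_binomial_test(rep(1, 14))$p_two_tailed, 1.220703e-4,
               tolerance = 1e-6)
  expect_equal(sign_binomial_test(c(rep(1, 7), rep(-1, 7)))$p_two_tailed, 1.0)
  expect_equal(sign_binomial_test(1)$p_two_tailed, 1.0)
  # exhaustive agreement with direct enumeration of the binomial distribution
  for (n in 1:20) {
    probs <- stats::dbinom(0:n, n, 0.5)
    for (k in 0:n) {
      slopes <- c(rep(1, k), rep(-1, n - k))
      p_pkg <- sign_binomial_test(slopes)$p_two_tailed
      p_enum <- min(1, 2 * min(sum(probs[seq_len(k + 1)]),
                               sum(probs[seq(k + 1, n + 1)])))
      expect_equal(p_pkg, p_enum, tolerance = 1e-12,
                   label = sprintf("n=%d k=%d", n, k))
    }
  }
  # zeros are excluded and reported
  res <- sign_binomial_test(c(0, 1, 1, 0, -1))
  expect_equal(res$n, 3L)
  expect_equal(res$n_zero, 2L)
  expect_error(sign_binomial_test(c(0, 0)), class = "clonodiv_validation_error")
})

test_that("curvature is 0 for linear curves and approaches 1 for steps", {
  mk_curve <- function(x, s, N, S) {
    structure(list(x = x, s = s, N_full = N, S_obs = S, method = "exact"),
              class = "rarefaction_curve")
  }
  N <- 1000; S <- 50
  x <- seq(1, N, length.out = 40)
  lin <- mk_curve(x, S * x / N, N, S)
  expect_equal(curvature(lin), 0, tolerance = 1e-12)
  # step curve: everything observed at the first grid point
  step <- mk_curve(c(1, x[-1]), c(S, rep(S, 39)), N, S)
  expect_gt(curvature(step), 0.99)
  # single-species data: curve flat at 1 after x = 1
  one <- abundance_vector(c(A = 500))
  cu <- build_curve(one, 50)
  expect_gt(curvature(cu), 0.9)
  expect_lt(curvature(cu), 1)
})

test_that("the under-sampling guard warns below threshold and passes above", {
  N <- 1000; S <- 50
  x <- seq(1, N, length.out = 40)
  lin <- structure(list(x = x, s = S * x / N, N_full = N, S_obs = S,
                        method = "exact"), class = "rarefaction_curve")
  expect_warning(res <- undersampling_guard(lin, threshold = 0.1), "linear")
  expect_false(res$pass)
  # threshold 0 always passes
  expect_silent(res0 <- undersampling_guard(lin, threshold = 0))
  expect_true(res0$pass)
  sat <- build_curve(zipf_sample(S_true = 20, n = 3000), 30)
  expect_silent(res_sat <- undersampling_guard(sat, 0.1))
  expect_true(res_sat$pass)
})

test_that("classical estimators drift upward with sample size on heavy tails", {
  # small-scale version of the bias protocol: one Zipf dataset, one seed
  pop <- make_population("zipf", 2000, params = list(exponent = 1))
  av <- draw_sample(pop, 20000, seed = 4)
  for (est in c("chao1_bc", "ace", "bootstrap", "good_turing", "chao2")) {
    series <- estimate_vs_size(av, est, fractions = seq(0.2, 1, 0.2), seed = 4)
    grad <- bias_gradient(series)
    expect_gt(grad$slope_norm, 0)
    # underestimation: the smallest subsample estimate sits below the full
    # sample's observed richness (ACE escapes this at such deep sampling
    # depths, where its variance inflation overshoots instead)
    if (est != "ace") expect_true(series$below_full_S_obs[1], label = est)
  }
})
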