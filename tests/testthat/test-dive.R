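# A tiny hand-built "fit" lets the criteria be checked against constructed
# truths without running the optimizer.
constant_shift_model <- function(factor) {
  curve_model(paste0("shift", factor), 2L,
    S = function(x, p) factor * (p[1] * x / (p[2] + x)),
    S1 = function(x, p) factor * p[1] * p[2] / (p[2] + x)^2,
    S2 = function(x, p) -2 * factor * p[1] * p[2] / (p[2] + x)^3,
    lower = c(1e-12, 1e-12), upper = c(Inf, Inf),
    init = function(curve) c(2 * curve$S_obs, curve$N_full / 2))
}

mk_fit <- function(model_name, par, N_full = 1000) {
  structure(list(model = model_name, par = par, converged = TRUE, sse = 0,
                 n_restarts_used = 1, fitted_on = "constructed",
                 N_full = N_full),
            class = "model_fit")
}

test_that("discrepancy is the mean percentage error and is order-invariant", {
  reg <- default_registry()
  x <- c(1, 10, 50, 200, 1000)
  mm <- reg$michaelis_menten
  curve <- structure(list(x = x, s = mm$S(x, c(100, 50)), N_full = 1000,
                          S_obs = mm$S(1000, c(100, 50)), method = "exact"),
                     class = "rarefaction_curve")
  exact_fit <- mk_fit("michaelis_menten", c(100, 50))
  expect_equal(score_discrepancy(exact_fit, curve, mm), 0, tolerance = 1e-12)
  # a model 10% above the data everywhere scores exactly 10
  shifted <- constant_shift_model(1.1)
  expect_equal(score_discrepancy(mk_fit("shift", c(100, 50)), curve, shifted),
               10, tolerance = 1e-9)
  perm <- c(3, 1, 5, 2, 4)
  curve_perm <- curve
  curve_perm$x <- curve$x[perm]; curve_perm$s <- curve$s[perm]
  expect_equal(score_discrepancy(exact_fit, curve_perm, mm),
               score_discrepancy(exact_fit, curve, mm))
})

test_that("accuracy is the symmetric percentage error at full sample size", {
  reg <- default_registry()
  full_curve <- structure(list(x = c(1, 500, 1000), s = c(1, 80, 100),
                               N_full = 1000, S_obs = 100, method = "exact"),
                          class = "rarefaction_curve")
  # hyperbolic with asymptote a/b evaluated at N_full = 1000
  hy <- reg$hyperbolic
  over <- mk_fit("hyperbolic", c(1, 1 / 110.11))
  pred_over <- hy$S(1000, over$par)
  expect_equal(score_accuracy(over, full_curve, hy),
               100 * abs(pred_over - 100) / 100)
  # predictions of 90 and 110 score identically
  p110 <- 110; p90 <- 90
  f110 <- mk_fit("shift", c(1, 1))
  s110 <- curve_model("c110", 2L, S = function(x, p) rep(p110, length(x)),
                      S1 = function(x, p) 0 * x, S2 = function(x, p) 0 * x,
                      lower = c(0, 0), upper = c(Inf, Inf),
                      init = function(curve) c(1, 1))
  s90 <- curve_model("c90", 2L, S = function(x, p) rep(p90, length(x)),
                     S1 = function(x, p) 0 * x, S2 = function(x, p) 0 * x,
                     lower = c(0, 0), upper = c(Inf, Inf),
                     init = function(curve) c(1, 1))
  expect_equal(score_accuracy(f110, full_curve, s110), 10)
  expect_equal(score_accuracy(f110, full_curve, s90), 10)
})

test_that("similarity is a normalized symmetric area and scales linearly", {
  reg <- default_registry()
  mm <- reg$michaelis_menten
  base <- mk_fit("michaelis_menten", c(100, 50))
  expect_equal(score_similarity(base, base, mm, mm, x_max = 1000), 0)
  # S_sub = 1.1 * S_full everywhere -> normalized area exactly 0.1
  shifted <- constant_shift_model(1.1)
  sub <- mk_fit("shift", c(100, 50))
  expect_equal(score_similarity(sub, base, shifted, mm, x_max = 1000), 0.1,
               tolerance = 1e-9)
  # the unnormalized area is symmetric in the two fits; swapping the roles
  # only rescales the reference integral (here by the factor 1.1)
  expect_equal(score_similarity(base, sub, mm, shifted, x_max = 1000),
               0.1 / 1.1, tolerance = 1e-9)
})

test_that("with no extrapolation the estimate stays near the observed richness", {
  av <- zipf_sample(S_true = 150, n = 3000, seed = 7)
  res <- dive_estimate(av, target_population_size = av$N, seed = 1)
  expect_gte(res$estimate$estimate, av$S_obs)
  expect_lte(res$estimate$estimate, av$N)
  expect_lt(abs(res$estimate$estimate - av$S_obs) / av$S_obs, 0.05)
})

test_that("implausible models are never aggregated", {
  av <- zipf_sample(S_true = 100, n = 2000, seed = 3)
  res <- dive_estimate(av, target_population_size = 1e6, seed = 0)
  sc <- res$scorecards
  expect_true(all(sc$plausible[sc$aggregated]))
  expect_true(all(is.na(sc$combined_rank[!sc$plausible])))
  # a registry with only a superlinear-power trap must fail loudly:
  trap <- default_registry()["power"]
  # force b > 1 by bounding it away from the concave region
  trap$power$lower <- c(1e-12, 1.2)
  trap$power$init <- function(curve) c(1e-3, 1.5)
  expect_error(
    dive_estimate(av, target_population_size = 1e6, registry = trap, seed = 0),
    class = "clonodiv_estimation_error")
})

test_that("estimates are reproducible and monotone in the extrapolation target", {
  av <- zipf_sample(S_true = 100, n = 2000, seed = 5)
  r1 <- dive_estimate(av, target_population_size = 1e5, seed = 11)
  r2 <- dive_estimate(av, target_population_size = 1e5, seed = 11)
  expect_identical(r1$estimate$estimate, r2$estimate$estimate)
  expect_identical(r1$scorecards, r2$scorecards)
  r_big <- dive_estimate(av, target_population_size = 1e6, seed = 11)
  expect_lte(r1$estimate$estimate, r_big$estimate$estimate + 1e-9)
  # estimate bounded by the target population
  expect_lte(r_big$estimate$estimate, 1e6)
})

test_that("the under-sampling guard blocks near-linear curves unless forced", {
  # a near-uniform, barely-sampled population yields a near-linear curve
  av2 <- abundance_vector(c(rep(1, 39), 2))
  expect_error(dive_estimate(av2, target_population_size = 1e4, seed = 0),
               class = "clonodiv_undersampling_error")
  forced <- tryCatch(
    dive_estimate(av2, target_population_size = 1e4, seed = 0, force = TRUE),
    clonodiv_estimation_error = function(e) NULL)
  if (!is.null(forced)) {
    expect_match(forced$estimate$warnings, "linear", all = FALSE)
  }
})

test_that("a known Zipf population is recovered within a factor of 1.5", {
  pop <- make_population("zipf", 1000, params = list(exponent = 1),
                         population_size = 1e6)
  av <- draw_sample(pop, 5000, seed = 0, finite = TRUE)
  res <- dive_estimate(av, target_population_size = 1e6, seed = 0)
  est <- res$estimate$estimate
  expect_gt(est, 1000 / 1.5)
  expect_lt(est, 1000 * 1.5)
})

test_that("full-sample richness is recovered from quarter subsamples", {
  errs <- recovery_experiment("zipf", 1000, n = 5000,
                              estimators = c("dive", "chao1_bc", "ace",
                                             "bootstrap", "good_turing"),
                              seeds = 1:10, mode = "subsample",
                              params = list(exponent = 1),
                              population_size = 1e6)
  med <- function(e) stats::median(abs(errs$rel_error[errs$estimator == e]))
  expect_lt(med("dive"), 0.20)
  for (cl in c("chao1_bc", "ace", "bootstrap", "good_turing")) {
    expect_lt(med("dive"), med(cl), label = paste("dive vs", cl))
  }
})

test_that("scorecards export as a readable delimited table", {
  av <- zipf_sample(S_true = 80, n = 1500, seed = 2)
  res <- dive_estimate(av, target_population_size = 1e5, seed = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_scorecards(res, path)
  tab <- utils::read.delim(path)
  expect_true(all(c("model", "discrepancy", "accuracy", "similarity",
                    "plausible", "combined_rank", "prediction",
                    "aggregated") %in% names(tab)))
  expect_equal(nrow(tab), nrow(res$scorecards))
})
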