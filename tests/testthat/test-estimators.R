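test_that("estimators reproduce the hand-derived constants on the fixed vector", {
  av <- fixed_av()
  expect_equal(chao1(av)$estimate, 7.0, tolerance = 1e-9)
  expect_equal(chao1_bc(av)$estimate, 5.5, tolerance = 1e-9)
  expect_equal(good_turing(av)$estimate, 55 / 9, tolerance = 1e-9)
  boot_expected <- 5 + (7 / 11)^11 + (8 / 11)^11 + (9 / 11)^11 + 2 * (10 / 11)^11
  expect_equal(bootstrap_richness(av)$estimate, boot_expected, tolerance = 1e-9)
  # ACE by direct evaluation: C = 9/11, gamma2 = (55/9)*(20/110) - 1 = 1/9
  ace_expected <- 5 / (9 / 11) + (2 / (9 / 11)) * (1 / 9)
  expect_equal(ace(av)$estimate, ace_expected, tolerance = 1e-9)
  expect_equal(ace(av)$estimate, 6.383, tolerance = 1e-3)
})

test_that("chao2 matches both closed forms on the fixed incidence fixture", {
  inc <- fixed_incidence()
  expect_equal(chao2(inc, bias_corrected = FALSE)$estimate, 9.25,
               tolerance = 1e-9)
  expect_equal(chao2(inc, bias_corrected = TRUE)$estimate, 7.75,
               tolerance = 1e-9)
})

test_that("ICE matches an independently hand-coded oracle", {
  inc <- fixed_incidence()
  # oracle computed straight from the incidence matrix, not via the package
  pres <- inc$presence
  inc_counts <- rowSums(pres)
  stopifnot(all(inc_counts <= 10))           # all species infrequent
  n_infreq <- sum(inc_counts)                # 14
  q1 <- sum(inc_counts == 1)                 # 3
  C <- 1 - q1 / n_infreq                     # 11/14
  m_inf <- sum(colSums(pres) > 0)            # 4
  qk_tab <- tabulate(inc_counts, nbins = 4)
  sum_kk1 <- sum((1:4) * (0:3) * qk_tab)     # 22
  g2 <- max(nrow(pres) / C * (m_inf / (m_inf - 1)) * sum_kk1 / n_infreq^2 - 1, 0)
  oracle <- nrow(pres) / C + (q1 / C) * g2
  expect_equal(ice(inc)$estimate, oracle, tolerance = 1e-9)
})

test_that("degenerate limits collapse to S_obs or fail loudly", {
  no_singletons <- abundance_vector(c(5, 4, 2, 2))
  expect_equal(chao1(no_singletons)$estimate, 4)
  expect_equal(chao1_bc(no_singletons)$estimate, 4)
  expect_equal(good_turing(no_singletons)$estimate, 4)
  expect_equal(ace(abundance_vector(c(2, 2, 2)))$estimate, 3)
  # chao1 degenerate f2 = 0 form
  expect_equal(chao1(abundance_vector(c(1, 1)))$estimate, 3.0)
  # chao1_bc with a single singleton
  expect_equal(chao1_bc(abundance_vector(c(3, 1)))$estimate, 2)
  # all-singleton contracts
  expect_error(good_turing(abundance_vector(c(1, 1, 1))),
               class = "clonodiv_degenerate_error")
  expect_error(ace(abundance_vector(c(1, 1, 1))),
               class = "clonodiv_degenerate_error")
  # bootstrap single species: 1 + 0
  expect_equal(bootstrap_richness(abundance_vector(c(A = 5)))$estimate, 1.0)
  # incidence analogues
  all_double <- incidence_data(rbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(chao2(all_double)$estimate, 2)
  expect_equal(chao2(all_double, bias_corrected = FALSE)$estimate, 2)
  expect_equal(ice(all_double)$estimate, 2)
  one_q1 <- incidence_data(rbind(c(1, 0), c(1, 1)))
  expect_equal(chao2(one_q1)$estimate, 2)
})

test_that("every richness estimator is >= S_obs on randomized inputs", {
  set.seed(101)
  for (i in 1:1000) {
    counts <- sample(1:12, sample(2:25, 1), replace = TRUE)
    av <- abundance_vector(counts)
    expect_gte(chao1(av)$estimate, av$S_obs)
    expect_gte(chao1_bc(av)$estimate, av$S_obs)
    expect_gte(bootstrap_richness(av)$estimate, av$S_obs)
    if (sum(counts == 1) < av$N) {
      expect_gte(good_turing(av)$estimate, av$S_obs)
    }
    ace_est <- tryCatch(ace(av)$estimate, clonodiv_degenerate_error =
                          function(e) NA_real_)
    if (!is.na(ace_est)) expect_gte(ace_est, av$S_obs - 1e-9)
    # chao1_bc never exceeds chao1 when doubletons exist
    if (sum(counts == 2) >= 1) {
      expect_lte(chao1_bc(av)$estimate, chao1(av)$estimate + 1e-12)
    }
    # bootstrap excess is bounded by S_obs (1 - 1/N)^N
    expect_lte(bootstrap_richness(av)$estimate - av$S_obs,
               av$S_obs * (1 - 1 / av$N)^av$N + 1e-12)
  }
})

test_that("incidence estimators are >= S_obs on randomized replicate splits", {
  set.seed(202)
  for (i in 1:50) {
    av <- abundance_vector(sample(1:15, 12, replace = TRUE))
    inc <- split_into_replicates(av, 4, seed = i)
    expect_gte(chao2(inc)$estimate, inc$S_obs)
    ice_est <- tryCatch(ice(inc)$estimate, clonodiv_degenerate_error =
                          function(e) NA_real_)
    if (!is.na(ice_est)) expect_gte(ice_est, inc$S_obs - 1e-9)
  }
})

test_that("the population-size cap binds with a warning", {
  av <- abundance_vector(c(rep(1, 9), 2))  # chao1 = 10 + 81/4
  capped <- chao1(av, population_size = 12)
  expect_equal(capped$estimate, 12)
  expect_match(capped$warnings, "capped", all = FALSE)
  uncapped <- chao1(av, population_size = 1e6)
  expect_length(uncapped$warnings, 0L)
})

test_that("diversity indices match closed forms", {
  expect_equal(diversity_indices(abundance_vector(c(2, 2))),
               list(shannon = log(2), simpson = 0.5))
  expect_equal(diversity_indices(abundance_vector(c(A = 7))),
               list(shannon = 0, simpson = 1))
  s <- 8
  unif <- abundance_vector(rep(3, s))
  expect_equal(diversity_indices(unif)$shannon, log(s))
  expect_equal(diversity_indices(unif)$simpson, 1 / s)
})

test_that("similarity indices respect set logic and scale invariance", {
  a <- abundance_vector(c(A = 5, B = 1, C = 2))
  b <- abundance_vector(c(B = 4, C = 1, D = 9))
  sim <- similarity_indices(a, b)
  expect_equal(sim$jaccard, 0.5)
  expect_gt(sim$morisita_horn, 0)
  # identical vectors
  self <- similarity_indices(a, a)
  expect_equal(self$jaccard, 1)
  expect_equal(self$morisita_horn, 1)
  # disjoint species sets
  d <- abundance_vector(c(X = 2, Y = 3))
  expect_equal(similarity_indices(a, d), list(jaccard = 0, morisita_horn = 0))
  # Jaccard unchanged by replicating every individual k times;
  # Morisita-Horn invariant under proportional scaling
  a10 <- abundance_vector(stats::setNames(a$counts * 10, a$species_ids))
  expect_equal(similarity_indices(a10, b)$jaccard, sim$jaccard)
  expect_equal(similarity_indices(a10, b)$morisita_horn, sim$morisita_horn,
               tolerance = 1e-12)
})
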