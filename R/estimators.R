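#' Chao1 richness estimator
#'
#' Lower-bound richness estimator driven by singletons and doubletons:
#' `S_obs + f1^2 / (2 f2)`. When no doubletons are present the standard
#' degenerate form `S_obs + f1 (f1 - 1) / 2` is used instead of failing,
#' because heavy-tailed clonotype data frequently has `f2 = 0` in small
#' subsamples.
#'
#' @param data An [abundance_vector()].
#' @param population_size Optional known maximum population size; estimates
#'   above it are capped with a warning.
#' @return A [diversity_estimate()].
#' @examples
#' chao1(abundance_vector(c(4, 3, 2, 1, 1)))$estimate  # 7
#' @export
chao1 <- function(data, population_size = NULL) {
  stopifnot(inherits(data, "abundance_vector"))
  f1 <- fk(data, 1); f2 <- fk(data, 2)
  est <- if (f2 > 0) data$S_obs + f1^2 / (2 * f2)
         else data$S_obs + f1 * (f1 - 1) / 2
  out <- diversity_estimate("chao1", est, data$N,
                            settings = list(degenerate_f2 = (f2 == 0)))
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Bias-corrected Chao1 estimator
#'
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`; equals `S_obs` when `f1 <= 1` and is
#' never larger than [chao1()].
#'
#' @inheritParams chao1
#' @return A [diversity_estimate()].
#' @export
chao1_bc <- function(data, population_size = NULL) {
  stopifnot(inherits(data, "abundance_vector"))
  f1 <- fk(data, 1); f2 <- fk(data, 2)
  est <- data$S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  out <- diversity_estimate("chao1_bc", est, data$N)
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Abundance-based coverage estimator (ACE)
#'
#' Splits species at a rare/abundant cutoff (default count 10), estimates the
#' sample coverage of the rare group as `C = 1 - f1 / N_rare`, and inflates by
#' a squared coefficient of variation:
#' \deqn{\hat S = S_{abund} + S_{rare}/C + (f_1/C)\,\gamma^2}
#' with \eqn{\gamma^2 = \max\{(S_{rare}/C)\sum k(k-1)f_k / (N_{rare}(N_{rare}-1)) - 1,\ 0\}.}
#'
#' @inheritParams chao1
#' @param rare_cutoff Count at or below which a species is "rare" (>= 1).
#' @return A [diversity_estimate()].
#' @export
ace <- function(data, rare_cutoff = 10, population_size = NULL) {
  stopifnot(inherits(data, "abundance_vector"))
  if (!is_count_scalar(rare_cutoff) || rare_cutoff < 1) {
    stop_validation("rare_cutoff must be an integer >= 1")
  }
  rare <- data$counts <= rare_cutoff
  S_rare <- sum(rare)
  S_abund <- data$S_obs - S_rare
  if (S_rare == 0L) {
    # no rare group: coverage estimation has nothing to correct
    out <- diversity_estimate("ace", data$S_obs, data$N,
                              settings = list(rare_cutoff = rare_cutoff))
    return(apply_population_cap(out, population_size))
  }
  N_rare <- sum(data$counts[rare])
  f1 <- fk(data, 1)
  C_ace <- 1 - f1 / N_rare
  if (C_ace <= 0) {
    stop_degenerate(paste("ACE coverage is zero (all rare species are",
                          "singletons); fall back to chao1()"))
  }
  ks <- seq_len(rare_cutoff)
  sum_kk1 <- sum(ks * (ks - 1) * fk(data, ks))
  gamma2 <- max((S_rare / C_ace) * sum_kk1 / (N_rare * (N_rare - 1)) - 1, 0)
  est <- S_abund + S_rare / C_ace + (f1 / C_ace) * gamma2
  out <- diversity_estimate("ace", est, data$N,
                            settings = list(rare_cutoff = rare_cutoff,
                                            coverage = C_ace, gamma2 = gamma2))
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Chao2 incidence-based richness estimator
#'
#' Incidence analogue of Chao1 using the species present in exactly one (`q1`)
#' or two (`q2`) of `m` replicates. The small-m bias-corrected form
#' `S_obs + ((m-1)/m) q1 (q1 - 1) / (2 (q2 + 1))` is the default since the
#' typical use here divides one sample into a handful of in-silico replicates;
#' the classic `S_obs + q1^2 / (2 q2)` form is available with
#' `bias_corrected = FALSE`.
#'
#' @param data An [incidence_data()].
#' @param bias_corrected Use the bias-corrected small-m form (default `TRUE`).
#' @inheritParams chao1
#' @return A [diversity_estimate()].
#' @export
chao2 <- function(data, bias_corrected = TRUE, population_size = NULL) {
  stopifnot(inherits(data, "incidence_data"))
  if (data$m < 2L) stop_validation("chao2 needs m >= 2 replicates")
  q1 <- qk(data, 1); q2 <- qk(data, 2)
  est <- if (bias_corrected) {
    data$S_obs + ((data$m - 1) / data$m) * q1 * (q1 - 1) / (2 * (q2 + 1))
  } else if (q2 > 0) {
    data$S_obs + q1^2 / (2 * q2)
  } else {
    data$S_obs + q1 * (q1 - 1) / 2
  }
  out <- diversity_estimate("chao2", est, sum(data$presence),
                            settings = list(m = data$m,
                                            bias_corrected = bias_corrected))
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Incidence-based coverage estimator (ICE)
#'
#' Incidence analogue of [ace()]: species are split at an infrequent/frequent
#' cutoff (default 10 replicate-occurrences), the coverage of the infrequent
#' group is `C = 1 - q1 / n_infreq` where `n_infreq` is the total number of
#' incidences of infrequent species, and a variance-inflation term of the same
#' algebraic shape as ACE's is added:
#' \deqn{\hat S = S_{freq} + S_{infreq}/C + (q_1/C)\,\gamma^2}
#' with \eqn{\gamma^2 = \max\{(S_{infreq}/C)\,\frac{m_\infty}{m_\infty - 1}\,
#'   \sum k(k-1)q_k / n_{infreq}^2 - 1,\ 0\}}, where \eqn{m_\infty} is the
#' number of replicates containing at least one infrequent species.
#'
#' @param data An [incidence_data()].
#' @param infreq_cutoff Incidence count at or below which a species is
#'   "infrequent".
#' @inheritParams chao1
#' @return A [diversity_estimate()].
#' @export
ice <- function(data, infreq_cutoff = 10, population_size = NULL) {
  stopifnot(inherits(data, "incidence_data"))
  if (data$m < 2L) stop_validation("ice needs m >= 2 replicates")
  inc <- rowSums(data$presence)
  infreq <- inc <= infreq_cutoff
  S_infreq <- sum(infreq)
  S_freq <- data$S_obs - S_infreq
  if (S_infreq == 0L) {
    out <- diversity_estimate("ice", data$S_obs, sum(data$presence),
                              settings = list(infreq_cutoff = infreq_cutoff))
    return(apply_population_cap(out, population_size))
  }
  n_infreq <- sum(inc[infreq])
  q1 <- qk(data, 1)
  C_ice <- 1 - q1 / n_infreq
  if (C_ice <= 0) {
    stop_degenerate(paste("ICE coverage is zero (every infrequent species is",
                          "in a single replicate); fall back to chao2()"))
  }
  m_inf <- sum(colSums(data$presence[infreq, , drop = FALSE]) > 0)
  ks <- seq_len(min(infreq_cutoff, data$m))
  sum_kk1 <- sum(ks * (ks - 1) * qk(data, ks))
  gamma2 <- if (m_inf > 1) {
    max((S_infreq / C_ice) * (m_inf / (m_inf - 1)) * sum_kk1 / n_infreq^2 - 1, 0)
  } else 0
  est <- S_freq + S_infreq / C_ice + (q1 / C_ice) * gamma2
  out <- diversity_estimate("ice", est, sum(data$presence),
                            settings = list(infreq_cutoff = infreq_cutoff,
                                            coverage = C_ice, gamma2 = gamma2))
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Bootstrap richness estimator
#'
#' `S_obs + sum_i (1 - N_i/N)^N`: each observed species contributes the
#' probability that a bootstrap resample of the data would miss it.
#'
#' @inheritParams chao1
#' @return A [diversity_estimate()].
#' @export
bootstrap_richness <- function(data, population_size = NULL) {
  stopifnot(inherits(data, "abundance_vector"))
  est <- data$S_obs + sum((1 - data$counts / data$N)^data$N)
  out <- diversity_estimate("bootstrap", est, data$N)
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Good-Turing richness estimator
#'
#' Estimates sample coverage as `C = 1 - f1/N` and returns `S_obs / C`. When
#' every individual is a singleton the coverage estimate is zero and the
#' sample carries no information about richness, so an error is raised.
#'
#' @inheritParams chao1
#' @return A [diversity_estimate()].
#' @export
good_turing <- function(data, population_size = NULL) {
  stopifnot(inherits(data, "abundance_vector"))
  f1 <- fk(data, 1)
  if (f1 >= data$N) {
    stop_degenerate("Good-Turing coverage is zero (all species are singletons); sample uninformative")
  }
  coverage <- 1 - f1 / data$N
  out <- diversity_estimate("good_turing", data$S_obs / coverage, data$N,
                            settings = list(coverage = coverage))
  apply_population_cap(check_floor(out, data$S_obs), population_size)
}

#' Shannon entropy and Simpson index
#'
#' Dispersion indices of the relative abundances `p_i = N_i / N`: Shannon
#' entropy `-sum p_i log p_i` in natural-log units (nats; other bases only
#' rescale) and the Simpson concentration `sum p_i^2`.
#'
#' @param data An [abundance_vector()].
#' @return List with elements `shannon` and `simpson`.
#' @export
diversity_indices <- function(data) {
  stopifnot(inherits(data, "abundance_vector"))
  p <- data$counts / data$N
  list(shannon = -sum(p * log(p)), simpson = sum(p^2))
}

#' Jaccard and Morisita-Horn similarity between two samples
#'
#' Jaccard is incidence-based (shared species / union of species) and so is
#' unchanged by replicating every individual; Morisita-Horn,
#' `2 sum p_i q_i / (sum p_i^2 + sum q_i^2)` over the species union, is
#' invariant under proportional rescaling of either sample. Both lie in
#' `[0, 1]`.
#'
#' @param a,b [abundance_vector()]s.
#' @return List with elements `jaccard` and `morisita_horn`.
#' @export
similarity_indices <- function(a, b) {
  stopifnot(inherits(a, "abundance_vector"), inherits(b, "abundance_vector"))
  union_ids <- union(a$species_ids, b$species_ids)
  pa <- stats::setNames(numeric(length(union_ids)), union_ids)
  pb <- pa
  pa[a$species_ids] <- a$counts / a$N
  pb[b$species_ids] <- b$counts / b$N
  shared <- sum(pa > 0 & pb > 0)
  denom <- sum(pa^2) + sum(pb^2)
  list(jaccard = shared / length(union_ids),
       morisita_horn = if (denom == 0) 0 else 2 * sum(pa * pb) / denom)
}
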