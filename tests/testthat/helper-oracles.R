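# Shared fixtures and independent oracles, all built in code.

# The reference vector used for hand-derived estimator constants.
fixed_av <- function() abundance_vector(c(A = 4, B = 3, C = 2, D = 1, E = 1))

# 7 species x 4 replicates with q1 = 3, q2 = 2 (plus one species in 3 and
# one in all 4 replicates); every replicate non-empty.
fixed_incidence <- function() {
  m <- rbind(
    s1 = c(1, 0, 0, 0),
    s2 = c(0, 1, 0, 0),
    s3 = c(0, 0, 1, 0),
    s4 = c(1, 1, 0, 0),
    s5 = c(0, 0, 1, 1),
    s6 = c(1, 1, 1, 0),
    s7 = c(1, 1, 1, 1))
  incidence_data(m)
}

# Brute-force rarefaction oracle: mean distinct-species count over complete
# enumeration of all C(N, x) subsets of individuals.
brute_force_rarefy <- function(counts, x) {
  individuals <- rep.int(seq_along(counts), counts)
  subsets <- utils::combn(length(individuals), x)
  mean(apply(subsets, 2, function(idx) length(unique(individuals[idx]))))
}

# All integer partitions of n (every abundance vector shape with N = n).
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

# A reproducible heavy-tailed test sample.
zipf_sample <- function(S_true = 100, n = 2000, seed = 42, exponent = 1) {
  pop <- make_population("zipf", S_true, params = list(exponent = exponent))
  draw_sample(pop, n, seed = seed)
}

# Standard error of a Monte-Carlo mean.
mc_se <- function(values) stats::sd(values) / sqrt(length(values))
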