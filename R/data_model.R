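#' Construct an abundance vector
#'
#' The universal input of the abundance-based estimators: absolute counts of
#' individuals (e.g. T cells) per species (e.g. TCR clonotype). Species with a
#' zero count are dropped with a warning, since published count tables often
#' list absent species. The frequency-of-frequencies table `f` (`f[k]` =
#' number of species seen exactly `k` times) is tallied at construction; the
#' singleton and doubleton counts `f[1]`, `f[2]` drive the Chao-type
#' estimators.
#'
#' @param counts Non-negative integer counts, one per species.
#' @param species_ids Unique species labels; defaults to `names(counts)` or
#'   `sp1, sp2, ...`. Labels are opaque: no sequence parsing is done.
#' @return An object of class `abundance_vector` with elements `species_ids`,
#'   `counts`, `N` (total individuals), `S_obs` (observed richness) and `f`
#'   (named integer vector of frequency counts).
#' @examples
#' av <- abundance_vector(c(A = 4, B = 3, C = 2, D = 1, E = 1))
#' av$N      # 11
#' av$S_obs  # 5
#' @export
abundance_vector <- function(counts, species_ids = NULL) {
  if (length(counts) == 0L) stop_validation("abundance table is empty")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop_format("counts must be numeric and non-missing")
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts))[1L]
    stop_format("count in row %d (%s) is not an integer", bad,
                format(counts[bad]))
  }
  if (any(counts < 0)) {
    stop_format("negative count in row %d", which(counts < 0)[1L])
  }
  if (is.null(species_ids)) {
    species_ids <- names(counts) %||% paste0("sp", seq_along(counts))
  }
  counts <- as.integer(round(counts))  # drops names; ids already captured
  species_ids <- as.character(species_ids)
  if (length(species_ids) != length(counts)) {
    stop_validation("species_ids and counts differ in length")
  }
  if (anyDuplicated(species_ids)) {
    stop_validation("duplicate species_id: %s",
                    species_ids[anyDuplicated(species_ids)])
  }
  zero <- counts == 0L
  if (any(zero)) {
    warning(sprintf("dropped %d zero-count species", sum(zero)),
            call. = FALSE)
    counts <- counts[!zero]
    species_ids <- species_ids[!zero]
  }
  if (length(counts) == 0L) stop_validation("no species with count >= 1")
  f_tab <- table(counts)
  f <- as.integer(f_tab)
  names(f) <- names(f_tab)
  out <- structure(
    list(species_ids = species_ids,
         counts = unname(counts),
         N = sum(counts),
         S_obs = length(counts),
         f = f),
    class = "abundance_vector")
  stopifnot(sum(as.integer(names(f)) * f) == out$N, sum(f) == out$S_obs)
  out
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("<abundance_vector> S_obs = %d species, N = %d individuals\n",
              x$S_obs, x$N))
  cat(sprintf("  f1 = %d singletons, f2 = %d doubletons\n",
              fk(x, 1), fk(x, 2)))
  invisible(x)
}

# f[k] with 0 for absent k
fk <- function(x, k) {
  v <- unname(x$f[as.character(k)])
  v[is.na(v)] <- 0L
  v
}

#' Construct incidence data
#'
#' Presence/absence of species across `m >= 2` replicate samples, the input of
#' the incidence-based estimators (Chao2, ICE). Species absent from every
#' replicate are dropped with a warning. The incidence frequency counts `q`
#' (`q[k]` = species present in exactly `k` replicates) are tallied at
#' construction.
#'
#' @param presence Logical (or numeric, `> 0` meaning present) matrix,
#'   species in rows, replicates in columns.
#' @param species_ids Unique species labels; defaults to row names.
#' @return An object of class `incidence_data` with elements `species_ids`,
#'   `presence`, `m`, `q` and `S_obs`.
#' @export
incidence_data <- function(presence, species_ids = NULL) {
  presence <- as.matrix(presence)
  if (ncol(presence) < 2L) {
    stop_validation("incidence data needs m >= 2 replicates, got %d",
                    ncol(presence))
  }
  if (is.numeric(presence)) {
    if (anyNA(presence)) stop_format("missing values in incidence matrix")
    if (any(presence < 0)) stop_validation("negative entry in incidence matrix")
    presence <- presence > 0
  }
  if (!is.logical(presence)) stop_format("incidence matrix must be numeric or logical")
  if (is.null(species_ids)) {
    species_ids <- rownames(presence) %||% paste0("sp", seq_len(nrow(presence)))
  }
  species_ids <- as.character(species_ids)
  if (anyDuplicated(species_ids)) {
    stop_validation("duplicate species_id: %s",
                    species_ids[anyDuplicated(species_ids)])
  }
  seen <- rowSums(presence) > 0
  if (!all(seen)) {
    warning(sprintf("dropped %d species absent from all replicates", sum(!seen)),
            call. = FALSE)
    presence <- presence[seen, , drop = FALSE]
    species_ids <- species_ids[seen]
  }
  if (nrow(presence) == 0L) stop_validation("no species present in any replicate")
  inc <- rowSums(presence)
  q_tab <- table(inc)
  q <- as.integer(q_tab)
  names(q) <- names(q_tab)
  out <- structure(
    list(species_ids = species_ids,
         presence = unname(presence),
         m = ncol(presence),
         q = q,
         S_obs = nrow(presence)),
    class = "incidence_data")
  stopifnot(sum(q) == out$S_obs)
  out
}

#' @export
print.incidence_data <- function(x, ...) {
  cat(sprintf("<incidence_data> S_obs = %d species x m = %d replicates\n",
              x$S_obs, x$m))
  cat(sprintf("  q1 = %d, q2 = %d\n", qk(x, 1), qk(x, 2)))
  invisible(x)
}

qk <- function(x, k) {
  v <- unname(x$q[as.character(k)])
  v[is.na(v)] <- 0L
  v
}

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an abundance table
#'
#' Reads a delimited text file with a header row and columns `species_id` and
#' `count` into an [abundance_vector()]. Tab-separated by default; `.csv`
#' files are read comma-separated.
#'
#' @param path File path.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return An [abundance_vector()].
#' @export
read_abundance <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("species_id", "count")
  if (!all(need %in% names(df))) {
    stop_format("abundance table must have columns %s",
                paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_validation("abundance table is empty")
  counts <- suppressWarnings(as.numeric(df$count))
  if (anyNA(counts)) {
    bad <- which(is.na(counts))[1L]
    stop_format("count in row %d ('%s') does not parse as a number",
                bad, df$count[bad])
  }
  abundance_vector(counts, df$species_id)
}

#' Read an incidence table
#'
#' Reads a wide delimited text file (first column `species_id`, one column per
#' replicate, integer entries where `> 0` means present) into
#' [incidence_data()].
#'
#' @inheritParams read_abundance
#' @return An [incidence_data()].
#' @export
read_incidence <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                          stringsAsFactors = FALSE)
  if (!"species_id" %in% names(df)) {
    stop_format("incidence table must have a species_id column")
  }
  mat <- as.matrix(df[setdiff(names(df), "species_id")])
  if (!is.numeric(mat)) stop_format("replicate columns must be numeric")
  incidence_data(mat, df$species_id)
}

#' Write an abundance vector to a delimited file
#'
#' @param data An [abundance_vector()].
#' @param path Output path (`.csv` gives comma separation, else tab).
#' @param sep Optional explicit separator.
#' @export
write_abundance <- function(data, path, sep = NULL) {
  df <- data.frame(species_id = data$species_ids, count = data$counts)
  utils::write.table(df, path, sep = infer_sep(path, sep),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an incidence matrix to a delimited file
#'
#' @param data An [incidence_data()].
#' @inheritParams write_abundance
#' @export
write_incidence <- function(data, path, sep = NULL) {
  mat <- data$presence * 1L
  colnames(mat) <- paste0("rep", seq_len(ncol(mat)))
  df <- data.frame(species_id = data$species_ids, mat)
  utils::write.table(df, path, sep = infer_sep(path, sep),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Randomly divide a sample into in-silico replicates
#'
#' Assigns each of the `N` individuals independently and uniformly at random
#' to one of `r` replicates (an individual-level multinomial split) and
#' returns the derived presence/absence data. This is how incidence-based
#' estimators (Chao2, ICE) are applied to a single abundance sample. The
#' per-species replicate counts are retained in the `replicate_counts`
#' attribute so the split can be checked to conserve individuals.
#'
#' @param data An [abundance_vector()].
#' @param r Number of replicates, `2 <= r <= N`.
#' @param seed RNG seed.
#' @return An [incidence_data()] with attribute `replicate_counts` (species x
#'   replicate integer matrix summing to the original counts).
#' @export
split_into_replicates <- function(data, r, seed = 0) {
  stopifnot(inherits(data, "abundance_vector"))
  if (!is_count_scalar(r) || r < 2L) stop_validation("r must be an integer >= 2")
  if (r > data$N) stop_validation("r = %d exceeds N = %d", r, data$N)
  counts <- with_seed(seed, {
    t(vapply(data$counts,
             function(n) as.integer(stats::rmultinom(1L, n, rep(1, r))),
             integer(r)))
  })
  inc <- incidence_data(counts > 0, data$species_ids)
  attr(inc, "replicate_counts") <- counts
  attr(inc, "seed") <- seed
  inc
}

#' Construct a diversity estimate record
#'
#' A point estimate of species richness with full provenance: the estimator
#' name, the sample size it was computed from, the extrapolation target (DivE
#' only), every setting including the seed, and any warnings (e.g. an
#' under-sampling guard or a population-size cap that bound).
#'
#' @param method Estimator name.
#' @param estimate Point estimate of richness (>= 0).
#' @param sample_size `N` of the input sample.
#' @param target_population_size Population size extrapolated to, or `NULL`.
#' @param settings Named list of all parameters needed to reproduce the run.
#' @param warnings Character vector of warnings attached to the estimate.
#' @return An object of class `diversity_estimate`.
#' @export
diversity_estimate <- function(method, estimate, sample_size,
                               target_population_size = NULL,
                               settings = list(), warnings = character()) {
  stopifnot(is.character(method), length(method) == 1L,
            is.numeric(estimate), length(estimate) == 1L, estimate >= 0)
  structure(
    list(method = method,
         estimate = as.numeric(estimate),
         sample_size = as.numeric(sample_size),
         target_population_size = if (is.null(target_population_size)) NULL
                                  else as.numeric(target_population_size),
         settings = settings,
         warnings = as.character(warnings)),
    class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> %s: S-hat = %.4g (from N = %g%s)\n",
              x$method, x$estimate, x$sample_size,
              if (!is.null(x$target_population_size))
                sprintf(", extrapolated to N_pop = %g",
                        x$target_population_size) else ""))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Apply the optional maximum-upper-bound cap: richness cannot exceed the
# number of individuals in the population the user specifies.
apply_population_cap <- function(est, population_size) {
  if (!is.null(population_size) && est$estimate > population_size) {
    est$warnings <- c(est$warnings,
                      sprintf("estimate %.4g capped at population size %g",
                              est$estimate, population_size))
    est$estimate <- as.numeric(population_size)
  }
  est$settings$population_cap <- population_size
  est
}

# Record (do not fail) when an estimator lands below the observed richness.
check_floor <- function(est, S_obs) {
  if (est$estimate < S_obs) {
    est$warnings <- c(est$warnings,
                      sprintf("estimate %.4g is below S_obs = %d", est$estimate,
                              S_obs))
  }
  est
}

#' Write and read machine-readable estimate reports
#'
#' Serializes a list of [diversity_estimate()] records to JSON with full
#' settings and seeds, and reads them back losslessly.
#'
#' @param estimates List of [diversity_estimate()] objects (may be empty).
#' @param path Output path.
#' @return `write_estimate_report` returns the path invisibly;
#'   `read_estimate_report` returns a list of `diversity_estimate` objects.
#' @export
write_estimate_report <- function(estimates, path) {
  stopifnot(is.list(estimates))
  recs <- lapply(estimates, function(e) {
    stopifnot(inherits(e, "diversity_estimate"))
    unclass(e)
  })
  ok <- tryCatch({
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_validation("cannot write report to %s: %s", path,
                                   conditionMessage(ok))
  invisible(path)
}

#' @rdname write_estimate_report
#' @export
read_estimate_report <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    diversity_estimate(r$method, r$estimate, r$sample_size,
                       r$target_population_size,
                       settings = r$settings %||% list(),
                       warnings = unlist(r$warnings) %||% character())
  })
}
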