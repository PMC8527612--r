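# Shared fixtures and brute-force oracles used across the suite.

iset <- function(chrom, start, end, ...) interval_set(chrom, start, end, ...)

random_interval_set <- function(n, chrom = "chr1", chrom_len = 10000,
                                max_len = 500, chrom_sizes = NULL) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  interval_set(rep(chrom, n), start, pmin(start + len, chrom_len),
               chrom_sizes = chrom_sizes)
}

# per-base boolean coverage oracle on a single chromosome
coverage_vector <- function(set, chrom, chrom_len) {
  v <- logical(chrom_len)
  rows <- which(set$chrom == chrom)
  for (i in rows) v[(set$start[i] + 1):set$end[i]] <- TRUE
  v
}

# dense per-base signal oracle helpers
dense_track <- function(values_by_chrom, normalized = FALSE) {
  signal_track(values_by_chrom, normalized = normalized)
}

oracle_query <- function(values, start, end, stat) {
  # values: dense numeric; BED half-open [start, end)
  out <- numeric(length(start))
  for (i in seq_along(start)) {
    idx <- seq.int(start[i] + 1, min(end[i], length(values)))
    idx <- idx[idx >= 1 & idx <= length(values)]
    v <- values[idx]
    out[i] <- if (stat == "sum") sum(v) else if (length(v)) max(v, 0) else 0
  }
  out
}

# tiny synthetic bundle shared across tests (cached per session)
small_sim_config <- function(seed = 7, ...) {
  sim_config(seed = seed,
             chrom_sizes = stats::setNames(rep(150000, 2),
                                           c("scaffold_1", "scaffold_2")),
             n_crms = 60, frac_promoter_overlap = 10 / 60, ...)
}

small_bundle_cache <- new.env(parent = emptyenv())
get_small_bundle <- function() {
  if (is.null(small_bundle_cache$bundle))
    small_bundle_cache$bundle <- simulate_crm_study(small_sim_config())
  small_bundle_cache$bundle
}

default_bundle_cache <- new.env(parent = emptyenv())
get_default_bundle <- function() {
  if (is.null(default_bundle_cache$bundle))
    default_bundle_cache$bundle <- simulate_crm_study(sim_config(seed = 11))
  default_bundle_cache$bundle
}

# small feature table with a clean signal -> activity relation, for fast
# model/evaluation tests that do not need the full generator
toy_feature_table <- function(n = 120, prevalence = 0.25, beta = 2,
                              seed = 5, noise = 1) {
  set.seed(seed)
  active <- seq_len(n) <= round(n * prevalence)
  x1 <- exp(rnorm(n, mean = beta * active, sd = noise))
  x2 <- exp(rnorm(n, mean = beta * active, sd = noise))
  x3 <- exp(rnorm(n, mean = 0.5 * beta * active, sd = noise))
  data.frame(crm_id = sprintf("C%03d", seq_len(n)),
             ATAC_sum = x1, ATAC_max = x1 / 3,
             dREG_sum = x2, dREG_max = x2 / 3,
             PolII_sum = x3, PolII_max = x3 / 3,
             expr = pmax(0, 1 + 2 * active + rnorm(n, 0, 0.3)),
             active = active,
             promoter_overlap = rep(FALSE, n))
}
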