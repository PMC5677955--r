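# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# exact lower-tail binomial CDF by direct summation of the pmf on the log
# scale (no pbinom)
oracle_binom_lower <- function(alt, depth, p = 0.5) {
  k <- 0:alt
  sum(exp(lchoose(depth, k) + k * log(p) + (depth - k) * log1p(-p)))
}

# exhaustive burden oracle: fraction of all N-subsets of the pool whose
# carrier frequency exceeds (or ties, per tie_rule) the target frequency
oracle_burden_p <- function(flags, target_freq, N,
                            tie_rule = "strict_greater") {
  subsets <- combn(length(flags), N)
  freqs <- colMeans(matrix(flags[subsets], nrow = N))
  if (tie_rule == "strict_greater") mean(freqs > target_freq)
  else mean(freqs >= target_freq)
}

# exhaustive signed-rank oracle: full 2^n sign-flip enumeration of
# P(W >= w_obs) for the positive-rank sum, tie-aware via midranks
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  if (alternative == "greater") mean(w_all >= w_obs - 1e-9)
  else mean(w_all <= w_obs + 1e-9)
}

# small cohort configuration used by several tests
small_config <- function(...) {
  cohort_config(n_cases = 200, n_controls = 200,
                phenotype_counts = c(OV = 100, GBM = 100),
                carrier_base_rate = 0.05, seed = 42, ...)
}

# build a minimal samples/carriers pair directly (no generator), with
# identical ages so age-matching always accepts
flat_cases <- function(flags, phenotype, age = 60) {
  n <- length(flags)
  samples <- data.frame(sample_id = sprintf("C%03d", seq_len(n)),
                        status = "case", phenotype = phenotype,
                        age = age, mean_coverage = 30,
                        stringsAsFactors = FALSE)
  carriers <- data.frame(sample_id = samples$sample_id,
                         is_carrier = as.logical(flags),
                         carrier_genes = ifelse(flags, "PPM1D", ""),
                         n_mosaic_ptv = as.integer(flags),
                         stringsAsFactors = FALSE)
  list(samples = samples, carriers = carriers)
}
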