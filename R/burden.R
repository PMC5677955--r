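#' Bonferroni significance threshold
#'
#' Family-wise threshold for testing `n_tests` phenotypes at level
#' `alpha`: `alpha / n_tests` (e.g. 0.05 / 20 = 0.0025).
#'
#' @param alpha Family-wise error level.
#' @param n_tests Number of tests.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (!is_count(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}

# two-sided Wilcoxon rank-sum p for the age-match acceptance filter;
# normal approximation with continuity correction, and p = 1 when every
# age in both groups is identical (no rank variance)
age_match_p <- function(x, y) {
  if (max(x, y) == min(x, y)) return(1)
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                    correct = TRUE)$p.value)
  if (is.na(p)) 1 else p
}

#' Draw one age-matched random case set
#'
#' Draws `N` samples uniformly without replacement from the case pool and
#' accepts the draw when a two-sided Wilcoxon rank-sum test finds no
#' significant age difference from the target set (p > `age_match_alpha`).
#' Up to `max_draw_factor` attempts are made; running out is an error
#' naming the phenotype, signalling that the phenotype's age distribution
#' cannot be matched from the pool.
#'
#' @param pool_ages Ages of the full case pool.
#' @param target_ages Ages of the target phenotype's cases.
#' @param N Set size to draw.
#' @param params A [resampling_params()].
#' @param phenotype Label used in error messages.
#' @return A list with `indices` (into the pool), `age_p` (the acceptance
#'   Wilcoxon p) and `n_attempts`.
#' @export
draw_age_matched_set <- function(pool_ages, target_ages, N,
                                 params = resampling_params(),
                                 phenotype = "target") {
  if (length(pool_ages) < N)
    stop("pool smaller than the requested set size")
  constant <- max(pool_ages, target_ages) == min(pool_ages, target_ages)
  for (tries in seq_len(params$max_draw_factor)) {
    idx <- sample.int(length(pool_ages), N)
    p <- if (constant) 1 else age_match_p(pool_ages[idx], target_ages)
    if (p > params$age_match_alpha)
      return(list(indices = idx, age_p = p, n_attempts = tries))
  }
  stop("could not draw an age-matched set for phenotype '", phenotype,
       "' within ", params$max_draw_factor,
       " attempts: age distribution unmatched")
}

# draw B accepted sets and return the B x K matrix of carrier frequencies,
# one column per flag vector in flags (n_pool x K logical matrix)
resample_freqs <- function(pool_ages, target_ages, N, flags, params,
                           phenotype = "target") {
  B <- params$n_resamples
  K <- ncol(flags)
  freqs <- matrix(NA_real_, B, K)
  attempts <- 0L
  constant <- max(pool_ages, target_ages) == min(pool_ages, target_ages)
  n_pool <- length(pool_ages)
  for (b in seq_len(B)) {
    ok <- FALSE
    for (tries in seq_len(params$max_draw_factor)) {
      idx <- sample.int(n_pool, N)
      attempts <- attempts + 1L
      if (constant ||
          age_match_p(pool_ages[idx], target_ages) > params$age_match_alpha) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not draw an age-matched set for phenotype '", phenotype,
           "' within ", params$max_draw_factor,
           " attempts: age distribution unmatched")
    freqs[b, ] <- colMeans(flags[idx, , drop = FALSE])
  }
  list(freqs = freqs, n_attempts = attempts)
}

per_gene_flags <- function(carriers, genes) {
  gene_sets <- strsplit(carriers$carrier_genes, ",", fixed = TRUE)
  out <- matrix(FALSE, nrow(carriers), length(genes),
                dimnames = list(NULL, genes))
  for (j in seq_along(genes))
    out[, j] <- vapply(gene_sets, function(g) genes[j] %in% g, TRUE)
  out
}

burden_row <- function(phenotype, gene, N, observed, freqs, params,
                       n_attempts, sig_threshold) {
  exceed <- if (params$tie_rule == "strict_greater") sum(freqs > observed)
            else sum(freqs >= observed)
  B <- length(freqs)
  p_lit <- exceed / B
  p_add <- (exceed + 1) / (B + 1)
  p <- if (params$p_correction == "literal_fraction") p_lit else p_add
  data.frame(phenotype = phenotype, gene = gene, n_cases = N,
             observed_freq = observed, n_accepted_sets = B,
             n_exceeding = exceed, p_literal = p_lit, p_add_one = p_add,
             empirical_p = p, significant = p < sig_threshold,
             sig_threshold = sig_threshold, n_attempted_draws = n_attempts,
             stringsAsFactors = FALSE)
}

#' Empirical age-matched burden test for one phenotype
#'
#' Tests whether one cancer phenotype carries an excess of mosaic-PTV
#' carriers relative to the pool of all cancer cases. For a phenotype of
#' `N` cases, `n_resamples` random sets of `N` cases are drawn from the
#' full case pool (the target phenotype included, unless
#' `exclude_self`), keeping only age-matched sets (two-sided Wilcoxon
#' rank-sum p > `age_match_alpha` versus the target ages, since age alone
#' strongly drives mosaic frequency). The empirical p is the fraction of
#' accepted sets whose carrier frequency exceeds the target's (strictly,
#' by default); the add-one variant `(exceedances + 1) / (B + 1)` is also
#' reported.
#'
#' @param samples Sample metadata (cases are pooled; controls ignored).
#' @param carriers A [carrier_table()] covering all cases, or any data
#'   frame with `sample_id`, `is_carrier` and (for per-gene tests)
#'   `carrier_genes`.
#' @param phenotype Target phenotype label.
#' @param gene `"all"` for overall carrier frequency, or one candidate
#'   gene to restrict carrier status to mosaics in that gene.
#' @param params A [resampling_params()].
#' @param sig_threshold Per-test significance threshold; the default is
#'   the Bonferroni level for 20 phenotypes, 0.05/20 = 0.0025.
#' @return A one-row data frame of class `burden_result`.
#' @export
phenotype_burden <- function(samples, carriers, phenotype, gene = "all",
                             params = resampling_params(),
                             sig_threshold = bonferroni_threshold(0.05, 20)) {
  stopifnot(inherits(params, "resampling_params"))
  with_seed_or_not(params$seed,
                   phenotype_burden_impl(samples, carriers, phenotype, gene,
                                         params, sig_threshold))
}

phenotype_burden_impl <- function(samples, carriers, phenotype, gene,
                                  params, sig_threshold) {
  cases <- samples[samples$status == "case", , drop = FALSE]
  if (!all(cases$sample_id %in% carriers$sample_id))
    stop("carrier table must cover every case sample")
  is_target <- !is.na(cases$phenotype) & cases$phenotype == phenotype
  N <- sum(is_target)
  if (N < 1) stop("phenotype '", phenotype, "' has no cases")
  ci <- match(cases$sample_id, carriers$sample_id)
  flag <- if (identical(gene, "all")) carriers$is_carrier[ci]
          else per_gene_flags(carriers[ci, , drop = FALSE], gene)[, 1]
  observed <- mean(flag[is_target])
  pool_keep <- if (params$exclude_self) !is_target else rep(TRUE, nrow(cases))
  pool_ages <- cases$age[pool_keep]
  rs <- resample_freqs(pool_ages, cases$age[is_target], N,
                       matrix(flag[pool_keep], ncol = 1), params, phenotype)
  out <- burden_row(phenotype, gene, N, observed, rs$freqs[, 1], params,
                    rs$n_attempts, sig_threshold)
  class(out) <- c("burden_result", "data.frame")
  out
}

#' Burden scan over all phenotypes and candidate genes
#'
#' Runs the age-matched resampling burden test for every cancer phenotype
#' (overall carrier frequency) and for every phenotype-gene pair over the
#' four candidate genes. The significance threshold is recomputed from the
#' data as `alpha / n_phenotypes` (Bonferroni over the tested phenotypes).
#' Within a phenotype the same accepted resampled sets are reused for the
#' overall and per-gene frequencies, since age-match acceptance depends
#' only on ages.
#'
#' @param samples,carriers As for [phenotype_burden()].
#' @param params A [resampling_params()].
#' @param genes Candidate genes for the per-gene scan.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return A data frame of class `burden_scan`: one row per
#'   (phenotype, gene-or-all), with the Bonferroni threshold in
#'   `sig_threshold`.
#' @export
burden_scan <- function(samples, carriers, params = resampling_params(),
                        genes = CANDIDATE_GENES, alpha = 0.05) {
  stopifnot(inherits(params, "resampling_params"))
  with_seed_or_not(params$seed,
                   burden_scan_impl(samples, carriers, params, genes, alpha))
}

burden_scan_impl <- function(samples, carriers, params, genes, alpha) {
  cases <- samples[samples$status == "case", , drop = FALSE]
  phenos <- sort(unique(cases$phenotype[!is.na(cases$phenotype)]))
  if (length(phenos) < 2) stop("burden scan needs at least 2 phenotypes")
  if (!all(cases$sample_id %in% carriers$sample_id))
    stop("carrier table must cover every case sample")
  threshold <- bonferroni_threshold(alpha, length(phenos))
  ci <- match(cases$sample_id, carriers$sample_id)
  flags <- cbind(all = carriers$is_carrier[ci],
                 per_gene_flags(carriers[ci, , drop = FALSE], genes))
  rows <- vector("list", length(phenos))
  for (i in seq_along(phenos)) {
    is_target <- !is.na(cases$phenotype) & cases$phenotype == phenos[i]
    N <- sum(is_target)
    pool_keep <- if (params$exclude_self) !is_target
                 else rep(TRUE, nrow(cases))
    rs <- resample_freqs(cases$age[pool_keep], cases$age[is_target], N,
                         flags[pool_keep, , drop = FALSE], params, phenos[i])
    obs <- colMeans(flags[is_target, , drop = FALSE])
    rows[[i]] <- do.call(rbind, lapply(colnames(flags), function(g) {
      burden_row(phenos[i], g, N, obs[[g]], rs$freqs[, g == colnames(flags)],
                 params, rs$n_attempts, threshold)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("burden_scan", "data.frame")
  out
}

#' @export
print.burden_scan <- function(x, ...) {
  cat(sprintf("Age-matched resampling burden scan: %d phenotypes, B = %d\n",
              length(unique(x$phenotype)), x$n_accepted_sets[1]))
  cat(sprintf("  Bonferroni threshold: %.4g\n", x$sig_threshold[1]))
  sig <- x[x$significant, c("phenotype", "gene", "observed_freq",
                            "empirical_p")]
  if (nrow(sig) == 0) cat("  no significant burden\n")
  else {
    cat("  significant rows:\n")
    print.data.frame(sig, row.names = FALSE)
  }
  invisible(x)
}
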