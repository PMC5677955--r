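# Exact one-sided signed-rank tail P(W >= w_obs) under random sign flips,
# tie-aware: |d| are midranked, ranks are doubled to integers and the null
# distribution of the positive-rank sum is built by convolution over the
# 2^n equiprobable sign assignments. stats::wilcox.test offers no exact
# null in the presence of tied magnitudes, hence this small DP.
signed_rank_exact_p <- function(d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(NA_real_)
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks
  w2 <- sum(r2[d > 0])
  total <- sum(r2)
  # counts[k + 1] = number of sign assignments with doubled rank sum k
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  if (alternative == "greater") sum(probs[(w2 + 1):(total + 1)])
  else sum(probs[seq_len(w2 + 1)])
}

# one-sided normal-approximation signed-rank p with continuity and tie
# corrections (used above n = 25)
signed_rank_normal_p <- function(d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(NA_real_)
  z <- if (alternative == "greater") (w - mu - 0.5) / sqrt(sigma2)
       else (w - mu + 0.5) / sqrt(sigma2)
  if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
}

signed_rank_p <- function(d, alternative = "greater", exact_n_max = 25) {
  d <- d[d != 0]
  if (length(d) <= exact_n_max) signed_rank_exact_p(d, alternative)
  else signed_rank_normal_p(d, alternative)
}

#' Paired blood-vs-tumor allele-balance depletion test
#'
#' Tests whether mosaic variants detected in blood are depleted from the
#' paired tumor DNA of the same individuals: a one-sided paired Wilcoxon
#' signed-rank test of blood allele balance greater than tumor allele
#' balance. Pairs with zero tumor depth are dropped before testing, and
#' zero differences are dropped per the standard signed-rank convention.
#' The exact sign-flip null distribution (tie-aware) is used for up to 25
#' informative pairs; the normal approximation with continuity and tie
#' corrections is used beyond that.
#'
#' @param pairs Data frame with columns `sample_id`, `site_id`, `gene`,
#'   `blood_ref`, `blood_alt`, `tumor_ref`, `tumor_alt` (see
#'   [paired_balances()]).
#' @param per_gene Also test each gene separately (the pooled test is
#'   always reported).
#' @param alternative `"greater"` tests blood depletion in tumor (the
#'   default, directional claim); `"less"` is the mirror.
#' @return An object of class `depletion_test`: `statistic` (positive-rank
#'   sum), `p_value`, `n` (informative pairs), `n_dropped_zero_depth`,
#'   `n_dropped_ties`, `median_blood_ab`, `median_tumor_ab`,
#'   `not_testable`, and `by_gene` (a list of per-gene results) when
#'   requested.
#' @export
depletion_test <- function(pairs, per_gene = FALSE,
                           alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  need <- c("blood_ref", "blood_alt", "tumor_ref", "tumor_alt")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  res <- depletion_test_one(pairs, alternative)
  if (isTRUE(per_gene) && nrow(pairs) > 0) {
    res$by_gene <- lapply(split(pairs, pairs$gene), depletion_test_one,
                          alternative = alternative)
  }
  res
}

depletion_test_one <- function(pairs, alternative) {
  blood_depth <- pairs$blood_ref + pairs$blood_alt
  tumor_depth <- pairs$tumor_ref + pairs$tumor_alt
  keep <- blood_depth >= 1 & tumor_depth >= 1
  n_zero <- sum(!keep)
  pr <- pairs[keep, , drop = FALSE]
  blood_ab <- pr$blood_alt / (pr$blood_ref + pr$blood_alt)
  tumor_ab <- pr$tumor_alt / (pr$tumor_ref + pr$tumor_alt)
  d <- blood_ab - tumor_ab
  n_ties <- sum(d == 0)
  d_use <- d[d != 0]
  res <- list(statistic = NA_real_, p_value = NA_real_,
              n = length(d_use), n_dropped_zero_depth = n_zero,
              n_dropped_ties = n_ties,
              median_blood_ab = if (length(blood_ab)) median(blood_ab)
                                else NA_real_,
              median_tumor_ab = if (length(tumor_ab)) median(tumor_ab)
                                else NA_real_,
              alternative = alternative,
              not_testable = length(d_use) == 0,
              reason = if (length(d_use) == 0)
                "no informative pairs (all differences zero or zero depth)"
                else NA_character_)
  if (!res$not_testable) {
    r <- rank(abs(d_use))
    res$statistic <- sum(r[d_use > 0])
    res$p_value <- signed_rank_p(d_use, alternative)
  }
  class(res) <- "depletion_test"
  res
}

#' @export
print.depletion_test <- function(x, ...) {
  cat("Paired blood/tumor allele-balance depletion test\n")
  if (x$not_testable) {
    cat("  not testable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d pairs; median AB blood %.3f vs tumor %.3f\n",
              x$n, x$median_blood_ab, x$median_tumor_ab))
  cat(sprintf("  signed-rank W = %.1f, one-sided p = %.3g (%s)\n",
              x$statistic, x$p_value,
              if (x$alternative == "greater") "blood > tumor"
              else "blood < tumor"))
  if (!is.null(x$by_gene))
    for (g in names(x$by_gene))
      cat(sprintf("    %s: n = %d, p = %.3g\n", g, x$by_gene[[g]]$n,
                  x$by_gene[[g]]$p_value))
  invisible(x)
}

#' Blood-vs-tumor coverage comparison at mosaic sites
#'
#' Paired comparison of sequencing depth in blood versus tumor at the
#' sites where blood mosaics were called, to check that their absence from
#' tumors is not a sensitivity artefact (tumors should be covered at least
#' as well as blood).
#'
#' @param pairs As for [depletion_test()]; needs at least 2 pairs.
#' @return A list of class `coverage_comparison`: per-side mean depths,
#'   mean difference, `direction` (`"tumor >= blood"`, `"blood > tumor"`
#'   or `"equal"`), and a two-sided signed-rank `p_value` (`NA` and
#'   not-testable when all depths are tied).
#' @export
coverage_comparison <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  blood_depth <- pairs$blood_ref + pairs$blood_alt
  tumor_depth <- pairs$tumor_ref + pairs$tumor_alt
  d <- tumor_depth - blood_depth
  mean_diff <- mean(d)
  direction <- if (all(d == 0)) "equal"
               else if (mean_diff >= 0) "tumor >= blood" else "blood > tumor"
  if (all(d == 0)) {
    p <- NA_real_
    nt <- TRUE
  } else {
    p_up <- signed_rank_p(d, "greater")
    p_dn <- signed_rank_p(d, "less")
    p <- min(1, 2 * min(p_up, p_dn))
    nt <- FALSE
  }
  structure(list(n = nrow(pairs),
                 mean_blood_depth = mean(blood_depth),
                 mean_tumor_depth = mean(tumor_depth),
                 mean_difference = mean_diff, direction = direction,
                 p_value = p, not_testable = nt),
            class = "coverage_comparison")
}

#' @export
print.coverage_comparison <- function(x, ...) {
  cat("Blood/tumor coverage comparison at mosaic sites\n")
  cat(sprintf("  mean depth: blood %.1f, tumor %.1f (%s)\n",
              x$mean_blood_depth, x$mean_tumor_depth, x$direction))
  if (x$not_testable) cat("  all depths tied; not testable\n")
  else cat(sprintf("  two-sided signed-rank p = %.3g\n", x$p_value))
  invisible(x)
}

#' Build paired blood/tumor balances from site observations
#'
#' Extracts the pairs table consumed by [depletion_test()] from site
#' observations carrying tumor read counts, optionally restricted to
#' mosaic-flagged calls.
#'
#' @param sites Site observations with `tumor_ref_reads` /
#'   `tumor_alt_reads`.
#' @param calls Optional `mosaic_calls`; when given, only sites whose call
#'   is mosaic are kept.
#' @return A pairs data frame (`sample_id`, `site_id`, `gene`,
#'   `blood_ref`, `blood_alt`, `tumor_ref`, `tumor_alt`).
#' @export
paired_balances <- function(sites, calls = NULL) {
  keep <- !is.na(sites$tumor_alt_reads) & !is.na(sites$tumor_ref_reads)
  if (!is.null(calls)) {
    mos <- calls[calls$is_mosaic, c("sample_id", "site_id")]
    keep <- keep & paste(sites$sample_id, sites$site_id) %in%
      paste(mos$sample_id, mos$site_id)
  }
  pr <- sites[keep, c("sample_id", "site_id", "gene", "ref_reads",
                      "alt_reads", "tumor_ref_reads", "tumor_alt_reads")]
  names(pr) <- c("sample_id", "site_id", "gene", "blood_ref", "blood_alt",
                 "tumor_ref", "tumor_alt")
  rownames(pr) <- NULL
  pr
}
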