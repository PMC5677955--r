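#' Binomial allele-balance test
#'
#' Lower-tail exact binomial test of a genotype's allele balance against
#' the germline heterozygous expectation: returns `P(X <= alt_reads)` for
#' `X ~ Binomial(depth, null_af)`. A small p indicates significantly fewer
#' alternate reads than a heterozygote would show, the signature of a
#' mosaic (clonal) variant present in only a fraction of blood cells.
#'
#' @param alt_reads Alternate read count(s), `0 <= alt_reads <= depth`.
#' @param depth Total informative reads (ref + alt), at least 1.
#' @param null_af Expected heterozygous allele fraction (default 0.5).
#' @param two_sided If `TRUE`, return the two-sided exact-binomial p
#'   instead of the default lower tail.
#' @return Probability vector, one per genotype.
#' @examples
#' binomial_ab_test(2, 30)   # ~4.34e-7: clearly mosaic at 30x
#' binomial_ab_test(15, 30)  # ~0.57: consistent with germline het
#' @export
binomial_ab_test <- function(alt_reads, depth, null_af = 0.5,
                             two_sided = FALSE) {
  if (any(depth < 1)) stop("depth must be at least 1")
  if (any(alt_reads < 0)) stop("alt_reads must be non-negative")
  if (any(alt_reads > depth)) stop("alt_reads must not exceed depth")
  if (null_af <= 0 || null_af >= 1) stop("null_af must be in (0, 1)")
  lower <- pbinom(alt_reads, depth, null_af)
  if (!two_sided) return(lower)
  # two-sided exact p: sum of outcome probabilities not exceeding the
  # observed one (the classical minlike convention)
  mapply(function(a, d) {
    p0 <- dbinom(a, d, null_af)
    sum(dbinom(0:d, d, null_af)[dbinom(0:d, d, null_af) <= p0 * (1 + 1e-7)])
  }, alt_reads, depth)
}

#' Call mosaic status for site observations
#'
#' Applies the binomial allele-balance test to every non-reference
#' genotype and flags as mosaic those with `p < alpha` *and* depth strictly
#' greater than `depth_min` (default: p < 0.001 at more than 20x coverage).
#' Depth is defined as `ref_reads + alt_reads` from `AD` — the informative
#' reads — not the VCF `DP` field. The p-value is populated even when the
#' depth gate fails.
#'
#' @param sites Site-observation data frame (`sample_id`, `site_id`,
#'   `gene`, `ref_reads`, `alt_reads`, ...).
#' @param params A [caller_params()].
#' @return A data frame of class `mosaic_calls`: `sample_id`, `site_id`,
#'   `gene`, `depth`, `alt_reads`, `allele_balance`, `p_value`,
#'   `is_mosaic`.
#' @export
call_mosaic <- function(sites, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"), is.data.frame(sites))
  need <- c("sample_id", "site_id", "gene", "ref_reads", "alt_reads")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  depth <- sites$ref_reads + sites$alt_reads
  if (nrow(sites) == 0) {
    calls <- data.frame(sample_id = character(), site_id = character(),
                        gene = character(), depth = integer(),
                        alt_reads = integer(), allele_balance = numeric(),
                        p_value = numeric(), is_mosaic = logical(),
                        stringsAsFactors = FALSE)
    class(calls) <- c("mosaic_calls", "data.frame")
    return(calls)
  }
  if (any(sites$alt_reads < 1))
    stop("site observations must have alt_reads >= 1")
  p <- binomial_ab_test(sites$alt_reads, depth, params$null_af,
                        two_sided = params$two_sided)
  calls <- data.frame(
    sample_id = sites$sample_id, site_id = sites$site_id,
    gene = sites$gene, depth = as.integer(depth),
    alt_reads = as.integer(sites$alt_reads),
    allele_balance = sites$alt_reads / depth,
    p_value = p,
    is_mosaic = p < params$alpha & depth > params$depth_min,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("mosaic_calls", "data.frame")
  calls
}

#' Per-sample mosaic-PTV carrier status
#'
#' A sample is a carrier when it has at least one mosaic-flagged PTV call.
#' Calls should already be restricted to protein-truncating consequences
#' (apply [filter_ptv()] before [call_mosaic()]). Every metadata sample
#' appears in the result, non-carriers included.
#'
#' @param samples Sample metadata data frame.
#' @param calls A `mosaic_calls` data frame.
#' @return A data frame of class `carrier_table`: `sample_id`,
#'   `is_carrier`, `carrier_genes` (comma-separated, `""` for
#'   non-carriers), `n_mosaic_ptv`.
#' @export
carrier_table <- function(samples, calls) {
  stopifnot(is.data.frame(samples), is.data.frame(calls))
  unknown <- setdiff(calls$sample_id, samples$sample_id)
  if (length(unknown) > 0)
    stop("call(s) for sample(s) absent from metadata: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  mos <- calls[calls$is_mosaic, , drop = FALSE]
  genes <- vapply(split(mos$gene, mos$sample_id),
                  function(g) paste(sort(unique(g)), collapse = ","), "")
  n_calls <- vapply(split(mos$gene, mos$sample_id), length, 0L)
  out <- data.frame(sample_id = samples$sample_id,
                    is_carrier = samples$sample_id %in% mos$sample_id,
                    carrier_genes = "",
                    n_mosaic_ptv = 0L, stringsAsFactors = FALSE)
  i <- match(names(genes), out$sample_id)
  out$carrier_genes[i] <- unname(genes)
  out$n_mosaic_ptv[i] <- unname(n_calls)
  rownames(out) <- NULL
  class(out) <- c("carrier_table", "data.frame")
  out
}

#' Coverage-bias QC between cohorts
#'
#' Among samples carrying at least one PTV, tests whether case/control
#' status is predicted by sequencing coverage (binomial GLM of the cohort
#' label on per-carrier mean depth, optionally age-adjusted). A
#' non-significant depth term indicates that PTVs are adequately covered in
#' both cohorts so mosaic events have equal detection chances — the
#' technical pre-requisite of the case-control comparison.
#'
#' @param samples Sample metadata.
#' @param ptv_calls Calls at PTV sites (mosaic or not) defining the
#'   "carries at least one PTV" subset.
#' @param adjust_age Include age in the model.
#' @return A `mosaic_assoc` result for the coverage term, or a
#'   not-testable result when either cohort has fewer than two PTV
#'   carriers.
#' @export
coverage_bias_check <- function(samples, ptv_calls, adjust_age = FALSE) {
  ids <- unique(ptv_calls$sample_id)
  d <- samples[samples$sample_id %in% ids, , drop = FALSE]
  n_case <- sum(d$status == "case")
  n_ctrl <- sum(d$status == "control")
  if (n_case < 2 || n_ctrl < 2) {
    return(not_testable_result(
      term = "coverage",
      reason = sprintf("need >= 2 PTV carriers per cohort (have %d cases, %d controls)",
                       n_case, n_ctrl),
      n_cases = n_case, n_controls = n_ctrl))
  }
  fml <- if (adjust_age) I(status == "case") ~ mean_coverage + age
         else I(status == "case") ~ mean_coverage
  fit <- glm(fml, family = binomial(), data = d,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  assoc_from_fit(fit, term = "mean_coverage", label = "coverage",
                 n_cases = n_case, n_controls = n_ctrl,
                 covariates = if (adjust_age) "age" else character(0))
}
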