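#' Cohort simulation configuration
#'
#' Parameters of the synthetic case-control cohort. Defaults reproduce the
#' design of the discovery study: 7979 cancer cases at ~33x mean target
#' coverage versus 6177 population controls at ~29x, controls on average
#' about ten years younger, and a rare (<1%) age-dependent mosaic-PTV
#' carrier state with clonal allele fractions well below the heterozygous
#' expectation of 0.5.
#'
#' Carrier status is drawn per sample from a logit-linear model
#' `logit P(carrier) = logit(carrier_base_rate) +
#' carrier_age_slope * (age - control_age_mean) +
#' carrier_case_log_or * I(case)`, so `carrier_base_rate` is the carrier
#' probability of a control at the control-cohort mean age and
#' `exp(carrier_case_log_or)` is the conditional (age-adjusted) carrier odds
#' ratio of cases versus controls.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param phenotype_counts Named integer vector of cases per cancer
#'   phenotype; must sum to `n_cases`. Default: 20 solid-tumor phenotypes.
#' @param case_age_mean,case_age_sd,control_age_mean,control_age_sd Age
#'   distributions in years (normal, truncated at 18).
#' @param case_depth_mean,control_depth_mean Mean sequencing depth over the
#'   candidate-gene target, in reads.
#' @param depth_cv Coefficient of variation of the per-sample mean depth
#'   around its cohort mean (gamma-distributed sample means).
#' @param depth_dispersion `NULL` for Poisson per-site depth around the
#'   per-sample mean, or a negative-binomial `size` for overdispersed depth.
#' @param carrier_base_rate Carrier probability for a control at
#'   `control_age_mean` years.
#' @param carrier_age_slope Per-year log-odds increment of carrier status.
#' @param carrier_case_log_or Log odds ratio of carrier status given case.
#' @param gene_weights Named probabilities (summing to 1 over PPM1D, TET2,
#'   ASXL1, DNMT3A) that a carrier's mosaic PTV falls in each gene.
#' @param mosaic_af_range Interval strictly inside (0, 0.5) from which the
#'   true clonal allele fraction of a mosaic PTV is drawn uniformly.
#' @param tumor_depletion_af Residual allele fraction of a blood mosaic in
#'   the paired tumor sample (blood contamination floor); must be below
#'   `mosaic_af_range[1]`.
#' @param tumor_depth_factor Multiplier on the per-sample mean depth for
#'   paired tumor reads (tumors are covered at least as well as blood).
#' @param germline_site_rate Poisson mean number of background germline
#'   heterozygous sites per sample per candidate gene (true AF 0.5).
#' @param germline_consequence_probs Named probabilities over the
#'   consequence vocabulary for germline sites (mostly non-PTV, to exercise
#'   the consequence filter).
#' @param exon_concentration Probability that a mosaic PTV falls in its
#'   gene's characteristic exon (last exon for PPM1D/ASXL1/TET2); the
#'   remainder is uniform over the other exons. DNMT3A has no positional
#'   pattern and is uniform over all exons.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_cases = 7979L,
                          n_controls = 6177L,
                          phenotype_counts = NULL,
                          case_age_mean = 60, case_age_sd = 12,
                          control_age_mean = 50, control_age_sd = 12,
                          case_depth_mean = 33, control_depth_mean = 29,
                          depth_cv = 0.10,
                          depth_dispersion = NULL,
                          carrier_base_rate = 0.005,
                          carrier_age_slope = 0.05,
                          carrier_case_log_or = log(1.26),
                          gene_weights = c(PPM1D = 18, TET2 = 50,
                                           ASXL1 = 40, DNMT3A = 60) / 168,
                          mosaic_af_range = c(0.10, 0.20),
                          tumor_depletion_af = 0.02,
                          tumor_depth_factor = 1.2,
                          germline_site_rate = 1,
                          germline_consequence_probs = c(
                            stop_gained = 0.04, splice_essential = 0.02,
                            frameshift = 0.04, missense = 0.60, other = 0.30),
                          exon_concentration = 0.9,
                          seed = 1L) {
  if (is.null(phenotype_counts)) {
    phenotype_counts <- default_phenotype_counts(n_cases)
  }
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    phenotype_counts = phenotype_counts,
    case_age_mean = case_age_mean, case_age_sd = case_age_sd,
    control_age_mean = control_age_mean, control_age_sd = control_age_sd,
    case_depth_mean = case_depth_mean, control_depth_mean = control_depth_mean,
    depth_cv = depth_cv, depth_dispersion = depth_dispersion,
    carrier_base_rate = carrier_base_rate,
    carrier_age_slope = carrier_age_slope,
    carrier_case_log_or = carrier_case_log_or,
    gene_weights = gene_weights,
    mosaic_af_range = mosaic_af_range,
    tumor_depletion_af = tumor_depletion_af,
    tumor_depth_factor = tumor_depth_factor,
    germline_site_rate = germline_site_rate,
    germline_consequence_probs = germline_consequence_probs,
    exon_concentration = exon_concentration,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

# 20 solid-tumor phenotypes, sizes roughly proportional to a large
# multi-cancer exome cohort; the last phenotype absorbs the remainder.
default_phenotype_counts <- function(n_cases) {
  base <- c(BRCA = 0.135, OV = 0.055, LUAD = 0.065, LUSC = 0.055,
            GBM = 0.070, SKCM = 0.055, COAD = 0.055, HNSC = 0.060,
            KIRC = 0.065, LGG = 0.060, THCA = 0.055, PRAD = 0.050,
            STAD = 0.045, BLCA = 0.045, LIHC = 0.040, CESC = 0.035,
            KIRP = 0.035, SARC = 0.030, ESCA = 0.025, UCEC = 0.065)
  counts <- floor(base / sum(base) * n_cases)
  counts[length(counts)] <- counts[length(counts)] + n_cases - sum(counts)
  as.integer(counts) -> out
  names(out) <- names(base)
  out
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_cases) || !is_count(cfg$n_controls))
    stop_config("n_cases and n_controls must be non-negative integers")
  if (sum(cfg$phenotype_counts) != cfg$n_cases)
    stop_config("sum of phenotype_counts (", sum(cfg$phenotype_counts),
                ") must equal n_cases (", cfg$n_cases, ")")
  if (is.null(names(cfg$phenotype_counts)) ||
      anyDuplicated(names(cfg$phenotype_counts)))
    stop_config("phenotype_counts must have unique names")
  gw <- cfg$gene_weights
  if (!setequal(names(gw), CANDIDATE_GENES))
    stop_config("gene_weights must be named over ",
                paste(CANDIDATE_GENES, collapse = ", "))
  if (any(gw < 0) || abs(sum(gw) - 1) > 1e-8)
    stop_config("gene_weights must be non-negative and sum to 1")
  afr <- cfg$mosaic_af_range
  if (length(afr) != 2 || afr[1] >= afr[2] || afr[1] <= 0 || afr[2] >= 0.5)
    stop_config("mosaic_af_range must be an interval strictly inside (0, 0.5)")
  if (cfg$tumor_depletion_af < 0 || cfg$tumor_depletion_af >= afr[1])
    stop_config("tumor_depletion_af must lie in [0, mosaic_af_range[1])")
  if (cfg$carrier_base_rate < 0 || cfg$carrier_base_rate >= 1)
    stop_config("carrier_base_rate must be a probability in [0, 1)")
  gcp <- cfg$germline_consequence_probs
  if (!all(names(gcp) %in% CONSEQUENCE_LEVELS) || abs(sum(gcp) - 1) > 1e-8)
    stop_config("germline_consequence_probs must be probabilities over the ",
                "consequence vocabulary summing to 1")
  if (cfg$exon_concentration < 0 || cfg$exon_concentration > 1)
    stop_config("exon_concentration must be in [0, 1]")
  if (cfg$case_age_sd < 0 || cfg$control_age_sd < 0)
    stop_config("age standard deviations must be non-negative")
  if (cfg$case_depth_mean <= 0 || cfg$control_depth_mean <= 0)
    stop_config("depth means must be positive")
  if (cfg$tumor_depth_factor < 1)
    stop_config("tumor_depth_factor must be >= 1 (tumors are covered at ",
                "least as well as blood)")
  cfg
}

#' Mosaic caller parameters
#'
#' @param alpha Significance threshold of the lower-tail binomial
#'   allele-balance test; genotypes with p below it are mosaic candidates.
#' @param depth_min Coverage gate: only genotypes with more than `depth_min`
#'   informative reads (strictly greater) can be flagged mosaic.
#' @param null_af Expected allele fraction of a germline heterozygote.
#' @param two_sided Use a two-sided test instead of the default lower tail.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(alpha = 0.001, depth_min = 20L, null_af = 0.5,
                          two_sided = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (!is_count(depth_min)) stop_config("depth_min must be a count >= 0")
  if (null_af <= 0 || null_af >= 1) stop_config("null_af must be in (0, 1)")
  structure(list(alpha = alpha, depth_min = as.integer(depth_min),
                 null_af = null_af, two_sided = isTRUE(two_sided)),
            class = "caller_params")
}

#' Resampling burden-test parameters
#'
#' @param n_resamples Number of accepted age-matched resampled sets (B).
#' @param age_match_alpha Two-sided Wilcoxon rank-sum p-value above which a
#'   drawn set is accepted as age-matched to the target phenotype.
#' @param max_draw_factor Maximum attempted draws per accepted set before
#'   declaring the phenotype's age distribution unmatched.
#' @param tie_rule `"strict_greater"` counts resampled sets whose carrier
#'   frequency strictly exceeds the observed one; `"greater_or_equal"`
#'   counts ties as exceedances.
#' @param p_correction Which empirical p is reported as `empirical_p`:
#'   `"literal_fraction"` (exceedances / B) or `"add_one"`
#'   ((exceedances + 1) / (B + 1)). Both are always computed.
#' @param exclude_self Drop the target phenotype's own cases from the
#'   resampling pool (sensitivity option; the default pools all cases).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A list of class `resampling_params`.
#' @export
resampling_params <- function(n_resamples = 10000L,
                              age_match_alpha = 0.05,
                              max_draw_factor = 50L,
                              tie_rule = c("strict_greater",
                                           "greater_or_equal"),
                              p_correction = c("literal_fraction", "add_one"),
                              exclude_self = FALSE,
                              seed = NULL) {
  if (!is_count(n_resamples) || n_resamples < 1)
    stop_config("n_resamples must be a positive integer")
  if (age_match_alpha <= 0 || age_match_alpha >= 1)
    stop_config("age_match_alpha must be in (0, 1)")
  if (!is_count(max_draw_factor) || max_draw_factor < 1)
    stop_config("max_draw_factor must be a positive integer")
  structure(list(n_resamples = as.integer(n_resamples),
                 age_match_alpha = age_match_alpha,
                 max_draw_factor = as.integer(max_draw_factor),
                 tie_rule = match.arg(tie_rule),
                 p_correction = match.arg(p_correction),
                 exclude_self = isTRUE(exclude_self),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "resampling_params")
}
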