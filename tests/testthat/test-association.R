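mk_cohort <- function(car_case, n_case, car_ctrl, n_ctrl, age = NULL) {
  n <- n_case + n_ctrl
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    phenotype = c(rep("OV", n_case), rep(NA_character_, n_ctrl)),
    age = if (is.null(age)) 55 else age,
    mean_coverage = 31, stringsAsFactors = FALSE)
  flags <- c(rep(c(TRUE, FALSE), c(car_case, n_case - car_case)),
             rep(c(TRUE, FALSE), c(car_ctrl, n_ctrl - car_ctrl)))
  carriers <- data.frame(sample_id = samples$sample_id, is_carrier = flags,
                         carrier_genes = ifelse(flags, "DNMT3A", ""),
                         n_mosaic_ptv = as.integer(flags),
                         stringsAsFactors = FALSE)
  list(samples = samples, carriers = carriers)
}

test_that("without covariates the fitted carrier OR equals the closed-form 2x2 OR", {
  d <- mk_cohort(10, 100, 5, 100)
  fit <- fit_carrier_model(d$samples, d$carriers, covariates = character(0))
  expect_equal(fit$odds_ratio, (10 * 95) / (90 * 5), tolerance = 1e-9)
  expect_true(fit$or_ci_low <= fit$odds_ratio &&
                fit$odds_ratio <= fit$or_ci_high)
  expect_identical(fit$n_cases, 100L + 0L)
})

test_that("the fit is invariant to sample relabelling and row order", {
  d <- mk_cohort(12, 150, 6, 120, age = stats::rnorm(270, 55, 8))
  a <- fit_carrier_model(d$samples, d$carriers, covariates = "age")
  perm <- withr::with_seed(1, sample.int(nrow(d$samples)))
  s2 <- d$samples[perm, ]
  c2 <- d$carriers[rev(perm), ]
  s2$sample_id <- paste0("X", s2$sample_id)
  c2$sample_id <- paste0("X", c2$sample_id)
  b <- fit_carrier_model(s2, c2, covariates = "age")
  expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  expect_equal(c(a$or_ci_low, a$or_ci_high), c(b$or_ci_low, b$or_ci_high),
               tolerance = 1e-10)
})

test_that("phenotype exclusion drops the right samples before fitting", {
  d <- mk_cohort(10, 100, 5, 100)
  d$samples$phenotype[41:90] <- "BRCA"  # keeps the 10 case carriers
  fit <- fit_carrier_model(d$samples, d$carriers,
                           covariates = character(0),
                           excluded_phenotypes = "BRCA")
  expect_identical(fit$n_cases, 50L + 0L)
  expect_identical(fit$excluded_phenotypes, "BRCA")
})

test_that("age adjustment removes the confounding of a younger control cohort", {
  # carriers driven purely by age; cases older; no true case effect
  coh <- generate_cohort(cohort_config(
    n_cases = 4000, n_controls = 4000,
    phenotype_counts = c(A = 2000, B = 2000),
    carrier_base_rate = 0.02, carrier_age_slope = 0.08,
    carrier_case_log_or = 0, case_depth_mean = 31,
    control_depth_mean = 31, seed = 77))
  carriers <- data.frame(sample_id = coh$truth$sample_id,
                         is_carrier = coh$truth$is_carrier_true,
                         carrier_genes = "", n_mosaic_ptv = 0L,
                         stringsAsFactors = FALSE)
  unadj <- fit_carrier_model(coh$samples, carriers,
                             covariates = character(0))
  adj <- fit_carrier_model(coh$samples, carriers, covariates = "age")
  expect_gt(unadj$odds_ratio, adj$odds_ratio)  # upward bias unadjusted
  expect_true(adj$or_ci_low <= 1 && 1 <= adj$or_ci_high)
})

test_that("degenerate designs are reported, not crashed on", {
  # no carriers among controls -> not testable
  d <- mk_cohort(5, 100, 0, 100)
  fit <- fit_carrier_model(d$samples, d$carriers)
  expect_true(fit$not_testable)

  # constant covariate -> not testable
  r <- carrier_covariate_test(rep(c(TRUE, FALSE), 50), rep(1, 100),
                              stats::rnorm(100, 55, 8))
  expect_true(r$not_testable)

  # covariate identical to carrier status -> separation error
  flags <- rep(c(TRUE, FALSE), 50)
  suppressWarnings(
    expect_error(carrier_covariate_test(flags, as.numeric(flags),
                                        stats::rnorm(100, 55, 8)),
                 "separation"))
})

test_that("a null treatment covariate rejects at the nominal 5% rate", {
  rej <- 0L
  for (s in 1:200) {
    withr::with_seed(3000 + s, {
      carrier <- stats::runif(500) < 0.1
      trt <- stats::runif(500) < 0.4
      age <- stats::rnorm(500, 58, 9)
      r <- carrier_covariate_test(carrier, trt, age, "treatment")
      if (!r$not_testable && r$p_value < 0.05) rej <- rej + 1L
    })
  }
  expect_gt(rej, 2L)
  expect_lt(rej, 25L)
})

test_that("population contingency reproduces the Swedish-register rates and ORs", {
  # all mosaic carriers (PTV + DNMT3A missense): ~17% vs ~10%
  r <- population_contingency(26, 153, 1104, 10870)
  expect_equal(r$event_rate_carriers, 100 * 26 / 153, tolerance = 1e-12)
  expect_equal(round(r$event_rate_carriers), 17)
  expect_equal(round(r$event_rate_noncarriers), 10)
  expect_equal(r$crude_or, (26 * 9766) / (127 * 1104), tolerance = 1e-12)
  expect_false(r$haldane_corrected)

  # PTV-only cohort: 11 of 83 carriers with prior cancer
  r2 <- population_contingency(11, 83, 1105, 10867)
  expect_equal(r2$event_rate_carriers, 100 * 11 / 83, tolerance = 1e-12)
  expect_equal(r2$crude_or, (11 * 9762) / (72 * 1105), tolerance = 1e-12)
  expect_equal(r2$crude_or, 1.350, tolerance = 1e-3)

  # zero-event edge: Haldane-Anscombe correction flagged
  r0 <- population_contingency(0, 10, 0, 10)
  expect_identical(c(r0$event_rate_carriers, r0$event_rate_noncarriers),
                   c(0, 0))
  expect_true(r0$haldane_corrected)
  expect_equal(r0$crude_or, 1)

  expect_error(population_contingency(5, 4, 0, 10), "exceed")

  # age-adjusted p attaches when per-sample data are supplied
  withr::with_seed(8, {
    carrier <- stats::runif(2000) < 0.05
    age <- stats::rnorm(2000, 55, 10)
    event <- stats::runif(2000) < stats::plogis(-2.5 + 0.03 * (age - 55))
  })
  r3 <- population_contingency(sum(carrier & event), sum(carrier),
                               sum(!carrier & event), sum(!carrier),
                               carrier, event, age)
  expect_true(is.finite(r3$age_adjusted_p))
})

test_that("a pure-noise covariate barely moves the carrier estimate at large n", {
  coh <- generate_cohort(cohort_config(
    n_cases = 5000, n_controls = 5000,
    phenotype_counts = c(A = 5000), carrier_base_rate = 0.05,
    carrier_age_slope = 0, carrier_case_log_or = log(1.5),
    case_depth_mean = 31, control_depth_mean = 31, seed = 99))
  carriers <- data.frame(sample_id = coh$truth$sample_id,
                         is_carrier = coh$truth$is_carrier_true,
                         carrier_genes = "", n_mosaic_ptv = 0L,
                         stringsAsFactors = FALSE)
  plain <- fit_carrier_model(coh$samples, carriers,
                             covariates = character(0))
  # mean_coverage is independent noise with respect to carrier and status
  with_cov <- fit_carrier_model(coh$samples, carriers,
                                covariates = "coverage")
  expect_lt(abs(log(with_cov$odds_ratio) - log(plain$odds_ratio)), 0.02)
})
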