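# shared constructor for GLM-backed association results
assoc_from_fit <- function(fit, term, label = term, n_cases, n_controls,
                           covariates = character(0),
                           excluded_phenotypes = character(0),
                           conf_level = 0.95, ci_method = "wald") {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm))
    stop("term '", term, "' missing from the fitted model (degenerate design?)")
  se <- sm[term, "Std. Error"]
  if (!is.finite(se) || se > 20)
    stop("complete or quasi-complete separation detected for term '", label,
         "'; consider an exact or penalized (Firth) logistic regression")
  est <- sm[term, "Estimate"]
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "profile") {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("profile CIs require the MASS package")
    ci <- suppressMessages(stats::confint(fit, parm = term,
                                          level = conf_level))
    lo <- exp(ci[[1]]); hi <- exp(ci[[2]])
  } else {
    lo <- exp(est - z * se); hi <- exp(est + z * se)
  }
  res <- list(term = label, odds_ratio = exp(est),
              or_ci_low = lo, or_ci_high = hi,
              p_value = sm[term, "Pr(>|z|)"],
              n_cases = n_cases, n_controls = n_controls,
              covariates = covariates,
              excluded_phenotypes = excluded_phenotypes,
              conf_level = conf_level, ci_method = ci_method,
              not_testable = FALSE, fit = fit)
  class(res) <- "mosaic_assoc"
  res
}

not_testable_result <- function(term, reason, n_cases = NA_integer_,
                                n_controls = NA_integer_) {
  res <- list(term = term, odds_ratio = NA_real_, or_ci_low = NA_real_,
              or_ci_high = NA_real_, p_value = NA_real_,
              n_cases = n_cases, n_controls = n_controls,
              covariates = character(0),
              excluded_phenotypes = character(0),
              not_testable = TRUE, reason = reason)
  class(res) <- "mosaic_assoc"
  res
}

#' Case-control association of mosaic-carrier status with cancer
#'
#' Logistic regression of case status on mosaic-PTV carrier status, with
#' optional adjustment for age and mean sequencing coverage — the two
#' nuisance variables that differ between cohorts (controls are younger and
#' slightly shallower-covered, and both age and depth raise the chance of
#' observing a mosaic variant). The reported odds ratio is
#' `exp(carrier coefficient)` with a Wald 95% CI on the log-odds scale
#' (profile-likelihood optional). Samples whose phenotype is listed in
#' `excluded_phenotypes` are dropped before fitting (e.g. rerunning without
#' breast and ovarian cancers).
#'
#' @param samples Sample metadata (`status`, `phenotype`, `age`,
#'   `mean_coverage`).
#' @param carriers A [carrier_table()].
#' @param covariates Subset of `c("age", "coverage")`.
#' @param excluded_phenotypes Phenotype labels to drop.
#' @param conf_level Confidence level of the OR interval.
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @return A `mosaic_assoc` result for the carrier term; a not-testable
#'   result when either cohort has no carriers after exclusions.
#' @export
fit_carrier_model <- function(samples, carriers,
                              covariates = c("age", "coverage"),
                              excluded_phenotypes = character(0),
                              conf_level = 0.95,
                              ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  covariates <- unique(covariates)
  if (length(setdiff(covariates, c("age", "coverage"))) > 0)
    stop("covariates must be a subset of {age, coverage}")
  d <- merge(samples, carriers[, c("sample_id", "is_carrier")],
             by = "sample_id")
  if (length(excluded_phenotypes) > 0)
    d <- d[!(d$phenotype %in% excluded_phenotypes), , drop = FALSE]
  cov_cols <- c(age = "age", coverage = "mean_coverage")[covariates]
  if (anyNA(d[, cov_cols, drop = FALSE]))
    stop("missing covariate value(s) for: ",
         paste(names(which(colSums(is.na(d[, cov_cols, drop = FALSE])) > 0)),
               collapse = ", "))
  n_cases <- sum(d$status == "case")
  n_controls <- sum(d$status == "control")
  car_case <- sum(d$is_carrier & d$status == "case")
  car_ctrl <- sum(d$is_carrier & d$status == "control")
  if (car_case < 1 || car_ctrl < 1) {
    return(not_testable_result(
      "carrier",
      sprintf("need >= 1 carrier per cohort (have %d in cases, %d in controls)",
              car_case, car_ctrl),
      n_cases, n_controls))
  }
  rhs <- paste(c("is_carrier", unname(cov_cols)), collapse = " + ")
  fml <- stats::as.formula(paste("I(status == \"case\") ~", rhs))
  fit <- glm(fml, family = binomial(), data = d,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  res <- assoc_from_fit(fit, term = "is_carrierTRUE", label = "carrier",
                        n_cases = n_cases, n_controls = n_controls,
                        covariates = covariates,
                        excluded_phenotypes = excluded_phenotypes,
                        conf_level = conf_level, ci_method = ci_method)
  res
}

#' Association of a covariate with carrier status
#'
#' Age-adjusted logistic regression of carrier status on an arbitrary
#' per-sample covariate (e.g. a treatment-history indicator): the check
#' used to establish that clinical variables are not confounded with
#' mosaic-PTV carriage.
#'
#' @param carrier Logical vector of carrier flags.
#' @param covariate Numeric or two-level covariate, same length.
#' @param age Numeric ages, same length; used as the adjustment term.
#' @param covariate_name Label for reporting.
#' @return A `mosaic_assoc` result for the covariate term; not-testable
#'   when the covariate is constant.
#' @export
carrier_covariate_test <- function(carrier, covariate, age,
                                   covariate_name = "covariate") {
  stopifnot(length(carrier) == length(covariate),
            length(carrier) == length(age))
  if (length(unique(covariate)) < 2)
    return(not_testable_result(covariate_name,
                               "covariate is constant across samples"))
  d <- data.frame(carrier = as.logical(carrier), x = covariate, age = age)
  fit <- glm(carrier ~ x + age, family = binomial(), data = d,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  term <- grep("^x", rownames(summary(fit)$coefficients), value = TRUE)[1]
  assoc_from_fit(fit, term = term, label = covariate_name,
                 n_cases = sum(d$carrier), n_controls = sum(!d$carrier),
                 covariates = "age")
}

#' Carrier-by-event contingency analysis for a population cohort
#'
#' Two-by-two analysis of prior-cancer records in mosaic-mutation carriers
#' versus non-carriers in a population unselected for cancer (e.g. 26 of
#' 153 carriers, ~17%, with a pre-DNA-collection solid-tumor record versus
#' 1104 of 10,870 non-carriers, ~10%). Reports per-group event rates in
#' percent and the crude odds ratio; when any cell is zero the
#' Haldane-Anscombe 0.5 correction is applied and flagged. When per-sample
#' carrier/event/age vectors are supplied, an age-adjusted logistic p-value
#' for the carrier term is added.
#'
#' @param carriers_with_event,carriers_total,noncarriers_with_event,noncarriers_total
#'   Cell counts.
#' @param carrier_flag,event_flag,age Optional per-sample vectors for the
#'   age-adjusted model.
#' @return An object of class `mosaic_contingency`.
#' @export
population_contingency <- function(carriers_with_event, carriers_total,
                                   noncarriers_with_event,
                                   noncarriers_total,
                                   carrier_flag = NULL, event_flag = NULL,
                                   age = NULL) {
  if (carriers_with_event > carriers_total ||
      noncarriers_with_event > noncarriers_total)
    stop("event counts must not exceed group totals")
  a <- carriers_with_event
  b <- carriers_total - carriers_with_event
  c_ <- noncarriers_with_event
  d <- noncarriers_total - noncarriers_with_event
  haldane <- any(c(a, b, c_, d) == 0)
  cells <- c(a = a, b = b, c = c_, d = d)
  or_cells <- if (haldane) cells + 0.5 else cells
  res <- list(
    a = a, b = b, c = c_, d = d,
    event_rate_carriers = 100 * a / carriers_total,
    event_rate_noncarriers = 100 * c_ / noncarriers_total,
    crude_or = unname((or_cells["a"] * or_cells["d"]) /
                        (or_cells["b"] * or_cells["c"])),
    haldane_corrected = haldane,
    age_adjusted_p = NA_real_)
  if (!is.null(carrier_flag) && !is.null(event_flag) && !is.null(age)) {
    fit <- glm(event ~ carrier + age, family = binomial(),
               data = data.frame(event = as.logical(event_flag),
                                 carrier = as.logical(carrier_flag),
                                 age = age))
    res$age_adjusted_p <-
      summary(fit)$coefficients["carrierTRUE", "Pr(>|z|)"]
  }
  class(res) <- "mosaic_contingency"
  res
}

#' @export
print.mosaic_assoc <- function(x, ...) {
  cat(sprintf("Logistic association: term '%s'\n", x$term))
  if (x$not_testable) {
    cat("  not testable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  OR = %.3f (%d%% CI %.3f-%.3f), p = %.3g\n",
              x$odds_ratio, round(100 * x$conf_level), x$or_ci_low,
              x$or_ci_high, x$p_value))
  cat(sprintf("  n = %d cases / %d controls; covariates: %s\n",
              x$n_cases, x$n_controls,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  if (length(x$excluded_phenotypes))
    cat("  excluded phenotypes:",
        paste(x$excluded_phenotypes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mosaic_contingency <- function(x, ...) {
  cat("Carrier-by-event contingency\n")
  cat(sprintf("  carriers: %d/%d with event (%.2f%%)\n", x$a, x$a + x$b,
              x$event_rate_carriers))
  cat(sprintf("  non-carriers: %d/%d with event (%.2f%%)\n", x$c,
              x$c + x$d, x$event_rate_noncarriers))
  cat(sprintf("  crude OR = %.3f%s\n", x$crude_or,
              if (x$haldane_corrected) " (Haldane-Anscombe corrected)"
              else ""))
  if (!is.na(x$age_adjusted_p))
    cat(sprintf("  age-adjusted carrier p = %.3g\n", x$age_adjusted_p))
  invisible(x)
}
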