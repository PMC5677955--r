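#' Run the full mosaic-burden pipeline
#'
#' Orchestrates simulate (or load) -> validate/read -> mosaic calling ->
#' case-control association -> burden scan -> tumor depletion, with one
#' global seed fanned out deterministically to the stochastic stages, and
#' writes a report bundle: `calls.tsv`, `carriers.tsv`, `assoc.json`,
#' `burden.tsv`, `depletion.json` and `manifest.json` (package version,
#' seed, parameters and input checksums; no timestamps, so a re-run with
#' the same configuration is byte-identical). Degenerate stages (no
#' carriers, a single phenotype, no tumor pairs) complete with a warning
#' and a not-testable record rather than failing; hard errors halt with
#' the stage named.
#'
#' @param cohort Either a [cohort_config()] (simulation mode; fixtures are
#'   written under `out_dir/fixtures` and read back through the standard
#'   file interface) or a named list of input paths with elements `vcf`,
#'   `metadata`, `annotation` and optionally `pairs`. Exactly one mode.
#' @param out_dir Output directory for the report bundle.
#' @param caller A [caller_params()].
#' @param resampling A [resampling_params()]; its seed is overridden by
#'   the pipeline seed.
#' @param covariates Covariates for the association stage.
#' @param excluded_phenotypes Phenotypes dropped in a second association
#'   fit (reported alongside the full fit).
#' @param seed Integer pipeline seed.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(cohort, out_dir,
                         caller = caller_params(),
                         resampling = resampling_params(n_resamples = 2000L),
                         covariates = c("age", "coverage"),
                         excluded_phenotypes = character(0),
                         seed = 1L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  seed <- as.integer(seed)
  stage_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  simulate_mode <- inherits(cohort, "cohort_config")
  if (simulate_mode) {
    cohort$seed <- stage_seed(1L)
    coh <- stage("simulate", generate_cohort(cohort))
    fix_dir <- file.path(out_dir, "fixtures")
    paths <- stage("simulate", write_fixtures(coh$samples, coh$sites,
                                              fix_dir))
  } else {
    stopifnot(is.list(cohort),
              all(c("vcf", "metadata", "annotation") %in% names(cohort)))
    paths <- cohort
  }

  inputs <- stage("validate", read_inputs(paths$vcf, paths$metadata,
                                          paths$annotation,
                                          pairs_path = paths$pairs))
  samples <- inputs$samples
  sites <- inputs$sites

  ptv_sites <- stage("call", filter_ptv(sites))
  calls <- stage("call", call_mosaic(ptv_sites, caller))
  carriers <- stage("call", carrier_table(samples, calls))
  calls_path <- file.path(out_dir, "calls.tsv")
  write.table(calls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  carriers_path <- file.path(out_dir, "carriers.tsv")
  write.table(carriers, carriers_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  assoc <- stage("associate",
                 fit_carrier_model(samples, carriers, covariates))
  if (assoc$not_testable)
    warning("association stage not testable: ", assoc$reason)
  assoc_excl <- NULL
  if (length(excluded_phenotypes) > 0)
    assoc_excl <- stage("associate",
                        fit_carrier_model(samples, carriers, covariates,
                                          excluded_phenotypes))
  assoc_path <- file.path(out_dir, "assoc.json")
  jsonlite::write_json(list(full = assoc_json(assoc),
                            excluded = if (is.null(assoc_excl)) NULL
                                       else assoc_json(assoc_excl)),
                       assoc_path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)

  burden <- NULL
  burden_path <- NULL
  n_phen <- length(unique(stats::na.omit(samples$phenotype)))
  if (n_phen >= 2) {
    resampling$seed <- stage_seed(2L)
    burden <- stage("burden", burden_scan(samples, carriers, resampling))
    burden_path <- file.path(out_dir, "burden.tsv")
    write.table(burden, burden_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    warning("burden stage skipped: fewer than 2 phenotypes")
  }

  depletion <- NULL
  depletion_path <- NULL
  pairs <- stage("depletion", paired_balances(sites, calls))
  if (nrow(pairs) > 0) {
    depletion <- stage("depletion", depletion_test(pairs, per_gene = TRUE))
    coverage <- stage("depletion", coverage_comparison_or_null(pairs))
    depletion_path <- file.path(out_dir, "depletion.json")
    jsonlite::write_json(list(depletion = depletion_json(depletion),
                              coverage = coverage),
                         depletion_path, auto_unbox = TRUE, digits = 10,
                         null = "null", pretty = TRUE)
  } else {
    warning("depletion stage skipped: no mosaic sites with tumor reads")
  }

  manifest <- list(
    package = "mosaicburden",
    version = as.character(packageVersion("mosaicburden")),
    seed = seed,
    mode = if (simulate_mode) "simulate" else "files",
    caller = unclass(caller),
    resampling = unclass(resampling),
    covariates = covariates,
    excluded_phenotypes = excluded_phenotypes,
    inputs = lapply(paths, function(p) list(
      file = basename(as.character(p)),
      md5 = unname(tools::md5sum(as.character(p))))),
    n_samples = nrow(samples), n_sites = nrow(sites),
    n_skipped_genotypes = inputs$n_skipped,
    stages = list(simulate = simulate_mode, validate = TRUE, call = TRUE,
                  associate = !assoc$not_testable,
                  burden = !is.null(burden),
                  depletion = !is.null(depletion)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = 10, null = "null", pretty = TRUE)

  invisible(list(samples = samples, sites = sites, calls = calls,
                 carriers = carriers, assoc = assoc,
                 assoc_excluded = assoc_excl, burden = burden,
                 depletion = depletion,
                 paths = list(calls = calls_path, carriers = carriers_path,
                              assoc = assoc_path, burden = burden_path,
                              depletion = depletion_path,
                              manifest = manifest_path)))
}

assoc_json <- function(x) {
  keep <- c("term", "odds_ratio", "or_ci_low", "or_ci_high", "p_value",
            "n_cases", "n_controls", "covariates", "excluded_phenotypes",
            "not_testable", "reason")
  out <- unclass(x)[intersect(keep, names(x))]
  out
}

depletion_json <- function(x) {
  keep <- c("statistic", "p_value", "n", "n_dropped_zero_depth",
            "n_dropped_ties", "median_blood_ab", "median_tumor_ab",
            "alternative", "not_testable")
  out <- unclass(x)[keep]
  if (!is.null(x$by_gene))
    out$by_gene <- lapply(x$by_gene, function(g) unclass(g)[keep])
  out
}

coverage_comparison_or_null <- function(pairs) {
  if (nrow(pairs) < 2) return(NULL)
  unclass(coverage_comparison(pairs))
}
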