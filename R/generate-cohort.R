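# Exon counts of the transcript used per gene. TET2 uses the short
# blood-expressed three-exon transcript, so its exon-3 concentration of
# mosaic PTVs is a last-exon pattern.
GENE_EXON_TOTAL <- c(PPM1D = 6L, TET2 = 3L, ASXL1 = 13L, DNMT3A = 23L)
GENE_CHROM <- c(PPM1D = "chr17", TET2 = "chr4", ASXL1 = "chr20",
                DNMT3A = "chr2")
GENE_TRANSCRIPT <- c(PPM1D = "ENST00000305921", TET2 = "ENST00000305737",
                     ASXL1 = "ENST00000375687", DNMT3A = "ENST00000264709")

#' Generate a synthetic case-control cohort
#'
#' Draws sample metadata, per-sample carrier status, mosaic-PTV site
#' observations and background germline heterozygous sites under the
#' configured study design (see [cohort_config()]). Each carrier receives
#' exactly one mosaic PTV, in a gene drawn by `gene_weights`, with a true
#' clonal allele fraction uniform in `mosaic_af_range`. All samples receive
#' Poisson-distributed background germline het sites (true AF 0.5) whose
#' consequences are mostly non-truncating. Per-site read depth is Poisson
#' (optionally negative-binomial) around the sample's mean target coverage,
#' and alternate read counts are binomial in depth and the true allele
#' fraction; a site is only emitted when at least one alternate read was
#' observed (mosaic sites are redrawn so that every carrier's variant is
#' observed). Cancer cases additionally carry paired tumor reads at every
#' site: germline sites stay at AF 0.5 in the tumor while blood mosaics drop
#' to the residual `tumor_depletion_af`, with tumor depth at least matching
#' blood depth in expectation.
#'
#' @param config A [cohort_config()].
#' @return An object of class `mosaic_cohort`: a list with elements
#'   `samples` (sample_id, status, phenotype, age, mean_coverage),
#'   `sites` (sample_id, gene, site_id, ref_reads, alt_reads, consequence,
#'   exon_rank, exon_total, tumor_ref_reads, tumor_alt_reads),
#'   `truth` (per-sample simulated carrier status, gene and allele
#'   fraction, plus a per-site `is_mosaic_true` flag inside `sites`), and
#'   the `config` used.
#' @examples
#' coh <- generate_cohort(cohort_config(n_cases = 100, n_controls = 100))
#' table(coh$samples$status)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed_or_not(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_cases + cfg$n_controls
  status <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  phenotype <- c(rep(names(cfg$phenotype_counts), cfg$phenotype_counts),
                 rep(NA_character_, cfg$n_controls))
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = status, phenotype = phenotype,
    age = trunc_normal(n, ifelse(status == "case", cfg$case_age_mean,
                                 cfg$control_age_mean),
                       ifelse(status == "case", cfg$case_age_sd,
                              cfg$control_age_sd), lower = 18),
    stringsAsFactors = FALSE)

  depth_mean <- ifelse(status == "case", cfg$case_depth_mean,
                       cfg$control_depth_mean)
  if (cfg$depth_cv > 0) {
    shape <- 1 / cfg$depth_cv^2
    samples$mean_coverage <- rgamma(n, shape = shape, rate = shape) * depth_mean
  } else {
    samples$mean_coverage <- depth_mean
  }

  # logit-linear carrier model; base rate refers to a control at the
  # control-cohort mean age
  if (cfg$carrier_base_rate == 0) {
    p_carrier <- rep(0, n)
  } else {
    p_carrier <- plogis(qlogis(cfg$carrier_base_rate) +
                          cfg$carrier_age_slope *
                            (samples$age - cfg$control_age_mean) +
                          cfg$carrier_case_log_or * (status == "case"))
  }
  is_carrier <- rbinom(n, 1L, p_carrier) == 1L

  carrier_idx <- which(is_carrier)
  n_car <- length(carrier_idx)
  truth <- data.frame(sample_id = samples$sample_id,
                      is_carrier_true = is_carrier,
                      carrier_gene = NA_character_,
                      true_af = NA_real_,
                      stringsAsFactors = FALSE)

  mosaic <- NULL
  if (n_car > 0) {
    gene <- sample(names(cfg$gene_weights), n_car, replace = TRUE,
                   prob = cfg$gene_weights)
    af <- runif(n_car, cfg$mosaic_af_range[1], cfg$mosaic_af_range[2])
    truth$carrier_gene[carrier_idx] <- gene
    truth$true_af[carrier_idx] <- af
    mosaic <- data.frame(
      sample_idx = carrier_idx, gene = gene, true_af = af,
      consequence = sample(PTV_CLASSES, n_car, replace = TRUE,
                           prob = c(0.45, 0.15, 0.40)),
      is_mosaic_true = TRUE, stringsAsFactors = FALSE)
    mosaic$exon_rank <- draw_exon_rank(gene, cfg$exon_concentration)
  }

  # background germline het sites: Poisson(rate) per sample per gene
  n_gl <- rpois(n * length(CANDIDATE_GENES), cfg$germline_site_rate)
  gl_sample <- rep(rep(seq_len(n), times = length(CANDIDATE_GENES)), n_gl)
  gl_gene <- rep(rep(CANDIDATE_GENES, each = n), n_gl)
  germline <- NULL
  if (length(gl_sample) > 0) {
    gcp <- cfg$germline_consequence_probs
    germline <- data.frame(
      sample_idx = gl_sample, gene = gl_gene, true_af = 0.5,
      consequence = sample(names(gcp), length(gl_sample), replace = TRUE,
                           prob = gcp),
      is_mosaic_true = FALSE, stringsAsFactors = FALSE)
    tot <- GENE_EXON_TOTAL[germline$gene]
    germline$exon_rank <- as.integer(1L + floor(runif(nrow(germline)) * tot))
  }

  sites <- rbind(mosaic, germline)
  if (is.null(sites) || nrow(sites) == 0) {
    return(empty_cohort(samples, truth, cfg))
  }

  # read depths and alt counts; mosaic sites are conditioned on alt >= 1 so
  # every carrier's variant is observed, germline sites with alt = 0 are
  # simply never called and dropped
  lam <- samples$mean_coverage[sites$sample_idx]
  sites$depth <- draw_depth(lam, cfg$depth_dispersion)
  sites$alt_reads <- rbinom(nrow(sites), sites$depth, sites$true_af)
  redo <- which(sites$is_mosaic_true & sites$alt_reads < 1)
  while (length(redo) > 0) {
    sites$depth[redo] <- draw_depth(lam[redo], cfg$depth_dispersion)
    sites$alt_reads[redo] <- rbinom(length(redo), sites$depth[redo],
                                    sites$true_af[redo])
    redo <- redo[sites$alt_reads[redo] < 1]
  }
  keep <- sites$alt_reads >= 1L & sites$depth >= 1L
  sites <- sites[keep, , drop = FALSE]
  sites$ref_reads <- sites$depth - sites$alt_reads

  # paired tumor reads for cancer cases only
  is_case_site <- samples$status[sites$sample_idx] == "case"
  sites$tumor_ref_reads <- NA_integer_
  sites$tumor_alt_reads <- NA_integer_
  if (any(is_case_site)) {
    i <- which(is_case_site)
    tlam <- samples$mean_coverage[sites$sample_idx[i]] * cfg$tumor_depth_factor
    tdp <- pmax(draw_depth(tlam, cfg$depth_dispersion), 1L)
    taf <- ifelse(sites$is_mosaic_true[i], cfg$tumor_depletion_af, 0.5)
    talt <- rbinom(length(i), tdp, taf)
    sites$tumor_alt_reads[i] <- talt
    sites$tumor_ref_reads[i] <- tdp - talt
  }

  ord <- order(sites$gene, sites$sample_idx)
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- sprintf("var%06d", seq_len(nrow(sites)))
  sites$sample_id <- samples$sample_id[sites$sample_idx]
  sites$exon_total <- unname(GENE_EXON_TOTAL[sites$gene])

  out_cols <- c("sample_id", "gene", "site_id", "ref_reads", "alt_reads",
                "consequence", "exon_rank", "exon_total",
                "tumor_ref_reads", "tumor_alt_reads", "is_mosaic_true")
  sites <- sites[, out_cols]
  rownames(sites) <- NULL

  structure(list(samples = samples, sites = sites, truth = truth,
                 config = cfg),
            class = "mosaic_cohort")
}

empty_cohort <- function(samples, truth, cfg) {
  sites <- data.frame(sample_id = character(), gene = character(),
                      site_id = character(), ref_reads = integer(),
                      alt_reads = integer(), consequence = character(),
                      exon_rank = integer(), exon_total = integer(),
                      tumor_ref_reads = integer(), tumor_alt_reads = integer(),
                      is_mosaic_true = logical(), stringsAsFactors = FALSE)
  structure(list(samples = samples, sites = sites, truth = truth,
                 config = cfg), class = "mosaic_cohort")
}

trunc_normal <- function(n, mean, sd, lower) {
  mu <- rep_len(mean, n)
  s <- rep_len(sd, n)
  x <- rnorm(n, mu, s)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mu[bad], s[bad])
    bad <- bad[x[bad] < lower]
  }
  x
}

draw_depth <- function(lambda, dispersion) {
  if (is.null(dispersion)) rpois(length(lambda), lambda)
  else rnbinom(length(lambda), size = dispersion, mu = lambda)
}

# mosaic PTVs concentrate in a gene-characteristic exon (the last exon for
# PPM1D/ASXL1 and for TET2's three-exon transcript); DNMT3A is uniform
draw_exon_rank <- function(gene, concentration) {
  tot <- GENE_EXON_TOTAL[gene]
  target <- ifelse(gene == "DNMT3A", NA_integer_, tot)
  u <- runif(length(gene))
  hit <- !is.na(target) & u < concentration
  rank <- integer(length(gene))
  rank[hit] <- target[hit]
  other <- which(!hit)
  if (length(other) > 0) {
    n_alt <- ifelse(is.na(target[other]), tot[other], tot[other] - 1L)
    pick <- 1L + floor(runif(length(other)) * n_alt)
    # for genes with a target exon, skip it when drawing the remainder
    shift <- !is.na(target[other]) & pick >= target[other]
    rank[other] <- as.integer(pick + ifelse(shift, 1L, 0L))
    rank[other] <- pmin(rank[other], tot[other])
  }
  as.integer(rank)
}

#' @export
print.mosaic_cohort <- function(x, ...) {
  cat("Synthetic mosaic-PTV cohort\n")
  cat(sprintf("  samples: %d cases, %d controls\n",
              sum(x$samples$status == "case"),
              sum(x$samples$status == "control")))
  cat(sprintf("  sites: %d (%d true mosaic, %d germline background)\n",
              nrow(x$sites), sum(x$sites$is_mosaic_true),
              sum(!x$sites$is_mosaic_true)))
  cat(sprintf("  true carriers: %d (%.2f%%)\n",
              sum(x$truth$is_carrier_true),
              100 * mean(x$truth$is_carrier_true)))
  invisible(x)
}
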