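test_that("the Bonferroni threshold is alpha over the number of tests", {
  expect_identical(bonferroni_threshold(0.05, 20), 0.0025)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("age-matched draws accept trivially matched pools and reject mismatched ones", {
  params <- resampling_params(n_resamples = 10, seed = 1)
  # identical ages: first draw accepted with p = 1
  withr::with_seed(2, {
    d <- draw_age_matched_set(rep(60, 30), rep(60, 10), 10, params)
  })
  expect_identical(d$n_attempts, 1L)
  expect_equal(d$age_p, 1)

  # N = pool size: the single possible set matches itself
  withr::with_seed(2, {
    d2 <- draw_age_matched_set(rep(c(40, 70), 5), rep(c(40, 70), 5), 10,
                               params)
  })
  expect_identical(sort(d2$indices), 1:10)
  expect_equal(d2$age_p, 1)

  expect_error(draw_age_matched_set(rep(60, 5), rep(60, 10), 10, params),
               "pool smaller")

  # two age strata with an old-only target: acceptance is materially
  # below 1 and accepted sets skew old
  pool <- c(rep(40, 30), rep(70, 30))
  target <- rep(70, 8)
  res <- withr::with_seed(5, {
    lapply(1:200, function(i)
      draw_age_matched_set(pool, target, 8,
                           resampling_params(max_draw_factor = 2000)))
  })
  attempts <- vapply(res, `[[`, 1L, "n_attempts")
  mean_age <- vapply(res, function(r) mean(pool[r$indices]), 0)
  expect_gt(mean(attempts), 2)          # most raw draws rejected
  expect_gt(mean(mean_age), mean(pool)) # accepted sets skew to the target
})

test_that("an unmatchable age distribution fails naming the phenotype", {
  pool <- c(rep(40, 200), rep(70, 8))
  params <- resampling_params(n_resamples = 5, max_draw_factor = 20,
                              seed = 3)
  expect_error(
    phenotype_burden(
      data.frame(sample_id = sprintf("S%03d", 1:208), status = "case",
                 phenotype = c(rep("YOUNG", 200), rep("OLD", 8)),
                 age = pool, mean_coverage = 30, stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("S%03d", 1:208), is_carrier = FALSE,
                 carrier_genes = "", stringsAsFactors = FALSE),
      "OLD", params = params),
    "OLD")
})

test_that("the exhaustive-enumeration oracle fixes the worked 1/6 example", {
  flags <- c(TRUE, TRUE, FALSE, FALSE)
  # target set {1, 3}: frequency 0.5; only the subset {1, 2} exceeds it
  expect_equal(oracle_burden_p(flags, 0.5, 2), 1 / 6, tolerance = 1e-12)

  d <- flat_cases(flags, phenotype = c("T", "O", "T", "O"))
  B <- 30000L
  pb <- phenotype_burden(d$samples, d$carriers, "T",
                         params = resampling_params(n_resamples = B,
                                                    seed = 10))
  expect_equal(pb$observed_freq, 0.5)
  se <- sqrt((1 / 6) * (5 / 6) / B)
  expect_lt(abs(pb$p_literal - 1 / 6), 3 * se)
  expect_gte(pb$p_add_one, pb$p_literal)
  expect_lte(pb$p_add_one, 1)
})

test_that("resampled p matches exhaustive enumeration across random small pools", {
  withr::with_seed(14, {
    cases <- replicate(6, list(flags = stats::runif(10) < 0.4,
                               n_target = sample(3:6, 1)),
                       simplify = FALSE)
  })
  for (k in seq_along(cases)) {
    flags <- cases[[k]]$flags
    nt <- cases[[k]]$n_target
    pheno <- rep("O", 10)
    pheno[seq_len(nt)] <- "T"
    truth <- oracle_burden_p(flags, mean(flags[seq_len(nt)]), nt)
    d <- flat_cases(flags, pheno)
    B <- 20000L
    pb <- phenotype_burden(d$samples, d$carriers, "T",
                           params = resampling_params(n_resamples = B,
                                                      seed = 100 + k))
    se <- sqrt(max(truth * (1 - truth), 1e-6) / B)
    expect_lt(abs(pb$p_literal - truth), 3 * se + 1e-9)
  }
})

test_that("maximal burden yields literal p 0 and add-one 1/(B+1)", {
  flags <- c(rep(TRUE, 3), rep(FALSE, 9))
  pheno <- c(rep("T", 3), rep("O", 9))
  d <- flat_cases(flags, pheno)
  pb <- phenotype_burden(d$samples, d$carriers, "T",
                         params = resampling_params(n_resamples = 500,
                                                    seed = 4))
  expect_identical(pb$p_literal, 0)
  expect_equal(pb$p_add_one, 1 / 501, tolerance = 1e-12)
})

test_that("burden results are deterministic in the seed and label-invariant", {
  d <- flat_cases(stats::runif(40) < 0.3, rep(c("T", "O"), 20))
  params <- resampling_params(n_resamples = 2000, seed = 6)
  a <- phenotype_burden(d$samples, d$carriers, "T", params = params)
  b <- phenotype_burden(d$samples, d$carriers, "T", params = params)
  expect_identical(a, b)

  perm <- withr::with_seed(7, sample.int(40))
  s2 <- d$samples[perm, ]
  c2 <- d$carriers[perm, ]
  s2$sample_id <- paste0("Z", s2$sample_id)
  c2$sample_id <- paste0("Z", c2$sample_id)
  b2 <- phenotype_burden(s2, c2, "T", params = params)
  expect_identical(a$observed_freq, b2$observed_freq)
  # identical ages: the resampling null itself is exchangeable, so the
  # empirical p agrees up to Monte-Carlo error
  expect_lt(abs(a$p_literal - b2$p_literal),
            3 * sqrt(0.25 / params$n_resamples))
})

test_that("the scan flags an enriched phenotype and localises its gene", {
  withr::with_seed(31, {
    n_per <- 250
    phen <- rep(c("ENR", "P2", "P3", "P4"), each = n_per)
    flags <- stats::runif(4 * n_per) < ifelse(phen == "ENR", 0.15, 0.03)
    genes <- ifelse(phen == "ENR", "PPM1D",
                    sample(CANDIDATE_GENES, 4 * n_per, replace = TRUE))
  })
  samples <- data.frame(sample_id = sprintf("S%04d", seq_along(phen)),
                        status = "case", phenotype = phen, age = 60,
                        mean_coverage = 30, stringsAsFactors = FALSE)
  carriers <- data.frame(sample_id = samples$sample_id,
                         is_carrier = flags,
                         carrier_genes = ifelse(flags, genes, ""),
                         stringsAsFactors = FALSE)
  scan <- burden_scan(samples, carriers,
                      resampling_params(n_resamples = 2000, seed = 12))
  expect_identical(nrow(scan), 4L * 5L)  # 4 phenotypes x (all + 4 genes)
  expect_equal(scan$sig_threshold[1], 0.05 / 4)
  overall <- scan[scan$gene == "all", ]
  expect_true(overall$significant[overall$phenotype == "ENR"])
  expect_false(any(overall$significant[overall$phenotype != "ENR"]))
  # the enriched phenotype's strongest gene cell is PPM1D
  enr_genes <- scan[scan$phenotype == "ENR" & scan$gene != "all", ]
  expect_identical(enr_genes$gene[which.min(enr_genes$empirical_p)],
                   "PPM1D")
})
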