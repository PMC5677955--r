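test_that("write/read round trip preserves the site-observation multiset", {
  coh <- generate_cohort(small_config())
  dir <- withr::local_tempdir()
  paths <- write_fixtures(coh$samples, coh$sites, dir)
  inp <- suppressMessages(read_inputs(paths$vcf, paths$metadata,
                                      paths$annotation, paths$pairs))
  expect_identical(inp$n_skipped, 0L)
  cols <- names(inp$sites)
  canon <- function(x) {
    x <- x[do.call(order, x[c("site_id", "sample_id")]), cols]
    rownames(x) <- NULL
    x
  }
  expect_equal(canon(inp$sites), canon(coh$sites[, cols]))
  # metadata round trip (controls' phenotype encoded as "none")
  expect_equal(inp$samples$sample_id, coh$samples$sample_id)
  expect_equal(inp$samples$age, coh$samples$age)
  expect_identical(is.na(inp$samples$phenotype),
                   is.na(coh$samples$phenotype))
})

test_that("VCF sample columns follow metadata order and empty site lists are valid", {
  samples <- data.frame(sample_id = c("B2", "A1", "C3"), status = "control",
                        phenotype = NA_character_, age = 50,
                        mean_coverage = 30, stringsAsFactors = FALSE)
  sites <- data.frame(sample_id = c("A1", "C3"), gene = c("PPM1D", "TET2"),
                      site_id = c("v1", "v2"), ref_reads = c(20L, 18L),
                      alt_reads = c(5L, 9L),
                      consequence = c("stop_gained", "missense"),
                      exon_rank = c(6L, 2L), exon_total = c(6L, 3L),
                      tumor_ref_reads = NA_integer_,
                      tumor_alt_reads = NA_integer_,
                      stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(samples, sites, dir)
  hdr <- grep("^#CHROM", readLines(paths$vcf), value = TRUE)
  expect_identical(utils::tail(strsplit(hdr, "\t")[[1]], 3),
                   c("B2", "A1", "C3"))
  inp <- read_inputs(paths$vcf, paths$metadata, paths$annotation)
  expect_setequal(inp$sites$sample_id, c("A1", "C3"))

  # zero variant records: header-only VCF that still reads back cleanly
  p0 <- write_fixtures(samples, sites[0, ], dir)
  expect_identical(sum(!grepl("^#", readLines(p0$vcf))), 0L)
  inp0 <- read_inputs(p0$vcf, paths$metadata, paths$annotation)
  expect_identical(nrow(inp0$sites), 0L)
})

write_hand_vcf <- function(dir, ad2 = "14,16") {
  vcf <- file.path(dir, "hand.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr17>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("chr17", "1000", "v1", "A", "T", ".", "PASS", ".", "GT:AD:DP",
            "0/1:25,5:30", "0/0:.:."), collapse = "\t"),
    paste(c("chr17", "1010", "v2", "A", "T", ".", "PASS", ".", "GT:AD:DP",
            "0/0:.:.", paste0("0/1:", ad2, ":30")), collapse = "\t")),
    vcf)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("sample_id\tstatus\tphenotype\tage\tmean_coverage",
               "S1\tcase\tOV\t61\t33.1", "S2\tcontrol\tnone\t50\t29.4"),
             meta)
  anno <- file.path(dir, "anno.tsv")
  writeLines(c("site_id\tgene\ttranscript\tconsequence\texon_rank\texon_total",
               "v1\tPPM1D\tENST00000305921\tstop_gain\t6\t6",
               "v2\tPPM1D\tENST00000305921\tsplice_donor_variant\t5\t6"),
             anno)
  list(vcf = vcf, meta = meta, anno = anno)
}

test_that("homozygous-reference genotypes yield no observation and bad AD is skipped", {
  dir <- withr::local_tempdir()
  p <- write_hand_vcf(dir)
  inp <- suppressMessages(read_inputs(p$vcf, p$meta, p$anno))
  # two records x two samples, but only the two 0/1 genotypes come back
  expect_identical(nrow(inp$sites), 2L)
  expect_setequal(paste(inp$sites$sample_id, inp$sites$site_id),
                  c("S1 v1", "S2 v2"))
  # raw VEP-style labels mapped onto the controlled vocabulary
  expect_setequal(inp$sites$consequence,
                  c("stop_gained", "splice_essential"))

  # one non-ref genotype with missing AD: skipped with a message (50%
  # skipped, above the 10% tolerance -> error)
  p2 <- write_hand_vcf(dir, ad2 = ".")
  expect_error(suppressMessages(read_inputs(p2$vcf, p2$meta, p2$anno)),
               "10%")
})

test_that("validation rejects unknown samples and consequence labels", {
  dir <- withr::local_tempdir()
  p <- write_hand_vcf(dir)
  meta_bad <- file.path(dir, "meta_bad.tsv")
  writeLines(c("sample_id\tstatus\tphenotype\tage\tmean_coverage",
               "S1\tcase\tOV\t61\t33.1"), meta_bad)
  expect_error(read_inputs(p$vcf, meta_bad, p$anno), "S2")

  anno_bad <- file.path(dir, "anno_bad.tsv")
  writeLines(c("site_id\tgene\ttranscript\tconsequence\texon_rank\texon_total",
               "v1\tPPM1D\tT1\tstop_gained\t6\t6",
               "v2\tPPM1D\tT1\tweird_label\t5\t6"), anno_bad)
  expect_error(read_inputs(p$vcf, p$meta, anno_bad), "weird_label")

  anno_missing <- file.path(dir, "anno_missing.tsv")
  writeLines(c("site_id\tgene\ttranscript\tconsequence\texon_rank\texon_total",
               "v1\tPPM1D\tT1\tstop_gained\t6\t6"), anno_missing)
  expect_error(read_inputs(p$vcf, p$meta, anno_missing), "annotation")
})
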