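#' Write a simulated cohort as standard input files
#'
#' Emits the three standard inputs consumed by [read_inputs()]: a VCF 4.2
#' with per-genotype `GT`, `AD` (ref,alt) and `DP` fields, a tab-separated
#' sample metadata file and a tab-separated variant annotation file, plus a
#' paired blood/tumor read-count table when any site carries tumor reads.
#' Each site is written as one biallelic VCF record (frameshifts as a 1-bp
#' deletion, all other classes as an A>T substitution — the representation
#' is schematic; consequences live in the annotation file). Sample columns
#' follow the metadata row order; samples without the variant are `0/0` with
#' missing AD/DP.
#'
#' @param samples,sites Tables as produced by [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths (`vcf`, `metadata`,
#'   `annotation`, and `pairs` when tumor reads are present).
#' @seealso [read_inputs()]
#' @export
write_fixtures <- function(samples, sites, out_dir) {
  if (nrow(samples) == 0) stop("samples must be non-empty")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                metadata = file.path(out_dir, "metadata.tsv"),
                annotation = file.path(out_dir, "annotation.tsv"))

  meta <- samples[, c("sample_id", "status", "phenotype", "age",
                      "mean_coverage")]
  meta$phenotype[is.na(meta$phenotype)] <- "none"
  write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)

  anno <- unique(sites[, c("site_id", "gene", "consequence", "exon_rank",
                           "exon_total")])
  anno$transcript <- unname(GENE_TRANSCRIPT[anno$gene])
  anno <- anno[, c("site_id", "gene", "transcript", "consequence",
                   "exon_rank", "exon_total")]
  anno <- anno[order(anno$site_id), ]
  write.table(anno, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)

  write_cohort_vcf(samples, sites, paths$vcf)

  has_tumor <- nrow(sites) > 0 && any(!is.na(sites$tumor_alt_reads))
  if (has_tumor) {
    paths$pairs <- file.path(out_dir, "pairs.tsv")
    pr <- sites[!is.na(sites$tumor_alt_reads),
                c("sample_id", "site_id", "gene", "ref_reads", "alt_reads",
                  "tumor_ref_reads", "tumor_alt_reads")]
    names(pr) <- c("sample_id", "site_id", "gene", "blood_ref", "blood_alt",
                   "tumor_ref", "tumor_alt")
    write.table(pr, paths$pairs, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

write_cohort_vcf <- function(samples, sites, path) {
  ids <- samples$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicburden",
    sprintf("##contig=<ID=%s>", unique(unname(GENE_CHROM))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Read depth (ref+alt informative reads)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  if (nrow(sites) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }

  site_ids <- sort(unique(sites$site_id))
  site_info <- sites[!duplicated(sites$site_id), ]
  rownames(site_info) <- site_info$site_id
  site_info <- site_info[site_ids, ]

  chrom <- unname(GENE_CHROM[site_info$gene])
  pos <- integer(nrow(site_info))
  for (g in unique(site_info$gene)) {
    idx <- which(site_info$gene == g)
    pos[idx] <- 100000L + 10L * seq_along(idx)
  }
  is_fs <- site_info$consequence == "frameshift"
  ref <- ifelse(is_fs, "CA", "A")
  alt <- ifelse(is_fs, "C", "T")

  gmat <- matrix("0/0:.:.", nrow = nrow(site_info), ncol = length(ids),
                 dimnames = list(site_ids, ids))
  ri <- match(sites$site_id, site_ids)
  ci <- match(sites$sample_id, ids)
  gmat[cbind(ri, ci)] <- sprintf("0/1:%d,%d:%d", sites$ref_reads,
                                 sites$alt_reads,
                                 sites$ref_reads + sites$alt_reads)

  body <- paste(chrom, pos, site_ids, ref, alt, ".", "PASS", ".",
                "GT:AD:DP",
                apply(gmat, 1L, paste, collapse = "\t"), sep = "\t")
  # keep a stable chromosomal sort for well-formedness
  ord <- order(chrom, pos)
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

# fixed mapping from raw VEP-style consequence strings to the controlled
# vocabulary; applied (and logged) at read time
CONSEQUENCE_ALIASES <- c(
  splice_donor_variant = "splice_essential",
  splice_acceptor_variant = "splice_essential",
  stop_gain = "stop_gained",
  frameshift_variant = "frameshift",
  missense_variant = "missense")

#' Read and validate the standard input files
#'
#' Loads a VCF (FORMAT fields `GT`, `AD`, `DP`), a sample metadata TSV and a
#' variant annotation TSV, and returns long-format tables: one row per
#' non-reference genotype per sample, with ref/alt read counts taken from
#' `AD`. Genotypes whose `AD` is missing or sums to zero are skipped with a
#' message; more than 10% skipped is an error. VEP-style consequence strings
#' (e.g. `splice_donor_variant`) are mapped onto the controlled vocabulary.
#'
#' @param vcf_path,metadata_path,annotation_path Input files as written by
#'   [write_fixtures()] (or equivalent).
#' @param pairs_path Optional paired blood/tumor read-count TSV; when given,
#'   tumor read counts are attached to the matching site observations.
#' @return A list with `samples` and `sites` data frames matching the
#'   layout of [generate_cohort()] output (without simulation truth), plus
#'   `n_skipped`, the number of genotypes dropped for unusable AD.
#' @export
read_inputs <- function(vcf_path, metadata_path, annotation_path,
                        pairs_path = NULL) {
  for (p in c(vcf_path, metadata_path, annotation_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)

  samples <- read.delim(metadata_path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  req <- c("sample_id", "status", "phenotype", "age", "mean_coverage")
  if (!all(req %in% names(samples)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  samples$phenotype[samples$phenotype %in% c("none", "", ".")] <-
    NA_character_

  anno <- read.delim(annotation_path, stringsAsFactors = FALSE,
                     colClasses = c(site_id = "character"))
  reqa <- c("site_id", "gene", "transcript", "consequence", "exon_rank",
            "exon_total")
  if (!all(reqa %in% names(anno)))
    stop("annotation must have columns: ", paste(reqa, collapse = ", "))
  mapped <- anno$consequence %in% names(CONSEQUENCE_ALIASES)
  if (any(mapped)) {
    message(sum(mapped), " annotation consequence label(s) mapped onto the ",
            "controlled vocabulary")
    anno$consequence[mapped] <-
      unname(CONSEQUENCE_ALIASES[anno$consequence[mapped]])
  }
  bad <- setdiff(unique(anno$consequence), CONSEQUENCE_LEVELS)
  if (length(bad) > 0)
    stop("unknown consequence label(s) in annotation: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(anno$site_id))
    stop("annotation must be pre-reduced to one row per site_id")

  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF lacks the GT FORMAT field")
  vcf_samples <- colnames(gt)
  missing_meta <- setdiff(vcf_samples, samples$sample_id)
  if (length(missing_meta) > 0)
    stop("VCF sample(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  site_ids <- rownames(gt)
  missing_anno <- setdiff(site_ids, anno$site_id)
  if (length(missing_anno) > 0)
    stop("VCF record(s) without annotation: ",
         paste(utils::head(missing_anno, 10), collapse = ", "))

  empty_sites <- function(n_skipped = 0L) {
    s <- data.frame(sample_id = character(), gene = character(),
                    site_id = character(), ref_reads = integer(),
                    alt_reads = integer(), consequence = character(),
                    exon_rank = integer(), exon_total = integer(),
                    tumor_ref_reads = integer(),
                    tumor_alt_reads = integer(), stringsAsFactors = FALSE)
    list(samples = samples, sites = s, n_skipped = n_skipped)
  }
  if (nrow(gt) == 0) return(empty_sites())

  nonref <- !is.na(gt) & grepl("1", gt, fixed = TRUE)
  hit <- which(nonref, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_sites())

  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD FORMAT field")
  ref_reads <- alt_reads <- integer(nrow(hit))
  usable <- logical(nrow(hit))
  for (k in seq_len(nrow(hit))) {
    v <- ad[[hit[k, 1], hit[k, 2]]]
    if (length(v) >= 2 && !anyNA(v[1:2]) && sum(v[1:2]) > 0) {
      usable[k] <- TRUE
      ref_reads[k] <- v[1]
      alt_reads[k] <- v[2]
    }
  }
  n_skipped <- sum(!usable)
  if (n_skipped > 0)
    message(n_skipped, " genotype(s) skipped for missing or zero AD")
  if (n_skipped > 0.10 * nrow(hit))
    stop("more than 10% of non-reference genotypes have unusable AD (",
         n_skipped, " of ", nrow(hit), ")")
  hit <- hit[usable, , drop = FALSE]

  sites <- data.frame(
    sample_id = vcf_samples[hit[, 2]],
    site_id = site_ids[hit[, 1]],
    ref_reads = ref_reads[usable],
    alt_reads = alt_reads[usable],
    stringsAsFactors = FALSE)
  ai <- match(sites$site_id, anno$site_id)
  sites$gene <- anno$gene[ai]
  sites$consequence <- anno$consequence[ai]
  sites$exon_rank <- as.integer(anno$exon_rank[ai])
  sites$exon_total <- as.integer(anno$exon_total[ai])
  sites$tumor_ref_reads <- NA_integer_
  sites$tumor_alt_reads <- NA_integer_

  if (!is.null(pairs_path)) {
    if (!file.exists(pairs_path)) stop("input file does not exist: ",
                                       pairs_path)
    pr <- read.delim(pairs_path, stringsAsFactors = FALSE,
                     colClasses = c(sample_id = "character",
                                    site_id = "character"))
    key <- paste(sites$sample_id, sites$site_id)
    pi <- match(paste(pr$sample_id, pr$site_id), key)
    if (anyNA(pi))
      stop("pairs file refers to sample/site combinations absent from ",
           "the VCF")
    sites$tumor_ref_reads[pi] <- as.integer(pr$tumor_ref)
    sites$tumor_alt_reads[pi] <- as.integer(pr$tumor_alt)
  }

  sites <- sites[, c("sample_id", "gene", "site_id", "ref_reads",
                     "alt_reads", "consequence", "exon_rank", "exon_total",
                     "tumor_ref_reads", "tumor_alt_reads")]
  rownames(sites) <- NULL
  list(samples = samples, sites = sites, n_skipped = n_skipped)
}
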