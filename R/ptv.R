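#' Keep protein-truncating variants only
#'
#' Restricts site observations to the protein-truncating consequence
#' classes: stop gain, essential splice site, frameshift. Row order is
#' preserved. Unknown consequence labels are an error rather than a silent
#' pass-through.
#'
#' @param sites A site-observation data frame with a `consequence` column.
#' @return The PTV subset of `sites`.
#' @export
filter_ptv <- function(sites) {
  stopifnot(is.data.frame(sites), "consequence" %in% names(sites))
  bad <- setdiff(unique(sites$consequence), CONSEQUENCE_LEVELS)
  if (length(bad) > 0)
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "))
  out <- sites[sites$consequence %in% PTV_CLASSES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exon-position enrichment of PTVs in one gene
#'
#' Counts PTVs per exon and summarises the last-exon concentration that
#' marks gain-of-function truncating alleles escaping nonsense-mediated
#' decay (e.g. 17 of 18 mosaic PPM1D PTVs in the gene's last exon).
#'
#' @param ptv_sites PTV site observations, all in `gene`, with `exon_rank`
#'   and `exon_total` populated.
#' @param gene Gene symbol.
#' @param test Also run a two-sided exact binomial test of the last-exon
#'   count against a uniform-across-exons null (a diagnostic extension;
#'   exon lengths are not modelled).
#' @return An object of class `exon_enrichment`: gene, `counts_by_exon`
#'   (named vector over observed exon ranks), `last_exon_count`,
#'   `total_ptv`, `last_exon_fraction` (`NA` and `undefined = TRUE` when
#'   there are no PTVs), and optionally `uniform_test_p`.
#' @export
exon_enrichment <- function(ptv_sites, gene, test = FALSE) {
  stopifnot(is.data.frame(ptv_sites))
  if (nrow(ptv_sites) > 0) {
    if (!all(ptv_sites$gene == gene))
      stop("all sites must belong to gene ", gene)
    if (anyNA(ptv_sites$exon_rank) || anyNA(ptv_sites$exon_total))
      stop("exon_rank and exon_total must be populated")
    if (any(ptv_sites$exon_rank > ptv_sites$exon_total))
      stop("exon_rank must not exceed exon_total")
  }
  total <- nrow(ptv_sites)
  if (total == 0) {
    res <- list(gene = gene, counts_by_exon = integer(0),
                last_exon_count = 0L, total_ptv = 0L,
                last_exon_fraction = NA_real_, undefined = TRUE)
    class(res) <- "exon_enrichment"
    return(res)
  }
  tab <- table(factor(ptv_sites$exon_rank,
                      levels = sort(unique(ptv_sites$exon_rank))))
  counts <- setNames(as.integer(tab), names(tab))
  last_n <- sum(ptv_sites$exon_rank == ptv_sites$exon_total)
  res <- list(gene = gene, counts_by_exon = counts,
              last_exon_count = as.integer(last_n),
              total_ptv = as.integer(total),
              last_exon_fraction = last_n / total,
              undefined = FALSE)
  if (isTRUE(test)) {
    exon_total <- max(ptv_sites$exon_total)
    res$uniform_test_p <- stats::binom.test(last_n, total,
                                            p = 1 / exon_total)$p.value
  }
  class(res) <- "exon_enrichment"
  res
}

#' @export
print.exon_enrichment <- function(x, ...) {
  cat(sprintf("Exon-position summary for %s\n", x$gene))
  if (x$total_ptv == 0) {
    cat("  no PTVs; last-exon fraction undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  %d of %d PTVs in the last exon (fraction %.3f)\n",
              x$last_exon_count, x$total_ptv, x$last_exon_fraction))
  if (!is.null(x$uniform_test_p))
    cat(sprintf("  exact binomial test vs uniform-across-exons: p = %.3g\n",
                x$uniform_test_p))
  invisible(x)
}
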