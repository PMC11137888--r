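#' Per-gene screening statistics from an FPKM matrix
#'
#' Computes, for every gene, the mean FPKM (MF), the standard deviation (SD)
#' of FPKM across samples, and the coefficient of variation
#' CV = 100 * SD / MF in percent — the three indices used to pre-select
#' candidate reference genes from RNA-seq compendia before any qPCR is run.
#'
#' The SD uses the n-1 denominator by default (the spreadsheet convention
#' under which such screens are usually done); `sd_denominator = "n"` is
#' available for sensitivity checks. A gene with MF = 0 gets CV = NaN.
#'
#' @param fpkm `fpkm_matrix` with at least two samples.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return data frame with columns `gene_id`, `mean_fpkm`, `sd_fpkm`,
#'   `cv_percent`, one row per gene in input order.
#' @export
compute_gene_stats <- function(fpkm, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(fpkm, "fpkm_matrix"))
  sd_denominator <- match.arg(sd_denominator)
  n <- ncol(fpkm$values)
  if (n < 2) stop("need >= 2 samples to compute an SD", call. = FALSE)
  mf <- rowMeans(fpkm$values)
  sdv <- apply(fpkm$values, 1, stats::sd)
  if (sd_denominator == "n") sdv <- sdv * sqrt((n - 1) / n)
  data.frame(gene_id = rownames(fpkm$values),
             mean_fpkm = unname(mf),
             sd_fpkm = unname(sdv),
             cv_percent = unname(100 * sdv / mf),
             stringsAsFactors = FALSE)
}

#' Screen candidate reference genes by expression level and variability
#'
#' Retains genes with mean FPKM at or above `min_mf` (adequately expressed)
#' and CV at or below `max_cv` percent (stable across the compendium), both
#' thresholds inclusive. The result is sorted by ascending CV, ties broken
#' by gene id, so the first row is the most promising candidate.
#'
#' Annotation credibility cannot be judged from expression values; when an
#' `allow` list is given, only genes on it are eligible (the filter is
#' applied after the numeric thresholds).
#'
#' @param stats data frame from [compute_gene_stats()].
#' @param min_mf minimum mean FPKM (default 10).
#' @param max_cv maximum CV in percent (default 20).
#' @param allow optional character vector of eligible gene ids.
#' @return the retained rows of `stats`, ascending in `cv_percent`.
#' @export
screen_candidates <- function(stats, min_mf = 10, max_cv = 20, allow = NULL) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0,
            min_mf > 0, max_cv > 0)
  keep <- stats$mean_fpkm >= min_mf & stats$cv_percent <= max_cv
  if (!is.null(allow)) keep <- keep & stats$gene_id %in% allow
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$cv_percent, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
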