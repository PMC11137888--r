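#' Comparative Delta Ct stability
#'
#' For every ordered gene pair (i, k) the per-sample difference
#' dCt_j = Ct_ij - Ct_kj is formed; the dispersion of a pair is the standard
#' deviation (n-1) of dCt over samples, and the stability value of gene i is
#' the arithmetic mean of its dispersions against all other genes. A lower
#' mean SD indicates more stable expression. Because only pairwise
#' differences enter, any per-sample loading shift common to all genes
#' cancels exactly — the method sees only relative instability.
#'
#' @param ct `ct_matrix` with at least 2 genes and 2 samples.
#' @return `stability_result` with `detail$pair_sd`, the symmetric matrix of
#'   pairwise dCt standard deviations (diagonal 0).
#' @export
delta_ct_stability <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  v <- ct$values
  if (nrow(v) < 2) stop("need >= 2 genes for the Delta Ct method", call. = FALSE)
  if (ncol(v) < 2) stop("need >= 2 samples for the Delta Ct method", call. = FALSE)
  g <- nrow(v)
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(g - 1)) {
    for (k in (i + 1):g) {
      s <- stats::sd(v[i, ] - v[k, ])
      pair_sd[i, k] <- s
      pair_sd[k, i] <- s
    }
  }
  values <- rowSums(pair_sd) / (g - 1)  # row mean excluding the diagonal
  new_stability_result("delta_ct", values, detail = list(pair_sd = pair_sd))
}

#' BestKeeper descriptive statistics
#'
#' Operates on raw Ct values (no relative-quantity transform). Per gene it
#' reports the arithmetic mean, minimum, maximum, a dispersion of Ct (sample
#' standard deviation by default, or the mean absolute deviation from the
#' mean — the convention of the original spreadsheet tool — with
#' `deviation = "mad"`), and CV = 100 * dispersion / mean. Genes are ranked
#' ascending by dispersion: the most stable gene has the smallest scatter of
#' raw Ct. Unlike the pairwise and log-ratio methods, a per-sample loading
#' shift common to all genes inflates every gene's dispersion — BestKeeper
#' measures absolute, not relative, variation.
#'
#' The BestKeeper index is the per-sample geometric mean of Ct across all
#' candidate genes; each gene is correlated (Pearson) against this index. A
#' zero-variance gene has no defined correlation and is reported as `NA`
#' with a warning.
#'
#' @param ct `ct_matrix` with at least 2 samples.
#' @param deviation `"sd"` (default) or `"mad"` (mean absolute deviation
#'   from the arithmetic mean).
#' @return `stability_result` whose `detail` is a list with `stats` (per-gene
#'   table: mean, min, max, dispersion, cv_percent, r, p_value) and `index`
#'   (named per-sample geometric mean Ct).
#' @export
bestkeeper_stats <- function(ct, deviation = c("sd", "mad")) {
  stopifnot(inherits(ct, "ct_matrix"))
  deviation <- match.arg(deviation)
  v <- ct$values
  if (ncol(v) < 2) stop("need >= 2 samples for BestKeeper", call. = FALSE)
  m <- rowMeans(v)
  disp <- switch(deviation,
    sd  = apply(v, 1, stats::sd),
    mad = rowMeans(abs(v - m)))
  index <- exp(colMeans(log(v)))  # geometric mean Ct per sample
  r <- p <- rep(NA_real_, nrow(v))
  const_index <- stats::sd(index) == 0
  for (i in seq_len(nrow(v))) {
    if (stats::sd(v[i, ]) == 0 || const_index) {
      warning("correlation with the BestKeeper index undefined for ",
              "zero-variance gene '", rownames(v)[i], "'", call. = FALSE)
      next
    }
    test <- stats::cor.test(v[i, ], index, method = "pearson")
    r[i] <- unname(test$estimate)
    p[i] <- test$p.value
  }
  stats_tab <- data.frame(
    gene_id = rownames(v),
    mean_ct = unname(m),
    min_ct = unname(apply(v, 1, min)),
    max_ct = unname(apply(v, 1, max)),
    dispersion = unname(disp),
    cv_percent = unname(100 * disp / m),
    r = r, p_value = p,
    stringsAsFactors = FALSE)
  values <- stats::setNames(disp, rownames(v))
  new_stability_result("bestkeeper", values,
                       detail = list(stats = stats_tab, index = index,
                                     deviation = deviation))
}
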