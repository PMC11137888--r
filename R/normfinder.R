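#' NormFinder model-based expression stability
#'
#' Decomposes the variation of each candidate gene into intra-group
#' (replicate scatter) and inter-group (systematic condition-dependent
#' shift) components and combines them into a single stability value; lower
#' values indicate more stable expression.
#'
#' The algorithm works on log-scale expression y = -Ct (Ct is already
#' logarithmic in template amount; the sign makes larger values mean more
#' template, and only variances and differences are used so the convention
#' does not affect results). With I genes, G groups of sizes n_g:
#' \enumerate{
#'   \item per sample, z_igj = y_igj - mean over genes (removes the shared
#'     sample loading effect);
#'   \item per (gene, group), s2_ig = sample variance (n-1) of z over the
#'     group's samples;
#'   \item bias-corrected intra-group variance
#'     sigma2_ig = max(0, (I/(I-2)) * (s2_ig - sum_i' s2_i'g / (I*(I-1))))
#'     — the correction removes the contamination introduced by subtracting
#'     the per-sample gene mean, and is unbiased for the true variance;
#'   \item with >= 2 groups, raw group difference
#'     d_ig = mean_g(z_ig) - mean over groups of those means (so
#'     sum over genes of d_ig = 0 within each group); the variance of true
#'     group differences is estimated as
#'     gamma2 = max(0, sum d2 / ((G-1)(I-1)) - mean(sigma2_ig / n_g)),
#'     and each d is shrunken toward zero:
#'     d~_ig = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g);
#'   \item stability rho_i = mean over groups of
#'     (|d~_ig| + sqrt(sigma2_ig / n_g)); with a single group,
#'     rho_i = sqrt(sigma2_i).
#' }
#'
#' @param ct `ct_matrix` with at least 3 genes (the variance correction
#'   divides by I-2).
#' @param groups optional named character vector sample -> group; defaults
#'   to the annotation stored in `ct`. Every group needs >= 2 samples.
#' @return `stability_result` whose `detail` (class `normfinder_detail`)
#'   holds `intragroup_var` (gene x group matrix of sigma2),
#'   `group_diff_raw` and `group_diff_shrunken` (gene x group matrices),
#'   `gamma_sq`, `group_sizes` and `groups_used`.
#' @export
normfinder_stability <- function(ct, groups = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (is.null(groups)) groups <- ct$groups
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", ncol(ct$values)), colnames(ct$values))
  }
  groups <- .check_groups(groups, colnames(ct$values))
  v <- ct$values
  I <- nrow(v)
  if (I < 3) stop("NormFinder needs >= 3 genes (variance correction divides by I-2)",
                  call. = FALSE)
  glev <- unique(unname(groups))
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2)) {
    stop("every group needs >= 2 samples; too small: ",
         paste(names(ng)[ng < 2], collapse = ", "), call. = FALSE)
  }
  G <- length(glev)

  y <- -v
  z <- sweep(y, 2, colMeans(y))  # remove per-sample loading effect

  s2 <- zbar <- matrix(NA_real_, I, G, dimnames = list(rownames(v), glev))
  for (g in glev) {
    zg <- z[, groups == g, drop = FALSE]
    s2[, g] <- apply(zg, 1, stats::var)
    zbar[, g] <- rowMeans(zg)
  }
  sigma2 <- pmax((I / (I - 2)) * sweep(s2, 2, colSums(s2) / (I * (I - 1))), 0)

  n_g <- as.numeric(ng)[match(glev, names(ng))]
  se2 <- sweep(sigma2, 2, n_g, "/")  # sigma2_ig / n_g

  if (G >= 2) {
    d <- zbar - rowMeans(zbar)
    gamma_sq <- max(0, sum(d^2) / ((G - 1) * (I - 1)) - mean(se2))
    d_shrunk <- d * gamma_sq / (gamma_sq + se2)
    if (gamma_sq == 0) d_shrunk[] <- 0  # 0/0 guard when se2 is also 0
    rho <- rowMeans(abs(d_shrunk) + sqrt(se2))
  } else {
    d <- d_shrunk <- matrix(0, I, 1, dimnames = list(rownames(v), glev))
    gamma_sq <- 0
    rho <- sqrt(sigma2[, 1])
  }
  detail <- structure(list(intragroup_var = sigma2,
                           group_diff_raw = d,
                           group_diff_shrunken = d_shrunk,
                           gamma_sq = gamma_sq,
                           group_sizes = stats::setNames(n_g, glev),
                           groups_used = glev),
                      class = "normfinder_detail")
  new_stability_result("normfinder", stats::setNames(rho, rownames(v)),
                       detail = detail)
}

#' Best pair of reference genes under the NormFinder model
#'
#' Candidate genes whose systematic group shifts point in opposite
#' directions partially cancel when averaged, so a pair can be more stable
#' than either member. The combined instability of genes (i, k) in group g
#' is |(d~_ig + d~_kg)/2| + sqrt((sigma2_ig + sigma2_kg) / (4 * n_g)) — the
#' shrunken bias of the pair average plus the standard error of the average
#' of the two genes' group means — and the pair score is its mean over
#' groups. The pair with the smallest score wins; ties are broken
#' lexicographically on the sorted pair.
#'
#' @param result `stability_result` from [normfinder_stability()] fitted
#'   with at least 2 groups.
#' @return list with `pair` (character vector of 2 gene ids, sorted) and
#'   `score`.
#' @export
normfinder_best_pair <- function(result) {
  stopifnot(inherits(result, "stability_result"),
            result$method == "normfinder")
  det <- result$detail
  if (length(det$groups_used) < 2) {
    stop("best-pair selection needs >= 2 groups", call. = FALSE)
  }
  genes <- rownames(det$intragroup_var)
  n_g <- det$group_sizes[det$groups_used]
  best <- NULL
  best_score <- Inf
  for (i in seq_len(length(genes) - 1)) {
    for (k in (i + 1):length(genes)) {
      bias <- abs(det$group_diff_shrunken[i, ] + det$group_diff_shrunken[k, ]) / 2
      se <- sqrt((det$intragroup_var[i, ] + det$intragroup_var[k, ]) / (4 * n_g))
      score <- mean(bias + se)
      pair <- sort(c(genes[i], genes[k]))
      better <- score < best_score ||
        (score == best_score && paste(pair, collapse = "\r") <
           paste(best, collapse = "\r"))
      if (better) {
        best <- pair
        best_score <- score
      }
    }
  }
  list(pair = best, score = best_score)
}
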