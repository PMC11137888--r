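#' Fit a qPCR standard curve and derive amplification efficiency
#'
#' Ordinary least-squares fit of Ct against log10 template concentration
#' over a dilution series. For an amplification factor E per cycle the
#' theoretical slope is -1/log10(E); inverting the fitted slope gives
#' E = 10^(-1/slope) and the efficiency in percent, (E - 1) * 100. A
#' perfectly doubling reaction has slope -3.32193 and efficiency 100%.
#'
#' @param log10_conc numeric vector of log10 template concentrations
#'   (arbitrary units; only differences matter).
#' @param ct numeric vector of Ct values, same length, >= 3 points.
#' @return object of class `efficiency_fit`: list with `slope`
#'   (cycles per log10 unit), `intercept` (cycles), `r_squared`,
#'   `amplification_factor`, `efficiency_percent`.
#' @export
fit_standard_curve <- function(log10_conc, ct) {
  stopifnot(is.numeric(log10_conc), is.numeric(ct),
            length(log10_conc) == length(ct))
  if (length(ct) < 3) stop("need >= 3 dilution points", call. = FALSE)
  fit <- stats::lm(ct ~ log10_conc)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid standard curve: slope must be negative (higher template",
         " -> lower Ct); got slope = ", format(slope), call. = FALSE)
  }
  factor <- 10 ^ (-1 / slope)
  # direct R^2 (summary.lm warns on noiseless series)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 amplification_factor = factor,
                 efficiency_percent = (factor - 1) * 100),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("standard curve: Ct = %.4f * log10(conc) + %.4f (R2 = %.5f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("amplification factor %.4f, efficiency %.1f%%\n",
              x$amplification_factor, x$efficiency_percent))
  invisible(x)
}

#' Per-sample normalization factor from a set of reference genes
#'
#' The geometric mean over the chosen reference genes of their relative
#' quantities (2^-dCt per gene). With a single reference gene the factor is
#' just that gene's quantity row.
#'
#' @param ct `ct_matrix` containing (at least) the reference genes.
#' @param rgs character vector of reference gene ids (>= 1).
#' @param efficiencies amplification factor(s) as in
#'   [to_relative_quantities()].
#' @return named numeric vector, one normalization factor per sample.
#' @export
normalization_factor <- function(ct, rgs, efficiencies = 2) {
  stopifnot(inherits(ct, "ct_matrix"), length(rgs) >= 1)
  unknown <- setdiff(rgs, rownames(ct$values))
  if (length(unknown) > 0) {
    stop("reference gene(s) not in matrix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sub <- ct_matrix(ct$values[rgs, , drop = FALSE], groups = ct$groups)
  q <- to_relative_quantities(sub, efficiencies)
  exp(colMeans(log(q$values)))
}

#' Relative expression of a target gene (2^-ddCt and Pfaffl-style)
#'
#' The target's Ct row is transformed to relative quantities with its own
#' amplification factor, divided per sample by the normalization factor of
#' the chosen reference genes, and expressed as fold change relative to a
#' calibrator sample set (whose aggregate fold is 1 by construction). With
#' all amplification factors at 2 this is the classic 2^-ddCt method; with
#' fitted per-gene factors it is the efficiency-corrected variant.
#'
#' @param target_ct named numeric vector of the target gene's Ct values
#'   (names = sample ids, matching `nf`).
#' @param nf named per-sample normalization factor from
#'   [normalization_factor()].
#' @param target_e amplification factor of the target assay (default 2).
#' @param calibrator character vector of sample ids forming the calibrator
#'   condition (non-empty subset of the samples).
#' @param calibrator_agg aggregation of the calibrator ratios:
#'   `"arithmetic"` mean (default) or `"geometric"`.
#' @return data frame of class `ddct_result` with columns `sample_id`,
#'   `target_q`, `nf`, `ratio`, `fold_change`; attribute `calibrator`.
#' @export
relative_expression <- function(target_ct, nf, target_e = 2, calibrator,
                                calibrator_agg = c("arithmetic", "geometric")) {
  calibrator_agg <- match.arg(calibrator_agg)
  stopifnot(is.numeric(target_ct), !is.null(names(target_ct)),
            is.numeric(nf), !is.null(names(nf)))
  if (!setequal(names(target_ct), names(nf))) {
    stop("target Ct and normalization factor cover different samples",
         call. = FALSE)
  }
  if (length(target_e) != 1 || target_e <= 1) {
    stop("target amplification factor must be a single value > 1", call. = FALSE)
  }
  nf <- nf[names(target_ct)]
  missing <- setdiff(calibrator, names(target_ct))
  if (length(calibrator) == 0 || length(missing) > 0) {
    stop("calibrator must be a non-empty subset of the samples; unknown: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  q <- target_e ^ (min(target_ct) - target_ct)
  ratio <- q / nf
  base <- switch(calibrator_agg,
                 arithmetic = mean(ratio[calibrator]),
                 geometric = exp(mean(log(ratio[calibrator]))))
  out <- data.frame(sample_id = names(target_ct),
                    target_q = unname(q), nf = unname(nf),
                    ratio = unname(ratio),
                    fold_change = unname(ratio / base),
                    stringsAsFactors = FALSE)
  attr(out, "calibrator") <- calibrator
  attr(out, "calibrator_agg") <- calibrator_agg
  class(out) <- c("ddct_result", class(out))
  out
}
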