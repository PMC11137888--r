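#' Run the full reference-gene validation workflow
#'
#' For each named analysis subset: quality check, the four stability
#' algorithms (Delta Ct, BestKeeper, geNorm, NormFinder), the comprehensive
#' geometric-mean ranking, the geNorm pairwise-variation series with the
#' optimal reference-gene count, and the recommended gene set. Optionally a
#' target gene is quantified (2^-ddCt) under three normalization strategies:
#' the recommended multi-gene set, the single best gene, and the least
#' stable gene — the standard check that an unstable normalizer distorts
#' the target's fold changes.
#'
#' The run is fully deterministic: identical inputs give identical outputs.
#'
#' @param ct `ct_matrix` with group labels (or pass `groups`).
#' @param subsets named list; each element is a character vector of group
#'   labels (or sample ids) defining one analysis set. Default: one subset
#'   `all` containing every sample.
#' @param groups optional sample -> group mapping overriding `ct$groups`.
#' @param efficiencies amplification factors for the relative-quantity
#'   transform (default 2 for every gene).
#' @param v_threshold geNorm pairwise-variation cutoff (default 0.15).
#' @param qc_bounds length-2 numeric, low/high Ct bounds (default 15, 30).
#' @param target optional target gene id (present in `ct`) to quantify.
#' @param calibrator calibrator group label or sample ids for the target
#'   quantification (required with `target`).
#' @param target_e amplification factor of the target assay (default 2).
#' @param out_dir optional directory; per-subset result tables and a JSON
#'   run summary are written via [write_report()].
#' @return list of class `rg_pipeline_result`, one element per subset, each
#'   holding `qc`, `stability` (list of 4 `stability_result`),
#'   `genorm` (`genorm_result`), `comprehensive`, `optimal_n`,
#'   `recommended`, and optionally `quantification` (list of `ddct_result`
#'   per strategy); plus attribute `parameters`.
#' @export
run_full_pipeline <- function(ct, subsets = NULL, groups = NULL,
                              efficiencies = 2, v_threshold = 0.15,
                              qc_bounds = c(15, 30), target = NULL,
                              calibrator = NULL, target_e = 2,
                              out_dir = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.null(groups)) ct <- ct_matrix(ct$values, groups = groups)
  if (is.null(subsets)) subsets <- list(all = colnames(ct$values))
  if (is.null(names(subsets)) || any(!nzchar(names(subsets)))) {
    stop("every subset needs a name", call. = FALSE)
  }
  if (!is.null(target) && is.null(calibrator)) {
    stop("target quantification needs a calibrator", call. = FALSE)
  }
  results <- list()
  for (label in names(subsets)) {
    sel <- subsets[[label]]
    by_group <- !is.null(ct$groups) && all(sel %in% ct$groups)
    sub <- tryCatch(
      if (by_group) subset_ct(ct, groups = sel) else subset_ct(ct, samples = sel),
      error = function(e) stop("subset '", label, "': ", conditionMessage(e),
                               call. = FALSE))
    analysis_genes <- setdiff(rownames(sub$values), target)
    stab_ct <- ct_matrix(sub$values[analysis_genes, , drop = FALSE],
                         groups = sub$groups)
    qc <- ct_quality_check(stab_ct, low = qc_bounds[1], high = qc_bounds[2])
    gen <- genorm_analysis(stab_ct, efficiencies = efficiencies,
                           v_threshold = v_threshold)
    stability <- list(
      delta_ct = delta_ct_stability(stab_ct),
      bestkeeper = bestkeeper_stats(stab_ct),
      genorm = gen$stability,
      normfinder = normfinder_stability(stab_ct))
    comp <- comprehensive_rank(stability)
    optimal_n <- gen$optimal_n
    recommended <- withCallingHandlers(
      recommend_rgs(comp, optimal_n),
      warning = function(w) invokeRestart("muffleWarning"))
    res <- list(qc = qc, stability = stability, genorm = gen,
                comprehensive = comp, optimal_n = optimal_n,
                recommended = recommended)
    if (!is.null(target)) {
      if (!target %in% rownames(sub$values)) {
        stop("subset '", label, "': target gene '", target,
             "' not in matrix", call. = FALSE)
      }
      calib <- if (!is.null(sub$groups) && all(calibrator %in% sub$groups)) {
        colnames(sub$values)[sub$groups %in% calibrator]
      } else calibrator
      least <- comp$gene_id[nrow(comp)]
      strategies <- list(multi_optimal = recommended,
                         single_best = comp$gene_id[1],
                         least_stable = least)
      res$quantification <- lapply(strategies, function(rgs) {
        nf <- normalization_factor(sub, rgs, efficiencies)
        relative_expression(sub$values[target, ], nf, target_e = target_e,
                            calibrator = calib)
      })
    }
    results[[label]] <- res
  }
  params <- list(subsets = subsets, v_threshold = v_threshold,
                 qc_bounds = qc_bounds, target = target,
                 calibrator = calibrator,
                 efficiencies = efficiencies)
  attr(results, "parameters") <- params
  class(results) <- "rg_pipeline_result"
  if (!is.null(out_dir)) {
    for (label in names(results)) {
      res <- results[[label]]
      tabs <- list(
        qc = res$qc,
        delta_ct = stability_table(res$stability$delta_ct),
        bestkeeper = res$stability$bestkeeper$detail$stats,
        genorm = stability_table(res$stability$genorm),
        normfinder = stability_table(res$stability$normfinder),
        comprehensive = as.data.frame(res$comprehensive),
        v_series = data.frame(n = as.integer(names(res$genorm$v_series)),
                              v = unname(res$genorm$v_series)))
      if (!is.null(res$quantification)) {
        for (s in names(res$quantification)) {
          tabs[[paste0("expression_", s)]] <-
            as.data.frame(res$quantification[[s]])
        }
      }
      write_report(tabs, file.path(out_dir, label),
                   params = c(params, list(subset = label,
                                           optimal_n = res$optimal_n,
                                           recommended = res$recommended)))
    }
  }
  results
}

#' Concordance of stability rankings between methods
#'
#' Pairwise Spearman rank correlations between the methods' rankings plus
#' the per-gene spread of ranks — a compact view of how much the four
#' algorithms disagree.
#'
#' @param results list of >= 2 `stability_result` objects on the same genes.
#' @return list with `spearman` (method x method correlation matrix) and
#'   `rank_range` (data frame: gene_id, min_rank, max_rank, range).
#' @export
compare_methods <- function(results) {
  stopifnot(is.list(results), length(results) >= 2)
  methods <- vapply(results, function(r) r$method, character(1))
  genes <- sort(names(results[[1]]$values))
  for (r in results[-1]) {
    if (!setequal(names(r$values), genes)) {
      stop("gene sets differ between methods", call. = FALSE)
    }
  }
  # correlate the underlying values' orderings (ties handled by cor)
  rank_mat <- vapply(results, function(r) rank(r$values[genes]),
                     numeric(length(genes)))
  colnames(rank_mat) <- methods
  rho <- stats::cor(rank_mat, method = "spearman")
  int_ranks <- vapply(results, function(r) as.numeric(r$ranks[genes]),
                      numeric(length(genes)))
  rr <- data.frame(gene_id = genes,
                   min_rank = apply(int_ranks, 1, min),
                   max_rank = apply(int_ranks, 1, max),
                   stringsAsFactors = FALSE)
  rr$range <- rr$max_rank - rr$min_rank
  list(spearman = rho, rank_range = rr)
}
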