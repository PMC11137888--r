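# synthetic qPCR / RNA-seq data with known ground truth

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration of a synthetic Ct dataset
#'
#' Encodes the generative model behind grouped qPCR experiments:
#' Ct_igj = baseline_i + shift_ig + b_gj + eps_igj, with a per-sample
#' loading effect b ~ N(0, tau^2) shared by all genes of a sample (pipetting
#' and input-amount variation), a designed gene-by-group shift (systematic
#' condition-dependent regulation — what makes a gene a poor reference), and
#' gene-specific noise eps ~ N(0, noise_sd_i^2) (assay scatter). All terms
#' are on the Ct (log2) scale, consistent with the log-linear PCR model.
#'
#' @param n_genes number of genes.
#' @param groups named integer vector: group label -> number of samples
#'   (>= 2 each).
#' @param baseline_ct per-gene baseline Ct in cycles (recycled).
#' @param sample_effect_sd tau, SD in cycles of the shared per-sample
#'   loading effect (>= 0).
#' @param group_shift gene x group matrix of shifts in cycles (0 = no
#'   regulation); a single 0 expands to the all-zero matrix.
#' @param noise_sd per-gene noise SD in cycles (recycled).
#' @param seed integer seed; mandatory, no global RNG state is consumed.
#' @param gene_ids optional gene labels (default g01, g02, ...).
#' @return validated list of class `synthetic_ct_config`.
#' @export
synthetic_ct_config <- function(n_genes, groups, baseline_ct = 24,
                                sample_effect_sd = 0.5, group_shift = 0,
                                noise_sd = 0.2, seed,
                                gene_ids = NULL) {
  stopifnot(n_genes >= 2, length(groups) >= 1, all(groups >= 2),
            !is.null(names(groups)), all(nzchar(names(groups))),
            sample_effect_sd >= 0, all(noise_sd >= 0),
            is.numeric(seed), length(seed) == 1)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  baseline_ct <- rep_len(baseline_ct, n_genes)
  noise_sd <- rep_len(noise_sd, n_genes)
  if (is.matrix(group_shift)) {
    stopifnot(nrow(group_shift) == n_genes,
              ncol(group_shift) == length(groups))
    dimnames(group_shift) <- list(gene_ids, names(groups))
  } else {
    stopifnot(length(group_shift) == 1)
    group_shift <- matrix(group_shift, n_genes, length(groups),
                          dimnames = list(gene_ids, names(groups)))
  }
  structure(list(n_genes = n_genes, groups = groups,
                 baseline_ct = stats::setNames(baseline_ct, gene_ids),
                 sample_effect_sd = sample_effect_sd,
                 group_shift = group_shift,
                 noise_sd = stats::setNames(noise_sd, gene_ids),
                 seed = as.integer(seed), gene_ids = gene_ids),
            class = "synthetic_ct_config")
}

#' Simulate a grouped Ct dataset with known ground truth
#'
#' Draws from the model described in [synthetic_ct_config()]. Regeneration
#' with the same config (including seed) is bit-identical. The returned
#' truth records the realized sample effects and a designed stability
#' ordering: genes sorted ascending by their total designed variation
#' sqrt(noise_sd^2 + population variance of the group shifts) — the
#' benchmark that recovery tests score the four algorithms against.
#'
#' @param config `synthetic_ct_config`.
#' @return list with `ct` (`ct_matrix` with group labels), `truth` (list:
#'   `designed_order`, `designed_score`, `sample_effects`, `config`).
#' @export
simulate_ct_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_ct_config"))
  glab <- rep(names(config$groups), times = config$groups)
  sample_ids <- paste0(glab, "_r",
                       unlist(lapply(config$groups, seq_len), use.names = FALSE))
  n <- length(sample_ids)
  I <- config$n_genes
  out <- with_seed(config$seed, {
    b <- stats::rnorm(n, 0, config$sample_effect_sd)
    eps <- matrix(stats::rnorm(I * n), I, n) * config$noise_sd
    list(b = b, eps = eps)
  })
  values <- config$baseline_ct + config$group_shift[, glab, drop = FALSE] +
    rep(out$b, each = I) + out$eps
  dimnames(values) <- list(config$gene_ids, sample_ids)
  shift_var <- apply(config$group_shift, 1, function(s) mean((s - mean(s))^2))
  score <- sqrt(config$noise_sd^2 + shift_var)
  ord <- config$gene_ids[order(score, config$gene_ids)]
  ct <- ct_matrix(values, groups = stats::setNames(glab, sample_ids))
  list(ct = ct,
       truth = list(designed_order = ord,
                    designed_score = score,
                    sample_effects = stats::setNames(out$b, sample_ids),
                    config = config))
}

#' Built-in synthetic scenario presets
#'
#' Ten-gene scenarios mirroring typical reference-gene validation designs:
#' \describe{
#'   \item{corm_growth}{3 growth-stage groups x 3 replicates.}
#'   \item{tissues}{4 tissue groups x 3 replicates.}
#'   \item{drought}{control vs drought x 3 replicates.}
#'   \item{all}{union of 9 condition groups (3 stages, 3 tissues, 3 drought
#'     conditions) x 3 replicates.}
#' }
#' Eight genes are stable (noise 0.2 cycles, no designed shifts), one
#' (`bTUB_like`) is systematically regulated across conditions (shifts up
#' to ~2 cycles, the classic unreliable structural-gene pattern), and one
#' (`EF1A_like`) has high assay scatter (noise 1.0 cycles). Baselines span
#' 18-28 cycles; the shared loading effect is tau = 0.5 cycles.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return `synthetic_ct_config`.
#' @export
synthetic_preset <- function(name = c("corm_growth", "tissues", "drought", "all"),
                             seed) {
  name <- match.arg(name)
  groups <- switch(name,
    corm_growth = c(stage1 = 3L, stage2 = 3L, stage3 = 3L),
    tissues = c(leaf = 3L, petiole = 3L, corm = 3L, root = 3L),
    drought = c(control = 3L, drought = 3L),
    all = c(stage1 = 3L, stage2 = 3L, stage3 = 3L,
            leaf = 3L, petiole = 3L, root = 3L,
            drought_corm = 3L, drought_leaf = 3L, drought_root = 3L))
  ids <- c(sprintf("hk%02d", 1:8), "bTUB_like", "EF1A_like")
  ng <- length(groups)
  shift <- matrix(0, 10, ng)
  # regulated gene: monotone drift across conditions, ~2 cycles end to end
  shift[9, ] <- seq(-1, 1, length.out = ng) * 2 * (ng - 1) / ng
  noise <- c(rep(0.2, 8), 0.3, 1.0)
  synthetic_ct_config(
    n_genes = 10, groups = groups,
    baseline_ct = c(26, 21, 24, 23, 25, 22, 27, 20, 28, 18),
    sample_effect_sd = 0.5, group_shift = shift, noise_sd = noise,
    seed = seed, gene_ids = ids)
}

#' Simulate an FPKM matrix with designed screening outcomes
#'
#' Per gene, samples are drawn log-normally with parameters chosen so the
#' distribution's mean and CV match the targets: sdlog^2 = log(1 + cv^2),
#' meanlog = log(mean) - sdlog^2 / 2. A CV target of 0 produces a constant
#' gene. The truth records which genes were designed to pass the default
#' screen (mean >= `min_mf`, CV <= `max_cv`).
#'
#' @param n_genes,n_samples dimensions.
#' @param mean_targets per-gene target mean FPKM (recycled).
#' @param cv_targets per-gene target CV in percent (recycled).
#' @param seed integer seed.
#' @param min_mf,max_cv screen thresholds recorded in the truth
#'   (defaults 10 and 20).
#' @return list with `fpkm` (`fpkm_matrix`) and `truth` (data frame:
#'   `gene_id`, `mean_target`, `cv_target`, `designed_pass`).
#' @export
simulate_fpkm_dataset <- function(n_genes, n_samples, mean_targets, cv_targets,
                                  seed, min_mf = 10, max_cv = 20) {
  stopifnot(n_genes >= 1, n_samples >= 2,
            all(mean_targets > 0), all(cv_targets >= 0))
  mean_targets <- rep_len(mean_targets, n_genes)
  cv_targets <- rep_len(cv_targets, n_genes)
  ids <- sprintf("gene%03d", seq_len(n_genes))
  sdlog <- sqrt(log(1 + (cv_targets / 100)^2))
  meanlog <- log(mean_targets) - sdlog^2 / 2
  values <- with_seed(seed, {
    t(vapply(seq_len(n_genes), function(i) {
      if (sdlog[i] == 0) rep(mean_targets[i], n_samples)
      else stats::rlnorm(n_samples, meanlog[i], sdlog[i])
    }, numeric(n_samples)))
  })
  dimnames(values) <- list(ids, sprintf("s%02d", seq_len(n_samples)))
  truth <- data.frame(gene_id = ids, mean_target = mean_targets,
                      cv_target = cv_targets,
                      designed_pass = mean_targets >= min_mf &
                        cv_targets <= max_cv,
                      stringsAsFactors = FALSE)
  list(fpkm = fpkm_matrix(values), truth = truth)
}

#' Simulate a qPCR dilution series
#'
#' A serial dilution starting at log10 concentration 0 and descending in
#' steps of `step_log10`, with Ct following the log-linear model
#' Ct = intercept - log10(conc) / log10(factor) + N(0, noise_sd^2).
#' With zero noise, [fit_standard_curve()] inverts the series exactly.
#'
#' @param amplification_factor per-cycle amplification (> 1; 2 = perfect
#'   doubling).
#' @param intercept Ct at log10(conc) = 0 (default 20 cycles).
#' @param n_points number of dilution points (>= 3, default 5).
#' @param step_log10 dilution step in log10 units (default 1 = 10-fold).
#' @param noise_sd Ct noise SD in cycles (default 0).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return data frame with columns `log10_conc`, `ct`.
#' @export
simulate_dilution_series <- function(amplification_factor = 2, intercept = 20,
                                     n_points = 5, step_log10 = 1,
                                     noise_sd = 0, seed = NULL) {
  stopifnot(amplification_factor > 1, n_points >= 3, step_log10 > 0,
            noise_sd >= 0)
  log10_conc <- -(seq_len(n_points) - 1) * step_log10
  ct <- intercept - log10_conc / log10(amplification_factor)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0", call. = FALSE)
    ct <- ct + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  }
  data.frame(log10_conc = log10_conc, ct = ct)
}
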