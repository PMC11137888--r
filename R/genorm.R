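#' Transform Ct values to relative quantities (2^-dCt)
#'
#' Q_ij = E_i^(minCt_i - Ct_ij), where minCt_i is that gene's minimum Ct
#' within the analyzed sample set and E_i its amplification factor (2 for a
#' perfectly doubling reaction). Every gene's maximum quantity is exactly 1,
#' attained at its minimum-Ct sample, and all quantities lie in (0, 1].
#'
#' The per-gene (not global) minimum is used so that each gene is expressed
#' relative to its own most-abundant sample; subset analyses therefore take
#' the minimum within the subset and are self-contained.
#'
#' @param ct `ct_matrix`.
#' @param efficiencies amplification factor(s) > 1: a single number applied
#'   to every gene (default 2) or a vector named by gene id.
#' @return object of class `rq_matrix`: list with `values` (genes x samples
#'   matrix of quantities) and `groups` carried over from `ct`.
#' @export
to_relative_quantities <- function(ct, efficiencies = 2) {
  stopifnot(inherits(ct, "ct_matrix"))
  e <- .expand_efficiencies(efficiencies, rownames(ct$values))
  mins <- apply(ct$values, 1, min)
  q <- e ^ (mins - ct$values)  # column-recycled per-gene vector
  structure(list(values = q, groups = ct$groups), class = "rq_matrix")
}

.expand_efficiencies <- function(efficiencies, gene_ids) {
  if (length(efficiencies) == 1 && is.null(names(efficiencies))) {
    efficiencies <- stats::setNames(rep(efficiencies, length(gene_ids)), gene_ids)
  }
  missing <- setdiff(gene_ids, names(efficiencies))
  if (length(missing) > 0) {
    stop("no amplification factor for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  e <- efficiencies[gene_ids]
  if (any(e <= 1)) {
    stop("amplification factors must exceed 1 (got ",
         paste(round(e[e <= 1], 3), collapse = ", "), ")", call. = FALSE)
  }
  e
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat("rq_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' geNorm expression-stability measure M
#'
#' For genes j and k, V_jk is the standard deviation (n-1) over samples of
#' log2(Q_j / Q_k); M_j is the arithmetic mean of V_jk over all partners
#' k != j. Two perfectly proportional genes have V = 0; a lower M indicates
#' more stable expression. Because only log ratios enter, M is invariant to
#' rescaling any sample (all genes) or any gene (all samples).
#'
#' @param q `rq_matrix` with at least 2 genes and 2 samples.
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(q) {
  stopifnot(inherits(q, "rq_matrix"))
  v <- q$values
  if (nrow(v) < 2) stop("need >= 2 genes to compute M", call. = FALSE)
  if (ncol(v) < 2) stop("need >= 2 samples to compute M", call. = FALSE)
  l <- log2(v)
  g <- nrow(v)
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(g - 1)) {
    for (k in (i + 1):g) {
      s <- stats::sd(l[i, ] - l[k, ])
      pair_sd[i, k] <- s
      pair_sd[k, i] <- s
    }
  }
  stats::setNames(rowSums(pair_sd) / (g - 1), rownames(v))
}

#' geNorm iterative stability ranking
#'
#' Repeatedly computes M on the remaining genes and removes the gene with
#' the highest M, until two genes remain; those two cannot be distinguished
#' by the procedure and are jointly the most stable pair (both get rank 1;
#' the next gene has rank 3). The exclusion order defines ranks G, G-1, ...,
#' 3. A tie at the maximal M is broken by removing the lexicographically
#' larger gene id (recorded in the trace).
#'
#' @param q `rq_matrix` with at least 3 genes.
#' @return object of class `genorm_result`: list with
#'   \describe{
#'     \item{ranking}{gene ids ordered most to least stable (final pair
#'       first, in ascending final-round M then gene id).}
#'     \item{ranks}{named integer ranks, final pair tied at 1.}
#'     \item{m_values}{per gene, the M value in the round where it was
#'       excluded (final pair: last-round M).}
#'     \item{first_round_m}{M of every gene before any exclusion.}
#'     \item{exclusion_trace}{data frame (round, gene_id, m, excluded).}
#'   }
#' @export
genorm_rank <- function(q) {
  stopifnot(inherits(q, "rq_matrix"))
  if (nrow(q$values) < 3) stop("need >= 3 genes for iterative geNorm ranking",
                               call. = FALSE)
  remaining <- q
  first_round_m <- genorm_m(q)
  m_at_exclusion <- stats::setNames(numeric(0), character(0))
  trace <- list()
  excluded <- character(0)
  round <- 1L
  repeat {
    m <- genorm_m(remaining)
    worst <- names(m)[m == max(m)]
    worst <- sort(worst, decreasing = TRUE)[1]  # lexicographically larger out
    trace[[round]] <- data.frame(round = round, gene_id = names(m),
                                 m = unname(m),
                                 excluded = names(m) == worst,
                                 stringsAsFactors = FALSE)
    if (length(m) == 2) {
      # final pair: both retained, jointly most stable
      trace[[round]]$excluded <- FALSE
      m_at_exclusion[names(m)] <- m
      # the two remaining genes always share the same M; order by id
      final_pair <- names(m)[order(m, names(m))]
      break
    }
    m_at_exclusion[worst] <- m[worst]
    excluded <- c(worst, excluded)  # most recently excluded = more stable
    keep <- setdiff(rownames(remaining$values), worst)
    remaining <- structure(list(values = remaining$values[keep, , drop = FALSE],
                                groups = remaining$groups), class = "rq_matrix")
    round <- round + 1L
  }
  ranking <- c(final_pair, excluded)
  ranks <- stats::setNames(c(1L, 1L, seq_along(excluded) + 2L), ranking)
  structure(list(ranking = ranking,
                 ranks = ranks[rownames(q$values)],
                 m_values = m_at_exclusion[rownames(q$values)],
                 first_round_m = first_round_m,
                 exclusion_trace = do.call(rbind, trace)),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("genorm_result:", length(x$ranking), "genes; ranking (stable first):\n ",
      paste(x$ranking, collapse = " > "), "\n")
  if (!is.null(x$v_series)) {
    cat("pairwise variation:",
        paste0("V", names(x$v_series), "/", as.integer(names(x$v_series)) + 1,
               "=", round(x$v_series, 3), collapse = ", "), "\n")
    cat("optimal number of reference genes:",
        if (is.na(x$optimal_n)) "undetermined" else x$optimal_n, "\n")
  }
  invisible(x)
}

#' geNorm pairwise variation V(n/n+1) of consecutive normalization factors
#'
#' NF_n is the per-sample geometric mean of the quantities of the n
#' top-ranked genes; V(n/n+1) is the standard deviation (n-1) over samples
#' of log2(NF_n / NF_{n+1}). A small V means adding the (n+1)-th gene hardly
#' changes the normalization factor, so n genes suffice.
#'
#' @param q `rq_matrix`.
#' @param ranking character vector of gene ids, most stable first (from
#'   [genorm_rank()]; must come from the same sample subset).
#' @return named numeric vector; element `"n"` holds V(n/n+1), n = 2..G-1.
#' @export
genorm_v_series <- function(q, ranking) {
  stopifnot(inherits(q, "rq_matrix"))
  v <- q$values
  if (!setequal(ranking, rownames(v)) || length(ranking) != nrow(v)) {
    stop("ranking must be a permutation of the matrix's gene ids", call. = FALSE)
  }
  g <- length(ranking)
  if (g < 3) stop("need >= 3 genes for a V series", call. = FALSE)
  l <- log2(v)[ranking, , drop = FALSE]
  out <- stats::setNames(numeric(g - 2), as.character(2:(g - 1)))
  for (n in 2:(g - 1)) {
    log_nf_n  <- colMeans(l[seq_len(n), , drop = FALSE])
    log_nf_n1 <- colMeans(l[seq_len(n + 1), , drop = FALSE])
    out[as.character(n)] <- stats::sd(log_nf_n - log_nf_n1)
  }
  out
}

#' Optimal number of reference genes from a V series
#'
#' The smallest n whose pairwise variation V(n/n+1) falls below the
#' threshold (0.15 by convention). When no n qualifies the count is
#' undetermined (`NA`), and using all candidate genes is recommended.
#'
#' @param v_series named vector from [genorm_v_series()].
#' @param threshold cutoff on V (default 0.15); strictly-below comparison.
#' @return integer, or `NA_integer_` when undetermined.
#' @export
optimal_rg_count <- function(v_series, threshold = 0.15) {
  stopifnot(length(v_series) > 0, threshold > 0)
  n <- as.integer(names(v_series))
  ok <- n[v_series < threshold]
  if (length(ok) == 0) NA_integer_ else min(ok)
}

#' Full geNorm analysis of a Ct matrix
#'
#' Convenience wrapper: relative quantities, iterative ranking, V series and
#' optimal reference-gene count in one call, plus a `stability_result` for
#' downstream comprehensive ranking.
#'
#' @inheritParams to_relative_quantities
#' @param v_threshold cutoff for [optimal_rg_count()] (default 0.15).
#' @return `genorm_result` with extra elements `v_series`, `optimal_n`, and
#'   `stability` (a `stability_result` whose values are the per-gene M at
#'   exclusion and whose ranks follow the tied-pair convention).
#' @export
genorm_analysis <- function(ct, efficiencies = 2, v_threshold = 0.15) {
  q <- to_relative_quantities(ct, efficiencies)
  res <- genorm_rank(q)
  res$v_series <- genorm_v_series(q, res$ranking)
  res$optimal_n <- optimal_rg_count(res$v_series, v_threshold)
  res$stability <- new_stability_result("genorm", res$m_values,
                                        detail = res["exclusion_trace"],
                                        ranks = res$ranks)
  res
}
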