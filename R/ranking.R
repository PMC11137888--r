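#' Comprehensive ranking by geometric mean of per-method ranks
#'
#' Aggregates the integer rankings of several stability methods into one
#' consensus ordering: the geometric mean of a gene's ranks across methods
#' (the RefFinder recipe), with the final ranking ascending in that
#' geometric mean and ties broken by gene id. Within-method ties carry the
#' shared minimum rank into the product; all methods are weighted equally.
#'
#' geNorm contributes its iterative-exclusion ranking with the final pair
#' tied at rank 1 (entered as 1 and 1, next gene 3), mirroring the classic
#' tool's output; `genorm_pair = "sequential"` re-labels the pair 1 and 2
#' (ordered by final-round M, then gene id) instead.
#'
#' @param results list of `stability_result` objects (>= 2) over identical
#'   gene sets; names are taken from each result's `method`.
#' @param genorm_pair `"tied"` (default) or `"sequential"`.
#' @return data frame of class `comprehensive_ranking`: one row per gene
#'   with one `rank_<method>` column per input, `geomean`, and `final_rank`;
#'   rows sorted by final rank.
#' @export
comprehensive_rank <- function(results, genorm_pair = c("tied", "sequential")) {
  genorm_pair <- match.arg(genorm_pair)
  stopifnot(is.list(results), length(results) >= 2)
  methods <- vapply(results, function(r) {
    stopifnot(inherits(r, "stability_result"))
    r$method
  }, character(1))
  if (anyDuplicated(methods)) {
    stop("duplicate methods in 'results': ",
         paste(methods[duplicated(methods)], collapse = ", "), call. = FALSE)
  }
  genes <- sort(names(results[[1]]$values))
  for (r in results[-1]) {
    if (!setequal(names(r$values), genes)) {
      off <- c(setdiff(names(r$values), genes), setdiff(genes, names(r$values)))
      stop("gene sets differ between methods; offending genes: ",
           paste(unique(off), collapse = ", "), call. = FALSE)
    }
  }
  rank_mat <- vapply(results, function(r) {
    rk <- r$ranks
    if (r$method == "genorm" && genorm_pair == "sequential") {
      pair <- names(rk)[rk == 1L]
      pair <- pair[order(r$values[pair], pair)]
      rk[pair] <- c(1L, 2L)
    }
    as.numeric(rk[genes])
  }, numeric(length(genes)))
  rank_mat <- matrix(rank_mat, nrow = length(genes),
                     dimnames = list(genes, paste0("rank_", methods)))
  geomean <- exp(rowMeans(log(rank_mat)))
  ord <- order(geomean, genes)
  out <- data.frame(gene_id = genes, rank_mat, geomean = unname(geomean),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- rank(out$geomean, ties.method = "min")
  rownames(out) <- NULL
  attr(out, "methods_included") <- unname(methods)
  class(out) <- c("comprehensive_ranking", class(out))
  out
}

#' Recommended reference-gene set
#'
#' The top `optimal_n` genes of the comprehensive ranking, where
#' `optimal_n` normally comes from the geNorm pairwise-variation analysis.
#' When the optimal count is undetermined (`NA`), the full ranking is
#' returned with a warning — the V analysis could not justify stopping at
#' any subset.
#'
#' @param ranking `comprehensive_ranking` from [comprehensive_rank()].
#' @param optimal_n integer number of genes, or `NA`.
#' @return character vector of gene ids, most stable first.
#' @export
recommend_rgs <- function(ranking, optimal_n) {
  stopifnot(inherits(ranking, "comprehensive_ranking"))
  genes <- ranking$gene_id
  if (is.na(optimal_n)) {
    warning("optimal reference-gene count undetermined; returning all ",
            length(genes), " genes", call. = FALSE)
    return(genes)
  }
  optimal_n <- as.integer(optimal_n)
  stopifnot(optimal_n >= 1, optimal_n <= length(genes))
  genes[seq_len(optimal_n)]
}
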