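# shared result container for the four stability algorithms

#' Construct a stability result
#'
#' Internal constructor shared by the four algorithms. Ranks are assigned
#' ascending in the stability value (lower = more stable for every method);
#' ties share the minimum rank, which is what the geometric-mean aggregation
#' downstream consumes.
#'
#' @param method one of `delta_ct`, `bestkeeper`, `genorm`, `normfinder`.
#' @param values named numeric vector of stability values, one per gene.
#' @param detail method-specific table or list.
#' @param ranks optional named integer ranks; computed from `values` when
#'   omitted (methods with their own ranking convention pass them in).
#' @return object of class `stability_result` with elements `method`,
#'   `values`, `ranks`, `detail`.
#' @keywords internal
new_stability_result <- function(method, values, detail = NULL, ranks = NULL) {
  stopifnot(method %in% c("delta_ct", "bestkeeper", "genorm", "normfinder"))
  if (is.null(ranks)) ranks <- rank_stability(values)
  structure(list(method = method, values = values, ranks = ranks,
                 detail = detail),
            class = "stability_result")
}

#' Rank stability values ascending, ties sharing the minimum rank
#'
#' @param values named numeric vector; lower = more stable.
#' @return named integer vector of ranks in the same order.
#' @export
rank_stability <- function(values) {
  r <- rank(values, ties.method = "min")
  stats::setNames(as.integer(r), names(values))
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result (", x$method, ")\n", sep = "")
  ord <- order(x$ranks, names(x$values))
  print(data.frame(gene_id = names(x$values)[ord],
                   value = round(unname(x$values[ord]), 4),
                   rank = unname(x$ranks[ord])), row.names = FALSE)
  invisible(x)
}

#' Tidy a stability result into a ranking table
#'
#' @param result `stability_result`.
#' @return data frame with columns `gene_id`, `value`, `rank`, sorted by
#'   rank then gene id.
#' @export
stability_table <- function(result) {
  stopifnot(inherits(result, "stability_result"))
  ord <- order(result$ranks, names(result$values))
  data.frame(gene_id = names(result$values)[ord],
             value = unname(result$values[ord]),
             rank = unname(result$ranks[ord]),
             stringsAsFactors = FALSE)
}
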