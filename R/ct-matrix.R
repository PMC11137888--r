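#' Construct a Ct matrix
#'
#' The central container for all stability analyses: a genes-by-samples
#' matrix of RT-qPCR cycle-threshold (Ct) values with an optional mapping
#' from sample to experimental group (growth stage, tissue, treatment, ...).
#'
#' Ct values are logarithmic in template amount (one cycle difference is one
#' doubling at 100% amplification efficiency), so all downstream methods
#' treat them as log-scale data. Missing or non-finite Ct values are
#' rejected rather than imputed: none of the stability algorithms defines
#' missing-data handling, so we fail fast with the offending cells named.
#'
#' @param values numeric matrix, rows = genes, columns = samples, with
#'   dimnames; all entries finite and strictly positive (PCR cycles).
#' @param groups optional character vector mapping samples to group labels,
#'   either named by sample id or in column order.
#' @return object of class `ct_matrix`: list with elements `values` and
#'   `groups` (named character or `NULL`).
#' @export
ct_matrix <- function(values, groups = NULL) {
  values <- .check_expr_matrix(values, what = "Ct")
  bad <- which(!(values > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive Ct value for gene '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "'", call. = FALSE)
  }
  groups <- .check_groups(groups, colnames(values))
  structure(list(values = values, groups = groups), class = "ct_matrix")
}

#' Construct an FPKM matrix
#'
#' Genes-by-samples matrix of RNA-seq expression values (fragments per
#' kilobase of transcript per million mapped reads), the input to
#' transcriptome-based candidate screening. Values must be non-negative.
#'
#' @param values numeric matrix with dimnames, rows = genes.
#' @return object of class `fpkm_matrix`.
#' @export
fpkm_matrix <- function(values) {
  values <- .check_expr_matrix(values, what = "FPKM")
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative FPKM value for gene '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "'", call. = FALSE)
  }
  structure(list(values = values), class = "fpkm_matrix")
}

# shared matrix validation: numeric, finite, complete, unique dimnames
.check_expr_matrix <- function(values, what) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(what, " values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop(what, " matrix needs gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  nf <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(nf) > 0) {
    stop("missing or non-numeric ", what, " value for gene '",
         rownames(values)[nf[1, 1]], "', sample '",
         colnames(values)[nf[1, 2]], "'", call. = FALSE)
  }
  storage.mode(values) <- "double"
  values
}

.check_groups <- function(groups, sample_ids) {
  if (is.null(groups)) return(NULL)
  nm <- if (is.null(names(groups))) sample_ids[seq_along(groups)] else names(groups)
  groups <- stats::setNames(as.character(groups), nm)
  if (!setequal(names(groups), sample_ids) || length(groups) != length(sample_ids)) {
    missing <- setdiff(sample_ids, names(groups))
    stop("every sample needs exactly one group label; unlabeled: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups[sample_ids]
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("ct_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste0(names(tab), " (n=", tab, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat("fpkm_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' @export
dim.fpkm_matrix <- function(x) dim(x$values)

#' Restrict a Ct matrix to a subset of samples or groups
#'
#' Subset analyses (e.g. one growth-stage series out of a larger run) must be
#' self-contained: per-gene minima, SDs and group means are computed within
#' the subset only, so restricting first is the supported route.
#'
#' @param ct `ct_matrix`.
#' @param samples character vector of sample ids to keep, or `NULL`.
#' @param groups character vector of group labels to keep (requires group
#'   annotation), or `NULL`. `samples` and `groups` are combined with OR.
#' @return `ct_matrix` restricted to the selected samples.
#' @export
subset_ct <- function(ct, samples = NULL, groups = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  ids <- colnames(ct$values)
  keep <- rep(FALSE, length(ids))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, ids)
    if (length(unknown) > 0) {
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    keep <- keep | ids %in% samples
  }
  if (!is.null(groups)) {
    if (is.null(ct$groups)) stop("ct_matrix has no group labels", call. = FALSE)
    unknown <- setdiff(groups, unique(ct$groups))
    if (length(unknown) > 0) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    keep <- keep | ct$groups[ids] %in% groups
  }
  if (is.null(samples) && is.null(groups)) keep[] <- TRUE
  if (!any(keep)) stop("subset selects no samples", call. = FALSE)
  ct_matrix(ct$values[, keep, drop = FALSE],
            groups = if (!is.null(ct$groups)) ct$groups[ids[keep]])
}

#' Average technical replicates to one Ct per gene and sample
#'
#' All stability algorithms operate on one Ct value per (gene, sample);
#' technical replicates of the same biological sample are collapsed by their
#' arithmetic mean on the Ct scale.
#'
#' @param ct `ct_matrix` whose columns are technical replicates.
#' @param replicate_of character vector, named by replicate sample id, giving
#'   the biological sample each replicate belongs to.
#' @return `ct_matrix` with one column per biological sample (group label of
#'   a biological sample is taken from its first replicate).
#' @export
average_replicates <- function(ct, replicate_of) {
  stopifnot(inherits(ct, "ct_matrix"))
  ids <- colnames(ct$values)
  if (is.null(names(replicate_of)) || !setequal(names(replicate_of), ids)) {
    stop("'replicate_of' must be named by every sample id", call. = FALSE)
  }
  replicate_of <- as.character(replicate_of[ids]) |> stats::setNames(ids)
  bio <- unique(replicate_of)
  vals <- vapply(bio, function(b) {
    rowMeans(ct$values[, replicate_of == b, drop = FALSE])
  }, numeric(nrow(ct$values)))
  vals <- matrix(vals, nrow = nrow(ct$values),
                 dimnames = list(rownames(ct$values), bio))
  grp <- NULL
  if (!is.null(ct$groups)) {
    grp <- vapply(bio, function(b) ct$groups[ids[replicate_of == b][1]],
                  character(1))
  }
  ct_matrix(vals, groups = grp)
}

#' Read a wide Ct table from delimited text
#'
#' Default dialect: tab-separated, genes in rows, first column = gene id,
#' header row of sample ids. A comma separator is auto-detected from the
#' first line. Group labels can be supplied as a second header row (a line of
#' non-numeric labels directly under the sample header) or as a sample sheet
#' with columns `sample_id` and `group`.
#'
#' @param path file path of the delimited table.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_cols"`.
#' @param sample_sheet optional path of a TSV/CSV sample sheet
#'   (columns `sample_id`, `group`).
#' @param sep field separator; `NULL` (default) sniffs tab vs comma.
#' @return validated `ct_matrix`.
#' @export
read_ct_table <- function(path, orientation = c("genes_in_rows", "genes_in_cols"),
                          sample_sheet = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  parsed <- .read_wide(path, sep)
  values <- parsed$values
  if (orientation == "genes_in_cols") {
    values <- t(values)
    parsed$groups <- NULL  # group row only meaningful for samples in columns
  }
  groups <- parsed$groups
  if (!is.null(sample_sheet)) groups <- .read_sample_sheet(sample_sheet)
  if (!is.null(groups)) groups <- groups[colnames(values)]
  ct_matrix(values, groups = groups)
}

#' Read a wide FPKM table (genes in rows) from delimited text
#'
#' @inheritParams read_ct_table
#' @return validated `fpkm_matrix`.
#' @export
read_fpkm_table <- function(path, sep = NULL) {
  parsed <- .read_wide(path, sep)
  fpkm_matrix(parsed$values)
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

.read_wide <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .sniff_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("malformed table (need an id column plus data columns): ", path,
         call. = FALSE)
  }
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  groups <- NULL
  # optional second header row: all-non-numeric line under the sample header
  first_row <- suppressWarnings(as.numeric(unlist(body[1, ])))
  if (nrow(raw) > 1 && all(is.na(first_row))) {
    groups <- stats::setNames(as.character(unlist(body[1, ])), colnames(body))
    ids <- ids[-1]
    body <- body[-1, , drop = FALSE]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = length(ids),
           dimnames = list(ids, colnames(body))))
  nf <- which(is.na(num), arr.ind = TRUE)
  if (nrow(nf) > 0) {
    stop("non-numeric or missing value for gene '", ids[nf[1, 1]],
         "', sample '", colnames(body)[nf[1, 2]], "' in ", path,
         call. = FALSE)
  }
  list(values = num, groups = groups)
}

.read_sample_sheet <- function(path) {
  sep <- .sniff_sep(path)
  sheet <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(sheet))) {
    stop("sample sheet must have columns 'sample_id' and 'group'",
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  stats::setNames(as.character(sheet$group), sheet$sample_id)
}

#' Write a Ct matrix as a tab-separated table
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-identically. An optional group row
#' is written directly under the sample header.
#'
#' @param ct `ct_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  stopifnot(inherits(ct, "ct_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(ct$values)), collapse = "\t"), con)
  if (!is.null(ct$groups)) {
    writeLines(paste(c("group", ct$groups[colnames(ct$values)]),
                     collapse = "\t"), con)
  }
  body <- apply(ct$values, 1:2, function(v) sprintf("%.17g", v))
  writeLines(paste(rownames(ct$values),
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Advisory quality check of per-gene mean Ct
#'
#' Mean Ct outside the conventional working window marks a gene as expressed
#' too highly (mean at or under `low` cycles: quantification may saturate) or
#' too weakly (mean at or over `high` cycles: stochastic late-cycle noise).
#' Flags are advisory; no gene is removed.
#'
#' @param ct `ct_matrix`.
#' @param low lower Ct bound in cycles (default 15; flag `low_ct` iff
#'   mean Ct <= `low`).
#' @param high upper Ct bound in cycles (default 30; flag `high_ct` iff
#'   mean Ct >= `high`).
#' @return data frame of class `qc_report` with columns `gene_id`, `mean_ct`,
#'   `flag` (`ok`, `low_ct` or `high_ct`).
#' @export
ct_quality_check <- function(ct, low = 15, high = 30) {
  stopifnot(inherits(ct, "ct_matrix"), low < high)
  m <- rowMeans(ct$values)
  flag <- ifelse(m >= high, "high_ct", ifelse(m <= low, "low_ct", "ok"))
  out <- data.frame(gene_id = rownames(ct$values), mean_ct = unname(m),
                    flag = unname(flag), stringsAsFactors = FALSE)
  class(out) <- c("qc_report", class(out))
  out
}

#' Write a collection of labeled result tables plus a run summary
#'
#' One TSV per table (deterministic column order as given) and a JSON
#' summary recording labels, dimensions, parameters and package version.
#'
#' @param tables named list of data frames; names become file stems.
#' @param dir output directory, created if needed.
#' @param params optional named list recorded verbatim in the summary.
#' @return character vector of written file paths, invisibly.
#' @export
write_report <- function(tables, dir, params = list()) {
  if (length(tables) > 0 && (is.null(names(tables)) || any(names(tables) == "")))
    stop("every table needs a label", call. = FALSE)
  if (anyDuplicated(names(tables))) {
    stop("duplicate table labels: ",
         paste(unique(names(tables)[duplicated(names(tables))]), collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- character(0)
  for (label in names(tables)) {
    stopifnot(is.data.frame(tables[[label]]))
    p <- file.path(dir, paste0(label, ".tsv"))
    utils::write.table(tables[[label]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  summary <- list(
    package = "rgstab",
    version = as.character(utils::packageVersion("rgstab")),
    tables = lapply(tables, function(t) list(rows = nrow(t), columns = names(t))),
    parameters = params)
  sp <- file.path(dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, sp))
}
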