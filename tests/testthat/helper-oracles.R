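# naive, loop-based reference implementations used as independent oracles;
# deliberately written without reusing any package internals

sd1 <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

oracle_delta_ct <- function(v) {
  g <- nrow(v)
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k == i) next
      sds <- c(sds, sd1(v[i, ] - v[k, ]))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(v)
  out
}

oracle_genorm_m <- function(qv) {
  g <- nrow(qv)
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k == i) next
      sds <- c(sds, sd1(log2(qv[i, ] / qv[k, ])))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(qv)
  out
}

# naive iterative exclusion; same tie-break (drop lexicographically larger id)
oracle_genorm_exclusion_order <- function(qv) {
  dropped <- character(0)
  while (nrow(qv) > 2) {
    m <- oracle_genorm_m(qv)
    worst <- sort(names(m)[m == max(m)], decreasing = TRUE)[1]
    dropped <- c(dropped, worst)
    qv <- qv[setdiff(rownames(qv), worst), , drop = FALSE]
  }
  dropped
}

oracle_v_series <- function(qv, ranking) {
  g <- length(ranking)
  out <- numeric(g - 2)
  for (n in 2:(g - 1)) {
    nf_n <- apply(qv[ranking[1:n], , drop = FALSE], 2,
                  function(x) prod(x)^(1 / length(x)))
    nf_n1 <- apply(qv[ranking[1:(n + 1)], , drop = FALSE], 2,
                   function(x) prod(x)^(1 / length(x)))
    out[n - 1] <- sd1(log2(nf_n / nf_n1))
  }
  names(out) <- as.character(2:(g - 1))
  out
}

random_ct <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  v <- matrix(runif(n_genes * n_samples, 18, 30), n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  ct_matrix(v)
}

make_rq <- function(qv) {
  structure(list(values = qv, groups = NULL), class = "rq_matrix")
}

# tiny wide table on disk (tempdir is cleaned up by R)
write_demo_table <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
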