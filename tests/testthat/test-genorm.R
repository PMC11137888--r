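test_that("relative quantities are per-gene 2^-dCt with max exactly 1", {
  v <- rbind(A = c(20, 21, 22), B = c(24, 24, 24))
  colnames(v) <- sprintf("s%d", 1:3)
  q <- to_relative_quantities(ct_matrix(v))
  expect_equal(unname(q$values["A", ]), c(1, 0.5, 0.25))
  expect_equal(unname(q$values["B", ]), c(1, 1, 1))

  q19 <- to_relative_quantities(ct_matrix(v), efficiencies = 1.9)
  expect_equal(unname(q19$values["A", ]), c(1, 1 / 1.9, 1 / 1.9^2))

  # every row attains its maximum 1 at the gene's minimum-Ct sample
  ct <- random_ct(6, 20, 5)
  qq <- to_relative_quantities(ct)
  expect_equal(unname(apply(qq$values, 1, max)), rep(1, 6))
  expect_true(all(qq$values > 0))

  expect_error(to_relative_quantities(ct_matrix(v), efficiencies = 1),
               "exceed 1")
  expect_error(to_relative_quantities(ct_matrix(v),
                                      efficiencies = c(A = 2)), "B")
})

test_that("M values match hand computation and the brute-force oracle", {
  qv <- rbind(A = c(1, 0.5, 0.25), B = c(1, 0.5, 0.25), C = c(1, 1, 0.5))
  colnames(qv) <- sprintf("s%d", 1:3)
  m <- genorm_m(make_rq(qv))
  expect_equal(unname(m), c(0.288675, 0.288675, 0.57735), tolerance = 1e-5)

  # exactly proportional genes have M = 0
  prop <- make_rq(rbind(A = c(1, 0.5, 0.2), B = c(1, 0.5, 0.2) * 1) |>
                    `colnames<-`(sprintf("s%d", 1:3)))
  expect_equal(unname(genorm_m(prop)), c(0, 0))

  for (seed in 1:5) {
    ct <- random_ct(5, 10, seed + 100)
    q <- to_relative_quantities(ct)
    expect_equal(genorm_m(q), oracle_genorm_m(q$values), tolerance = 1e-12)
  }
})

test_that("with all efficiencies 2, M equals the Delta Ct pair-SD mean", {
  for (seed in 1:50) {
    ct <- random_ct(8, 20, seed + 500)
    m <- genorm_m(to_relative_quantities(ct))
    expect_equal(m, delta_ct_stability(ct)$values, tolerance = 1e-10)
  }
})

test_that("M and V are invariant to per-sample and per-gene rescaling", {
  ct <- random_ct(5, 12, 77)
  q <- to_relative_quantities(ct)
  scaled <- q$values * matrix(runif(12, 0.5, 2), 5, 12, byrow = TRUE) *
    runif(5, 0.5, 2)
  qs <- make_rq(scaled)
  expect_equal(genorm_m(qs), genorm_m(q), tolerance = 1e-12)
  rk <- genorm_rank(q)$ranking
  expect_equal(genorm_v_series(qs, rk), genorm_v_series(q, rk),
               tolerance = 1e-12)
})

test_that("iterative ranking excludes the least stable gene first", {
  qv <- rbind(A = c(1, 0.5, 0.25), B = c(1, 0.5, 0.25), C = c(1, 1, 0.5))
  colnames(qv) <- sprintf("s%d", 1:3)
  res <- genorm_rank(make_rq(qv))
  expect_identical(res$ranking[3], "C")
  expect_setequal(res$ranking[1:2], c("A", "B"))
  expect_identical(unname(res$ranks[c("A", "B", "C")]), c(1L, 1L, 3L))

  expect_error(genorm_rank(make_rq(qv[1:2, ])), ">= 3 genes")
})

test_that("exclusion order matches an independent naive reimplementation", {
  for (seed in 1:5) {
    ct <- random_ct(6, 20, seed + 900)
    q <- to_relative_quantities(ct)
    res <- genorm_rank(q)
    dropped_first_to_last <- rev(res$ranking[3:6])
    expect_identical(dropped_first_to_last,
                     oracle_genorm_exclusion_order(q$values))
  }
})

test_that("ranking is invariant to gene input order", {
  ct <- random_ct(6, 15, 31)
  q <- to_relative_quantities(ct)
  perm <- sample(6)
  qp <- make_rq(q$values[perm, , drop = FALSE])
  expect_identical(genorm_rank(q)$ranking, genorm_rank(qp)$ranking)
})

test_that("V series matches hand computation and the naive oracle", {
  qv <- rbind(A = c(1, 0.5, 0.25), B = c(1, 0.5, 0.25), C = c(1, 1, 0.5))
  colnames(qv) <- sprintf("s%d", 1:3)
  v <- genorm_v_series(make_rq(qv), c("A", "B", "C"))
  expect_equal(unname(v["2"]), 1 / sqrt(27), tolerance = 1e-5)  # 0.19245

  # identical rows: V identically zero
  same <- make_rq(rbind(A = c(1, .5), B = c(1, .5), C = c(1, .5)) |>
                    `colnames<-`(c("s1", "s2")))
  expect_equal(unname(genorm_v_series(same, c("A", "B", "C"))), 0)

  for (seed in 1:5) {
    ct <- random_ct(5, 10, seed + 300)
    q <- to_relative_quantities(ct)
    rk <- genorm_rank(q)$ranking
    expect_equal(genorm_v_series(q, rk), oracle_v_series(q$values, rk),
                 tolerance = 1e-12)
  }
})

test_that("optimal count is the smallest n with V below the threshold", {
  expect_identical(optimal_rg_count(c(`2` = 0.12, `3` = 0.10)), 2L)
  expect_identical(optimal_rg_count(c(`2` = 0.20, `3` = 0.14, `4` = 0.13)), 3L)
  expect_identical(optimal_rg_count(c(`2` = 0.20, `3` = 0.16)), NA_integer_)
  # boundary: V exactly at the threshold does not qualify
  expect_identical(optimal_rg_count(c(`2` = 0.15, `3` = 0.149)), 3L)
})

test_that("genorm_analysis bundles ranking, V series and optimal n", {
  sim <- simulate_ct_dataset(synthetic_preset("corm_growth", seed = 11))
  res <- genorm_analysis(sim$ct)
  expect_s3_class(res$stability, "stability_result")
  expect_length(res$v_series, 10 - 2)
  expect_true(is.na(res$optimal_n) ||
                res$v_series[as.character(res$optimal_n)] < 0.15)
})
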