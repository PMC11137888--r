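test_that("degenerate inputs give all-zero stability", {
  v <- matrix(rep(c(20, 24, 28), 4), 3, 4,
              dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  ct <- ct_matrix(v, groups = setNames(rep(c("g1", "g2"), each = 2),
                                       colnames(v)))
  res <- normfinder_stability(ct)
  expect_equal(unname(res$values), rep(0, 3))
  expect_equal(unname(res$detail$intragroup_var), matrix(0, 3, 2),
               ignore_attr = TRUE)
  expect_equal(res$detail$gamma_sq, 0)
  expect_equal(unname(res$detail$group_diff_shrunken), matrix(0, 3, 2),
               ignore_attr = TRUE)
})

test_that("design errors are rejected", {
  ct <- random_ct(2, 6, 1)
  expect_error(normfinder_stability(ct), ">= 3 genes")
  ct3 <- random_ct(3, 3, 2)
  expect_error(
    normfinder_stability(ct3, groups = setNames(c("a", "a", "b"),
                                                colnames(ct3$values))),
    ">= 2 samples")
})

test_that("with one group the ranking is ascending sqrt(intragroup variance)", {
  cfg <- synthetic_ct_config(8, c(all = 30), noise_sd = seq(0.1, 0.8, 0.1),
                             sample_effect_sd = 0.5, seed = 5)
  sim <- simulate_ct_dataset(cfg)
  res <- normfinder_stability(sim$ct)
  expect_equal(unname(res$values),
               unname(sqrt(res$detail$intragroup_var[, 1])))
  expect_identical(res$ranks, rank_stability(res$values))
})

test_that("raw group differences sum to zero over genes and follow the designed shift", {
  # gene 1 up-regulated (Ct down) by delta in group 2; large n for precision
  I <- 6; delta <- 1.2
  shift <- matrix(0, I, 2); shift[1, 2] <- -delta
  cfg <- synthetic_ct_config(I, c(g1 = 400, g2 = 400), group_shift = shift,
                             noise_sd = 0.05, sample_effect_sd = 0.4,
                             seed = 17)
  sim <- simulate_ct_dataset(cfg)
  res <- normfinder_stability(sim$ct)
  d <- res$detail$group_diff_raw
  expect_equal(unname(colSums(d)), c(0, 0), tolerance = 1e-12)
  # between-group contrast on the analysis scale (y = -Ct)
  contrast <- d[, "g2"] - d[, "g1"]
  expect_equal(unname(contrast[1]), delta * (1 - 1 / I), tolerance = 0.02)
  expect_equal(unname(contrast[-1]), rep(-delta / I, I - 1), tolerance = 0.02)
})

test_that("outputs are invariant to per-sample and per-gene Ct shifts", {
  sim <- simulate_ct_dataset(synthetic_preset("tissues", seed = 23))
  base <- normfinder_stability(sim$ct)
  loading <- runif(ncol(sim$ct$values), -2, 2)
  pergene <- runif(nrow(sim$ct$values), -1, 1)
  shifted <- ct_matrix(sweep(sim$ct$values, 2, loading, "+") + pergene,
                       groups = sim$ct$groups)
  res <- normfinder_stability(shifted)
  expect_equal(res$values, base$values, tolerance = 1e-10)
  expect_equal(res$detail$gamma_sq, base$detail$gamma_sq, tolerance = 1e-10)
})

test_that("zero between-group signal shrinks all differences to zero", {
  cfg <- synthetic_ct_config(10, c(a = 8, b = 8), noise_sd = 0.3,
                             sample_effect_sd = 0.5, seed = 31)
  sim <- simulate_ct_dataset(cfg)
  res <- normfinder_stability(sim$ct)
  if (res$detail$gamma_sq == 0) {
    expect_equal(unname(res$detail$group_diff_shrunken),
                 matrix(0, 10, 2), ignore_attr = TRUE)
    expect_equal(unname(res$values),
                 unname(rowMeans(sqrt(res$detail$intragroup_var / 8))))
  } else {
    # shrinkage must still pull each difference toward zero
    expect_true(all(abs(res$detail$group_diff_shrunken) <=
                      abs(res$detail$group_diff_raw) + 1e-12))
  }
})

test_that("best pair favors genes with opposite-sign shrunken differences", {
  # two genes regulated in opposite directions, both with tiny noise:
  # their average cancels the shift and beats any other combination
  I <- 6
  shift <- matrix(0, I, 2)
  shift[1, 2] <- 0.8; shift[2, 2] <- -0.8
  cfg <- synthetic_ct_config(I, c(a = 12, b = 12), group_shift = shift,
                             noise_sd = c(0.05, 0.05, rep(0.4, I - 2)),
                             sample_effect_sd = 0.3, seed = 41)
  sim <- simulate_ct_dataset(cfg)
  res <- normfinder_stability(sim$ct)
  pair <- normfinder_best_pair(res)
  expect_setequal(pair$pair, c("g01", "g02"))

  # all-identical genes: deterministic lexicographic tie-break
  v <- matrix(rep(c(20, 21, 22, 23), each = 3), 3, 4, byrow = FALSE,
              dimnames = list(c("b", "c", "a"), sprintf("s%d", 1:4)))
  ct <- ct_matrix(v, groups = setNames(rep(c("x", "y"), each = 2),
                                       colnames(v)))
  tie <- normfinder_best_pair(normfinder_stability(ct))
  expect_identical(tie$pair, c("a", "b"))

  one_group <- normfinder_stability(
    ct_matrix(v, groups = setNames(rep("x", 4), colnames(v))))
  expect_error(normfinder_best_pair(one_group), ">= 2 groups")
})
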