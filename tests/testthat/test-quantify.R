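test_that("standard-curve slopes convert to amplification efficiency", {
  # slope -1/log10(2): perfect doubling
  ser <- simulate_dilution_series(amplification_factor = 2)
  fit <- fit_standard_curve(ser$log10_conc, ser$ct)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(fit$efficiency_percent, 100, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # slope -3.45 -> 94.9% (direct evaluation of 10^(1/3.45) - 1)
  ct345 <- 20 + 3.45 * -c(0, -1, -2, -3)
  fit345 <- fit_standard_curve(c(0, -1, -2, -3), ct345)
  expect_equal(fit345$efficiency_percent, (10^(1 / 3.45) - 1) * 100,
               tolerance = 1e-10)
  expect_equal(round(fit345$efficiency_percent, 1), 94.9)

  # generator inverse: factor 1.95 -> 95% exactly on a noiseless series
  ser195 <- simulate_dilution_series(amplification_factor = 1.95)
  expect_equal(fit_standard_curve(ser195$log10_conc, ser195$ct)$efficiency_percent,
               95, tolerance = 1e-9)
})

test_that("invalid dilution series are rejected", {
  expect_error(fit_standard_curve(c(0, -1), c(20, 23)), ">= 3")
  expect_error(fit_standard_curve(c(0, -1, -2), c(20, 23, 26) * -1 + 50),
               "slope must be negative")
})

test_that("normalization factors are per-sample geometric means of RG quantities", {
  v <- rbind(A = c(20, 21, 22), C = c(24, 24, 25))
  colnames(v) <- sprintf("s%d", 1:3)
  ct <- ct_matrix(v)
  # single RG: NF equals its quantity row
  expect_equal(unname(normalization_factor(ct, "A")), c(1, 0.5, 0.25))
  # two identical RGs reduce to either row
  ct2 <- ct_matrix(rbind(A = v["A", ], B = v["A", ]))
  expect_equal(unname(normalization_factor(ct2, c("A", "B"))), c(1, 0.5, 0.25))
  # hand geometric mean of rows (1,.5,.25) and (1,1,.5)
  expect_equal(unname(normalization_factor(ct, c("A", "C"))),
               c(1, sqrt(0.5), sqrt(0.125)), tolerance = 1e-12)
  expect_error(normalization_factor(ct, "nope"), "not in matrix")
})

test_that("fold changes follow the 2^-ddCt construction", {
  samples <- sprintf("s%d", 1:6)
  rg <- setNames(c(20, 20, 20, 20, 20, 20), samples)
  # target one cycle below the RG in treated samples only
  target <- setNames(c(25, 25, 25, 24, 24, 24), samples)
  ct <- ct_matrix(rbind(RG = rg, TG = target))
  nf <- normalization_factor(ct, "RG")
  res <- relative_expression(ct$values["TG", ], nf,
                             calibrator = samples[1:3])
  expect_equal(res$fold_change, c(1, 1, 1, 2, 2, 2))
  # calibrator aggregate fold is 1 by construction
  expect_equal(mean(res$fold_change[1:3]), 1)

  # target identical to the RG: all folds 1
  same <- relative_expression(rg, nf, calibrator = samples[1:2])
  expect_equal(same$fold_change, rep(1, 6))

  expect_error(relative_expression(target, nf, calibrator = "zzz"),
               "unknown: zzz")
})

test_that("per-sample rescaling of all genes cancels in the fold change", {
  set.seed(9)
  v <- matrix(runif(30, 20, 26), 3, 10,
              dimnames = list(c("R1", "R2", "T"), sprintf("s%d", 1:10)))
  loading <- runif(10, -2, 2)
  ct <- ct_matrix(v)
  ct_shift <- ct_matrix(sweep(v, 2, loading, "+"))
  f <- function(ctm) {
    nf <- normalization_factor(ctm, c("R1", "R2"))
    relative_expression(ctm$values["T", ], nf,
                        calibrator = sprintf("s%d", 1:5))$fold_change
  }
  expect_equal(f(ct_shift), f(ct), tolerance = 1e-10)
})

test_that("an unstable reference gene biases folds by its programmed shift", {
  # stable RG and a RG whose Ct rises 1 cycle in the treated group (its
  # expression halves); a truly unchanged target then appears 2-fold 'up'
  samples <- sprintf("s%d", 1:6)
  stable <- setNames(rep(21, 6), samples)
  bad <- setNames(c(22, 22, 22, 23, 23, 23), samples)
  target <- setNames(rep(25, 6), samples)
  ct <- ct_matrix(rbind(STABLE = stable, BAD = bad, T = target))
  good <- relative_expression(target, normalization_factor(ct, "STABLE"),
                              calibrator = samples[1:3])
  biased <- relative_expression(target, normalization_factor(ct, "BAD"),
                                calibrator = samples[1:3])
  expect_equal(good$fold_change[4:6], rep(1, 3))
  expect_equal(biased$fold_change[4:6], rep(2, 3))
})

test_that("geometric calibrator aggregation is available", {
  samples <- sprintf("s%d", 1:4)
  target <- setNames(c(24, 25, 23, 22), samples)
  nf <- setNames(rep(1, 4), samples)
  res <- relative_expression(target, nf, calibrator = samples[1:2],
                             calibrator_agg = "geometric")
  expect_equal(exp(mean(log(res$fold_change[1:2]))), 1, tolerance = 1e-12)
})
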