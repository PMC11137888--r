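test_that("regeneration under the same config is bit-identical", {
  cfg <- synthetic_preset("corm_growth", seed = 123)
  a <- simulate_ct_dataset(cfg)
  b <- simulate_ct_dataset(cfg)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$truth$sample_effects, b$truth$sample_effects)
  # a different seed changes the draw
  c2 <- simulate_ct_dataset(synthetic_preset("corm_growth", seed = 124))
  expect_false(identical(a$ct$values, c2$ct$values))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- runif(1)
  set.seed(555)
  invisible(simulate_ct_dataset(synthetic_preset("drought", seed = 9)))
  expect_identical(runif(1), before)
})

test_that("a fully degenerate config yields constant genes and all-zero stability", {
  cfg <- synthetic_ct_config(4, c(a = 3, b = 3), sample_effect_sd = 0,
                             noise_sd = 0, seed = 1)
  sim <- simulate_ct_dataset(cfg)
  expect_equal(unname(apply(sim$ct$values, 1, sd)), rep(0, 4))
  expect_equal(unname(delta_ct_stability(sim$ct)$values), rep(0, 4))
  suppressWarnings(
    expect_equal(unname(bestkeeper_stats(sim$ct)$values), rep(0, 4)))
  expect_equal(unname(genorm_m(to_relative_quantities(sim$ct))), rep(0, 4))
  expect_equal(unname(normfinder_stability(sim$ct)$values), rep(0, 4))
})

test_that("a pure loading effect is invisible to pairwise/log-ratio methods only", {
  cfg <- synthetic_ct_config(6, c(a = 6, b = 6), sample_effect_sd = 1,
                             noise_sd = 0, seed = 77)
  sim <- simulate_ct_dataset(cfg)
  expect_lt(max(delta_ct_stability(sim$ct)$values), 1e-10)
  expect_lt(max(genorm_m(to_relative_quantities(sim$ct))), 1e-10)
  expect_lt(max(normfinder_stability(sim$ct)$values), 1e-10)
  bk <- bestkeeper_stats(sim$ct)$values
  # BestKeeper sees exactly the realized loading-effect SD
  expect_equal(unname(bk), rep(sd(sim$truth$sample_effects), 6),
               tolerance = 1e-10)
})

test_that("the designed stability ordering tracks shift and noise magnitude", {
  cfg <- synthetic_preset("all", seed = 3)
  sim <- simulate_ct_dataset(cfg)
  ord <- sim$truth$designed_order
  expect_setequal(ord, cfg$gene_ids)
  expect_identical(ord[length(ord)], "bTUB_like")
  expect_identical(ord[length(ord) - 1], "EF1A_like")
})

test_that("designed FPKM screening outcomes are recovered across seeds", {
  # Monte-Carlo truth at n = 42 samples (20k draws of the generator's
  # lognormal): a CV-15% design passes the default screen 99.7% of the
  # time, a CV-18% design 85% (its realized CV straddles the 20% cutoff),
  # a CV-60% design fails essentially always.
  clear_pass <- near_pass <- fail_hits <- logical(200)
  for (s in 1:200) {
    sim <- simulate_fpkm_dataset(3, 42, mean_targets = 35,
                                 cv_targets = c(15, 18, 60), seed = s)
    st <- compute_gene_stats(sim$fpkm)
    kept <- screen_candidates(st)$gene_id
    clear_pass[s] <- "gene001" %in% kept
    near_pass[s] <- "gene002" %in% kept
    fail_hits[s] <- !("gene003" %in% kept)
  }
  expect_gte(mean(clear_pass), 0.95)
  expect_gte(mean(near_pass), 0.78)   # 0.85 - 3 binomial SE
  expect_gte(mean(fail_hits), 0.95)
})

test_that("zero-CV targets give exactly constant genes", {
  sim <- simulate_fpkm_dataset(3, 10, mean_targets = c(20, 30, 40),
                               cv_targets = 0, seed = 8)
  expect_equal(unname(apply(sim$fpkm$values, 1, sd)), rep(0, 3))
  expect_equal(unname(rowMeans(sim$fpkm$values)), c(20, 30, 40))
})

test_that("dilution series invert exactly without noise and nearly with noise", {
  ser <- simulate_dilution_series(amplification_factor = 1.945)
  fit <- fit_standard_curve(ser$log10_conc, ser$ct)
  expect_equal(fit$efficiency_percent, 94.5, tolerance = 1e-9)

  eff <- vapply(1:200, function(s) {
    ser <- simulate_dilution_series(2, noise_sd = 0.2, seed = s)
    fit_standard_curve(ser$log10_conc, ser$ct)$efficiency_percent
  }, numeric(1))
  expect_lt(abs(mean(eff) - 100), 2)
  expect_gte(mean(abs(eff - 100) <= 10), 0.99)
  expect_error(simulate_dilution_series(2, noise_sd = 0.1), "seed")
})

test_that("config validation rejects malformed designs", {
  expect_error(synthetic_ct_config(3, c(a = 1, b = 3), seed = 1))
  expect_error(synthetic_ct_config(3, c(3, 3), seed = 1))
  expect_error(synthetic_ct_config(3, c(a = 3), noise_sd = -1, seed = 1))
  expect_error(synthetic_ct_config(3, c(a = 3), sample_effect_sd = -1, seed = 1))
})
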