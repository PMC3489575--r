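test_that("a constant dataset decomposes to zero SS with the design's dfs", {
  design <- build_design(4, 4, 6)
  ds <- make_cell_dataset(design, function(s, b, k) 3.7)
  dec <- decompose_trial(ds)
  expect_true(all(abs(dec$ss) < 1e-18))
  expect_equal(dec$df[dec$stratum == "site"], 3)
  expect_equal(dec$df[dec$stratum == "block_in_site"], 12)
  expect_equal(dec$df[dec$stratum == "genotype_group"], 2)
  expect_equal(dec$df[dec$stratum == "genotype_within_reference"], 5)
  expect_equal(dec$df[dec$stratum == "site_x_test"], 3)
  expect_equal(dec$df[dec$stratum == "site_x_reference"], 15)
  expect_equal(dec$df[dec$stratum == "site_x_group"], 3)
  expect_equal(dec$df[dec$stratum == "residual"], 84)
  expect_equal(sum(dec$df), 127)
})

test_that("strata are orthogonal: SS sum to total and dfs to N - 1", {
  for (seed in c(5, 17, 301)) {
    ds <- simulate_trial(quick_cfg(seed = seed, interaction = 0.008))
    dec <- decompose_trial(ds)
    expect_true(all(dec$ss >= 0))
    expect_lt(abs(sum(dec$ss) - attr(dec, "total_ss")) / attr(dec, "total_ss"), 1e-9)
    expect_equal(sum(dec$df), attr(dec, "total_df"))
  }
  # and on a non-default geometry with partitioned interaction
  cfg <- simulation_config(build_design(3, 5, 4),
                           varcomps = variance_components(interaction_test = 0.01,
                                                          interaction_reference = 0.004),
                           seed = 9)
  dec <- decompose_trial(simulate_trial(cfg))
  expect_lt(abs(sum(dec$ss) - attr(dec, "total_ss")) / attr(dec, "total_ss"), 1e-9)
  expect_equal(sum(dec$df), attr(dec, "total_df"))
})

test_that("decompose_trial refuses unbalanced data and points at REML", {
  ds <- simulate_trial(quick_cfg(seed = 2))
  expect_error(decompose_trial(as.data.frame(ds)[-1, ], attr(ds, "design")),
               "unbalanced|incomplete")
})

test_that("expected mean squares: degenerate cases and the residual definition", {
  design <- build_design(4, 4, 6)
  zero <- variance_components(site = 0, block = 0, genotype = 0, interaction = 0,
                              residual = 0)
  expect_true(all(expected_mean_squares(design, zero)$ems == 0))

  vc <- variance_components(site = 0.03, block = 0.007, genotype = 0.011,
                            interaction = 0.004, residual = 0.009)
  ems <- expected_mean_squares(design, vc)
  expect_equal(ems$ems[ems$stratum == "residual"], 0.009)
  # textbook balanced forms for the classic strata (s=4, b=4, g=8)
  expect_equal(ems$ems[ems$stratum == "site_x_test"], 0.009 + 4 * 0.004)
  expect_equal(ems$ems[ems$stratum == "site_x_reference"], 0.009 + 4 * 0.004)
  expect_equal(ems$ems[ems$stratum == "genotype_within_reference"],
               0.009 + 4 * 0.004 + 16 * 0.011)
  expect_equal(ems$ems[ems$stratum == "block_in_site"], 0.009 + 8 * 0.007)
  expect_equal(ems$ems[ems$stratum == "site"],
               0.009 + 8 * 0.007 + 4 * 0.004 + 32 * 0.03)
})

test_that("Monte-Carlo mean squares match the closed-form EMS in every stratum", {
  vc <- variance_components(site = 0.02, block = 0.005, genotype = 0.01,
                            interaction = 0.005, residual = 0.01)
  cfg <- default_config(seed = 55, varcomps = vc)
  ems <- expected_mean_squares(cfg$design, vc)
  reps <- simulate_batch(cfg, 1500)
  ms <- vapply(reps, function(d) decompose_trial(d)$ms, numeric(8))
  for (i in seq_len(nrow(ms))) {
    se <- sd(ms[i, ]) / sqrt(ncol(ms))
    expect_lt(abs(mean(ms[i, ]) - ems$ems[i]), 3 * se)
  }
})

test_that("estimate_varcomps exactly inverts EMS-consistent mean squares", {
  vc <- variance_components(site = 0.03, block = 0.002, genotype = 0.015,
                            interaction_test = 0.006, interaction_reference = 0.003,
                            residual = 0.012)
  cfg <- default_config(seed = 1, varcomps = vc)
  ems <- expected_mean_squares(cfg$design, vc)
  dec <- decompose_trial(simulate_trial(cfg))
  dec$ms <- ems$ems
  dec$ss <- ifelse(dec$df > 0, dec$ms * dec$df, 0)
  est <- estimate_varcomps(dec, cfg$design)
  pick <- function(comp) est$estimate[est$component == comp]
  expect_equal(pick("site"), 0.03, tolerance = 1e-10)
  expect_equal(pick("block"), 0.002, tolerance = 1e-10)
  expect_equal(pick("genotype"), 0.015, tolerance = 1e-10)
  expect_equal(pick("interaction_test"), 0.006, tolerance = 1e-10)
  expect_equal(pick("interaction_reference"), 0.003, tolerance = 1e-10)
  expect_equal(pick("residual"), 0.012, tolerance = 1e-10)
  expect_false(any(est$truncated))
})

test_that("negative variance solutions truncate to zero with a flag", {
  cfg <- default_config(seed = 1)
  dec <- decompose_trial(simulate_trial(cfg))
  # force MS_SxT below MS_residual so the interaction solution is negative
  dec$ms[dec$stratum == "site_x_test"] <- 0.004
  dec$ms[dec$stratum == "residual"] <- 0.01
  est <- estimate_varcomps(dec, cfg$design)
  row <- est[est$component == "interaction_test", ]
  expect_equal(row$estimate, 0)
  expect_lt(row$raw, 0)
  expect_true(row$truncated)
})

test_that("a constant dataset yields all-zero variance estimates", {
  ds <- make_cell_dataset(build_design(4, 4, 6), function(s, b, k) 1)
  est <- estimate_varcomps(decompose_trial(ds))
  expect_true(all(est$estimate[!is.na(est$raw)] == 0))
})

test_that("method-of-moments estimates are unbiased before truncation", {
  vc <- variance_components(site = 0.02, block = 0.005, genotype = 0.01,
                            interaction_test = 0.006, interaction_reference = 0.003,
                            residual = 0.01)
  cfg <- default_config(seed = 303, varcomps = vc)
  truth <- c(site = 0.02, block = 0.005, genotype = 0.01,
             interaction_test = 0.006, interaction_reference = 0.003,
             residual = 0.01)
  reps <- simulate_batch(cfg, 5000)
  raw <- vapply(reps, function(d) {
    est <- estimate_varcomps(decompose_trial(d), cfg$design)
    setNames(est$raw, est$component)[names(truth)]
  }, numeric(6))
  for (comp in names(truth)) {
    se <- sd(raw[comp, ]) / sqrt(ncol(raw))
    expect_lt(abs(mean(raw[comp, ]) - truth[[comp]]), 3 * se)
  }
})

test_that("with no simulated interaction, the interaction mean square estimates plot error", {
  cfg <- quick_cfg(seed = 404, interaction = 0)
  reps <- simulate_batch(cfg, 2000)
  ms <- vapply(reps, function(d) {
    dec <- decompose_trial(d)
    p <- dec$ss[dec$stratum %in% c("site_x_test", "site_x_reference", "site_x_group")]
    sum(p) / sum(dec$df[dec$stratum %in% c("site_x_test", "site_x_reference",
                                           "site_x_group")])
  }, 1.0)
  expect_lt(abs(mean(ms) - 0.01), 3 * sd(ms) / sqrt(length(ms)))
})

test_that("interaction stratum df follows (s-1)(t-1)", {
  expect_identical(interaction_df(4, 2), 3L)
  expect_identical(interaction_df(2, 2), 1L)
  expect_identical(interaction_df(5, 3), 8L)
  expect_error(interaction_df(1, 2), "n_sites")
  expect_error(interaction_df(4, 1), "n_genotypes")
})
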