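test_that("identical reference varieties give a zero natural-variation estimate", {
  design <- build_design(3, 3, 4)
  ds <- make_cell_dataset(design, function(s, b, k) {
    base <- 0.2 * s + 0.05 * b
    if (k <= 2) base + 0.1 * k else base      # all references identical per plot
  })
  rv <- estimate_reference_variation(ds)
  expect_equal(rv$v_g, 0)
  expect_equal(rv$reference_mean, mean(ds$response[ds$group == "reference"]))
})

test_that("fewer than two reference varieties cannot estimate natural variation", {
  ds <- simulate_trial(simulation_config(build_design(3, 3, 1), seed = 4))
  expect_error(estimate_reference_variation(ds), "natural variation")
  expect_error(equivalence_limits(ds), "reference varieties")
})

test_that("v_g estimation is unbiased at the configured genotype variance", {
  cfg <- quick_cfg(seed = 1203, interaction = 0.004)
  vg <- vapply(simulate_batch(cfg, 1500), function(d) {
    est <- estimate_varcomps(decompose_trial(d))
    est$raw[est$component == "genotype"]
  }, 1.0)
  expect_lt(abs(mean(vg) - 0.01), 3 * sd(vg) / sqrt(length(vg)))
})

test_that("limits collapse toward zero in the degenerate no-variation case", {
  design <- build_design(4, 4, 6)
  set.seed(99)
  ds <- make_cell_dataset(design, function(s, b, k) rnorm(1, 0, 1e-6))
  lim <- equivalence_limits(ds)
  expect_lt(lim[["upper"]], 1e-4)
  expect_gt(lim[["upper"]], 0)
  expect_equal(lim[["lower"]], -lim[["upper"]])
})

test_that("inflating the between-variety spread strictly widens the limits", {
  ds <- simulate_trial(quick_cfg(seed = 15, interaction = 0.002))
  lim1 <- equivalence_limits(ds)
  # push each reference variety away from the reference mean by 50%
  df <- as.data.frame(ds)
  ref <- df$group == "reference"
  vmeans <- ave(df$response, df$genotype)
  refmean <- mean(df$response[ref])
  df$response[ref] <- df$response[ref] + 0.5 * (vmeans[ref] - refmean)
  lim2 <- equivalence_limits(trial_dataset(df, attr(ds, "design")))
  expect_gt(lim2[["upper"]], lim1[["upper"]])
})

test_that("study-specific limits match a spreadsheet-style recomputation", {
  ds <- simulate_trial(quick_cfg(seed = 77, interaction = 0.006))
  s <- 4; b <- 4; r <- 6
  df <- as.data.frame(ds)
  # plain arithmetic on plot means, no package internals
  cell <- tapply(df$response, list(df$genotype, df$site), mean)
  ref_rows <- rownames(cell)[!rownames(cell) %in% c("GMO", "Comparator")]
  gmeans <- rowMeans(cell)
  ms_ref <- s * b * sum((gmeans[ref_rows] - mean(gmeans[ref_rows]))^2) / (r - 1)
  # pooled no-interaction error: total - site - block - genotype strata
  site_m <- tapply(df$response, df$site, mean)
  blk_m <- tapply(df$response, list(df$block, df$site), mean)
  ss_tot <- sum((df$response - mean(df$response))^2)
  ss_site <- b * 8 * sum((site_m - mean(df$response))^2)
  ss_blk <- 8 * sum(sweep(blk_m, 2, site_m)^2)
  ss_gen <- s * b * sum((gmeans - mean(df$response))^2)
  mse_pool <- (ss_tot - ss_site - ss_blk - ss_gen) / (128 - 1 - 3 - 12 - 7)
  v_g <- max((ms_ref - mse_pool) / (s * b), 0)
  var_d <- mse_pool / (s * b) + ms_ref / (s * b * r)
  expected <- qt(0.95, r - 1) * sqrt(v_g + var_d)
  lim <- equivalence_limits(ds, alpha = 0.05)
  expect_equal(lim[["upper"]], expected, tolerance = 1e-10)
  expect_equal(lim[["lower"]], -expected, tolerance = 1e-10)
})

test_that("clear-cut verdicts: equivalent and not-equivalent geometries", {
  design <- build_design(4, 4, 6)
  set.seed(5)
  near <- make_cell_dataset(design, function(s, b, k) rnorm(1, 0, 0.001))
  expect_equal(equivalence_test(near, fixed_limits = c(-0.5, 0.5))$verdict,
               "EQUIVALENT")
  far <- make_cell_dataset(design, function(s, b, k)
    rnorm(1, if (k == 1) 2 else 0, 0.001))
  res <- equivalence_test(far, fixed_limits = c(-0.5, 0.5))
  expect_equal(res$verdict, "NOT_EQUIVALENT")
  expect_equal(res$limits_source, "USER_FIXED")
  expect_error(equivalence_test(near, fixed_limits = c(0.5, -0.5)), "lower < upper")
})

test_that("the verdict is invariant to a constant shift of all responses", {
  ds <- simulate_trial(quick_cfg(seed = 88, interaction = 0.004))
  df2 <- as.data.frame(ds); df2$response <- df2$response + 3.5
  ds2 <- trial_dataset(df2, attr(ds, "design"))
  for (mode in c("no_interaction", "interaction_inflated")) {
    a <- equivalence_test(ds, mode = mode)
    b <- equivalence_test(ds2, mode = mode)
    expect_equal(a$verdict, b$verdict)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-9)
    expect_equal(a$limits, b$limits, tolerance = 1e-9)
  }
})

test_that("with user-fixed limits the reference varieties matter only through their mean", {
  ds <- simulate_trial(quick_cfg(seed = 123, interaction = 0.005))
  base <- equivalence_test(ds, fixed_limits = c(-0.2, 0.2))
  # reshuffle which reference variety each reference plot is attributed to,
  # within every site/block cell: plot values and the reference mean are
  # untouched, the between-variety decomposition changes completely
  df <- as.data.frame(ds)
  set.seed(42)
  for (s in unique(df$site)) for (b in unique(df$block)) {
    idx <- which(df$site == s & df$block == b & df$group == "reference")
    df$response[idx] <- df$response[sample(idx)]
  }
  shuffled <- trial_dataset(df, attr(ds, "design"))
  perturbed <- equivalence_test(shuffled, fixed_limits = c(-0.2, 0.2))
  expect_equal(perturbed$verdict, base$verdict)
  expect_equal(perturbed$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(perturbed$conf_int, base$conf_int, tolerance = 1e-12)
})

test_that("widening limits never downgrades a verdict", {
  rank_of <- c(NOT_EQUIVALENT = 1, INCONCLUSIVE = 2, EQUIVALENT = 3)
  widths <- c(0.02, 0.1, 0.3, 1)
  for (seed in c(6, 60, 600)) {
    ds <- simulate_trial(quick_cfg(seed = seed, interaction = 0.005))
    verdicts <- vapply(widths, function(w)
      equivalence_test(ds, fixed_limits = c(-w, w))$verdict, "")
    expect_true(all(diff(rank_of[verdicts]) >= 0))
  }
})

test_that("the interaction-inflated mode reports wider or equal limits", {
  ds <- simulate_trial(quick_cfg(seed = 321, interaction = 0.01))
  l0 <- equivalence_limits(ds, mode = "no_interaction")
  l1 <- equivalence_limits(ds, mode = "interaction_inflated")
  expect_true(is.finite(l1[["upper"]]))
  expect_equal(attr(l1, "mode"), "interaction_inflated")
  # the inflated baseline adds the site-by-reference component
  expect_gte(attr(l1, "baseline"), attr(l1, "v_g"))
  expect_equal(l0[["lower"]], -l0[["upper"]])
})
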