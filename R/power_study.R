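#' Binomial standard error of a Monte-Carlo rejection rate
#'
#' \eqn{\sqrt{p(1-p)/n}} with no continuity correction; at 1000 replicates a
#' rate of 0.29 carries SE 0.014 and a rate of 0.36 carries SE 0.015 (to the
#' three decimals such rates are conventionally printed with).
#'
#' @param rate Proportion in \[0, 1\].
#' @param n_reps Number of replicates (\eqn{\ge 1}).
#' @return The standard error.
#' @examples
#' round(binomial_se(0.29, 1000), 3)  # 0.014
#' @export
binomial_se <- function(rate, n_reps) {
  if (!is.numeric(rate) || any(rate < 0) || any(rate > 1))
    stop("`rate` must be in [0, 1]", call. = FALSE)
  if (!all(vapply(n_reps, .is_count, TRUE)) || any(n_reps < 1))
    stop("`n_reps` must be an integer >= 1", call. = FALSE)
  sqrt(rate * (1 - rate) / n_reps)
}

#' Monte-Carlo study grid for the difference test
#'
#' The simulation layout of the trial-methodology power study: a grid of true
#' GMO offsets crossed with site-by-genotype interaction levels expressed as
#' ratios of the interaction variance to the reference-genotype variance
#' (0 = the no-interaction world; 0.5 and 1 are the survey-motivated levels).
#'
#' @param mu_gmo_values Ordered vector of fixed GMO offsets; the default is
#'   the grid 0, 0.02, 0.05, 0.07, 0.10, 0.12, 0.15, 0.17, 0.20, 0.22, 0.25
#'   (alternating +0.02/+0.03 steps).
#' @param interaction_ratios Ratios \eqn{\sigma^2_{SxG}/\sigma^2_{geno}}
#'   (\eqn{\ge 0}); default `c(0, 0.5, 1)`.
#' @param n_reps Replicates per cell (default 1000).
#' @param base_config A [simulation_config()] template; its seed is the master
#'   seed and its `varcomps$genotype` anchors the ratios.
#' @param alpha Test size (default 0.1).
#' @param test `"naive"` or `"interaction"`.
#' @return A `study_grid` object.
#' @export
study_grid <- function(mu_gmo_values = c(0, 0.02, 0.05, 0.07, 0.10, 0.12,
                                         0.15, 0.17, 0.20, 0.22, 0.25),
                       interaction_ratios = c(0, 0.5, 1),
                       n_reps = 1000L,
                       base_config = default_config(),
                       alpha = 0.1,
                       test = c("naive", "interaction")) {
  test <- match.arg(test)
  stopifnot(inherits(base_config, "simulation_config"))
  if (!.is_count(n_reps) || n_reps < 1)
    stop("`n_reps` must be an integer >= 1", call. = FALSE)
  if (any(interaction_ratios < 0)) stop("interaction ratios must be >= 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  structure(list(mu_gmo_values = mu_gmo_values,
                 interaction_ratios = interaction_ratios,
                 n_reps = as.integer(n_reps), base_config = base_config,
                 alpha = alpha, test = test),
            class = "study_grid")
}

#' Run a Monte-Carlo rejection-rate study
#'
#' For every (GMO offset, interaction ratio) cell: simulate `n_reps` trials
#' with \eqn{\sigma^2_{SxG} = ratio \times \sigma^2_{geno}}, run the chosen
#' difference test at `alpha`, and count rejections (p < alpha). The row with
#' zero offset estimates the type-I error rate; nonzero offsets trace the
#' power curve. Fully deterministic given the base config's seed: each cell
#' draws its replicate seeds from its own substream.
#'
#' @param grid A [study_grid()].
#' @return A `power_study` data frame: one row per cell with `mu_gmo`,
#'   `ratio`, `rejections`, `n_reps`, `rate`, `se`, `cell_seed`; attributes
#'   `alpha`, `test`, `seed`.
#' @export
run_power_study <- function(grid) {
  stopifnot(inherits(grid, "study_grid"))
  cells <- expand.grid(mu_gmo = grid$mu_gmo_values, ratio = grid$interaction_ratios,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- .substream_seeds(grid$base_config$seed, nrow(cells))
  base <- grid$base_config
  rej <- integer(nrow(cells))
  for (c_i in seq_len(nrow(cells))) {
    vc <- base$varcomps
    vc2 <- variance_components(site = vc$site, block = vc$block,
                               genotype = vc$genotype,
                               interaction = cells$ratio[c_i] * vc$genotype,
                               residual = vc$residual)
    means <- base$means
    means$gmo_offset <- cells$mu_gmo[c_i]
    cfg <- simulation_config(base$design, means, vc2, seed = cell_seeds[c_i])
    rep_seeds <- .substream_seeds(cfg$seed, grid$n_reps)
    n_rej <- 0L
    for (r in seq_len(grid$n_reps)) {
      set.seed(rep_seeds[r])
      ds <- .simulate_trial_nostate(cfg)
      res <- difference_test(ds, method = grid$test, alpha = grid$alpha)
      if (res$p_value < grid$alpha) n_rej <- n_rej + 1L
    }
    rej[c_i] <- n_rej
  }
  out <- data.frame(mu_gmo = cells$mu_gmo, ratio = cells$ratio,
                    rejections = rej, n_reps = rep(grid$n_reps, nrow(cells)),
                    rate = rej / grid$n_reps,
                    se = binomial_se(rej / grid$n_reps, grid$n_reps),
                    cell_seed = cell_seeds)
  structure(out, class = c("power_study", "data.frame"),
            alpha = grid$alpha, test = grid$test, seed = grid$base_config$seed)
}

#' Tidy table of a power study
#'
#' One row per (offset, ratio) cell, suitable for plotting the per-ratio
#' power-curve panels or writing to CSV.
#'
#' @param result A [run_power_study()] result (an empty data frame with the
#'   same columns is accepted and passed through).
#' @return Data frame with columns `mu_gmo`, `ratio`, `rate`, `se`, `n_reps`.
#' @export
power_curve_table <- function(result) {
  cols <- c("mu_gmo", "ratio", "rate", "se", "n_reps")
  if (nrow(result) == 0)
    return(as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols)))
  as.data.frame(result)[, cols]
}

#' Plot power curves, one panel per interaction ratio
#'
#' @param result A [run_power_study()] result.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_power_curves <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_power_curves() needs the ggplot2 package", call. = FALSE)
  tab <- power_curve_table(result)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mu_gmo, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rate - .data$se,
                                          ymax = .data$rate + .data$se)) +
    ggplot2::geom_hline(yintercept = attr(result, "alpha"), linetype = 2) +
    ggplot2::facet_wrap(~ratio, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "true GMO offset (log scale)", y = "rejection rate",
                  title = sprintf("%s difference test, alpha = %g",
                                  attr(result, "test"), attr(result, "alpha"))) +
    ggplot2::ylim(0, 1)
}

#' Named variance-component profiles for the power study
#'
#' `"stand-in"` returns the package's default log-scale components. The
#' `"companion-paper"` slot exists so the exact components of the cited
#' companion methodology can be dropped in for exact reproduction of its
#' rejection rates; those values are not bundled, so selecting it without
#' supplying them is an error.
#'
#' @param name Profile name.
#' @param ... Components passed to [variance_components()] when filling the
#'   `"companion-paper"` slot.
#' @return A [variance_components()] object.
#' @export
varcomp_profile <- function(name = c("stand-in", "companion-paper"), ...) {
  name <- match.arg(name)
  if (name == "stand-in") return(variance_components())
  if (nargs() < 2)
    stop("the \"companion-paper\" profile is a placeholder: supply the published ",
         "variance components, e.g. varcomp_profile(\"companion-paper\", site = ..., ",
         "block = ..., genotype = ..., residual = ...)", call. = FALSE)
  variance_components(...)
}
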