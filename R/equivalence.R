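# Equivalence of the GMO against the reference population.
#
# The reference varieties are a random sample from the population of non-GM
# varieties with a history of safe use; their between-variety variance V_g is
# part of the natural baseline variation, so study-specific equivalence limits
# include it explicitly. The exact published limit construction lives in a
# companion methodology; the construction here implements the stated
# principle (an lsd-style interval with V_g in the baseline) and is isolated
# in equivalence_limits() so it can be swapped without touching callers.

#' Reference-population variation
#'
#' Mean of the reference plots, the estimated between-variety variance V_g
#' (the genotype-within-reference method-of-moments component), and the
#' standard error of the reference mean. Because V_g is a between-variety
#' component, the SE carries the variety count in its denominator:
#' \eqn{SE^2 = MS_{geno(ref)}/(sbr)}, which unbiasedly estimates
#' \eqn{V_g/r + \sigma^2_{SxR}/(sr) + \sigma^2_e/(sbr)} (site and block main
#' effects cancel from every between-genotype contrast).
#'
#' @param data A complete balanced `trial_dataset` with at least 2 reference
#'   varieties.
#' @return List with `reference_mean`, `v_g`, `se_reference_mean`, and the
#'   underlying `varcomp_estimates`.
#' @export
estimate_reference_variation <- function(data) {
  design <- attr(data, "design")
  if (is.null(design)) design <- .design_from_records(data)
  d <- .design_dims(design)
  if (d$r < 2)
    stop("cannot estimate natural variation: at least 2 reference varieties ",
         "are needed (got ", d$r, ")", call. = FALSE)
  decomp <- decompose_trial(data, design)
  est <- estimate_varcomps(decomp, design)
  v_g <- est$estimate[est$component == "genotype"]
  ms_ref <- .anova_get(decomp, "genotype_within_reference")
  list(reference_mean = mean(data$response[data$group == "reference"]),
       v_g = v_g,
       se_reference_mean = sqrt(ms_ref / (d$s * d$b * d$r)),
       estimates = est)
}

# variance of the GMO-minus-reference-mean contrast, by mode.
# Site and block main effects cancel; what is left is the GMO mean's
# interaction + error part and the reference mean's genotype + interaction +
# error part. MS_geno(ref)/(sbr) estimates the latter exactly; the GMO part is
# MS_SxT/(sb) under the interaction model and MSE_pooled/(sb) under the
# no-interaction model.
.contrast_variance <- function(decomp, d, mode) {
  ms_ref <- .anova_get(decomp, "genotype_within_reference")
  if (mode == "no_interaction") {
    err <- .pooled_error(decomp)
    err$ms / (d$s * d$b) + ms_ref / (d$s * d$b * d$r)
  } else {
    .anova_get(decomp, "site_x_test") / (d$s * d$b) + ms_ref / (d$s * d$b * d$r)
  }
}

#' Study-specific equivalence limits
#'
#' lsd-style limits centred at zero difference,
#' \deqn{\pm\; t_{1-\alpha,\,r-1}\,\sqrt{baseline + \mathrm{Var}(\bar y_{GMO}-\bar y_{REF})},}
#' where the baseline is the estimated reference-population variance V_g
#' (`mode = "no_interaction"`, the default) or V_g plus the
#' site-by-reference-variety interaction component
#' (`mode = "interaction_inflated"`, answering whether limits should reflect
#' that reference varieties perform differently across locations). The
#' t quantile runs on the genotype-within-reference degrees of freedom
#' (\eqn{r - 1}).
#'
#' @param data A complete balanced `trial_dataset`, \eqn{r \ge 2}.
#' @param alpha Size of the underlying one-sided tests (default 0.05).
#' @param mode Baseline construction; see Details.
#' @return Length-2 numeric `(lower, upper)` with attributes `v_g`,
#'   `baseline`, `contrast_variance`, `df`, `mode`.
#' @export
equivalence_limits <- function(data, alpha = 0.05,
                               mode = c("no_interaction", "interaction_inflated")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 0.5)
  design <- attr(data, "design")
  if (is.null(design)) design <- .design_from_records(data)
  d <- .design_dims(design)
  if (d$r < 2)
    stop("cannot estimate natural variation: at least 2 reference varieties ",
         "are needed", call. = FALSE)
  decomp <- decompose_trial(data, design)
  est <- estimate_varcomps(decomp, design)
  if (mode == "no_interaction") {
    err <- .pooled_error(decomp)
    ms_ref <- .anova_get(decomp, "genotype_within_reference")
    v_g <- max((ms_ref - err$ms) / (d$s * d$b), 0)
    baseline <- v_g
  } else {
    v_g <- est$estimate[est$component == "genotype"]
    baseline <- v_g + est$estimate[est$component == "interaction_reference"]
  }
  var_d <- .contrast_variance(decomp, d, mode)
  hw <- qt(1 - alpha, d$r - 1L) * sqrt(baseline + var_d)
  structure(c(lower = -hw, upper = hw), v_g = v_g, baseline = baseline,
            contrast_variance = var_d, df = d$r - 1L, mode = mode)
}

#' Equivalence test of the GMO against the reference population
#'
#' TOST-style verdict for the difference between the GMO mean and the
#' reference-population mean: `EQUIVALENT` iff the \eqn{1-2\alpha} confidence
#' interval lies entirely inside the limits, `NOT_EQUIVALENT` iff it lies
#' entirely outside on one side, `INCONCLUSIVE` otherwise.
#'
#' With study-specific limits (the default) both the limits and the CI use
#' the reference-population decomposition (V_g in the baseline). With
#' user-fixed limits the test is the traditional fixed-margin TOST: the CI's
#' error term is the group-pooled residual (variety identity ignored), so the
#' verdict depends on the reference varieties only through their mean.
#'
#' @param data A complete balanced `trial_dataset`.
#' @param alpha Size of each one-sided test; CI level is \eqn{1-2\alpha}
#'   (default 0.05, independent of the difference test's 0.1).
#' @param fixed_limits Optional `c(lower, upper)` overriding the
#'   study-specific limits.
#' @param mode Baseline construction for study-specific limits; see
#'   [equivalence_limits()].
#' @return An `equivalence_test` object: `estimate`, `conf_int`, `limits`,
#'   `v_g`, `verdict`, `limits_source`, `df`, `alpha`, `mode`.
#' @export
equivalence_test <- function(data, alpha = 0.05, fixed_limits = NULL,
                             mode = c("no_interaction", "interaction_inflated")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 0.5)
  design <- attr(data, "design")
  if (is.null(design)) design <- .design_from_records(data)
  .check_test_entries(data)
  d <- .design_dims(design)
  decomp <- decompose_trial(data, design)
  est_d <- mean(data$response[data$group == "gmo"]) -
    mean(data$response[data$group == "reference"])
  if (is.null(fixed_limits)) {
    limits <- equivalence_limits(data, alpha, mode)
    v_g <- attr(limits, "v_g")
    var_d <- attr(limits, "contrast_variance")
    df <- attr(limits, "df")
    source <- "STUDY_SPECIFIC"
  } else {
    if (length(fixed_limits) != 2 || !all(is.finite(fixed_limits)) ||
        fixed_limits[1] >= fixed_limits[2])
      stop("`fixed_limits` must be c(lower, upper) with lower < upper", call. = FALSE)
    limits <- c(lower = fixed_limits[[1]], upper = fixed_limits[[2]])
    # traditional fixed-margin TOST: error pooled over genotypes within group,
    # invariant to how reference plots are labelled by variety
    strata_fixed <- c("site", "block_in_site", "genotype_group")
    ss_err <- attr(decomp, "total_ss") - sum(decomp$ss[decomp$stratum %in% strata_fixed])
    df <- attr(decomp, "total_df") - sum(decomp$df[decomp$stratum %in% strata_fixed])
    var_d <- (ss_err / df) * (1 / (d$s * d$b) + 1 / (d$s * d$b * d$r))
    v_g <- NA_real_
    source <- "USER_FIXED"
  }
  ci <- est_d + c(-1, 1) * qt(1 - alpha, df) * sqrt(var_d)
  verdict <- if (ci[1] >= limits[[1]] && ci[2] <= limits[[2]]) "EQUIVALENT"
  else if (ci[1] > limits[[2]] || ci[2] < limits[[1]]) "NOT_EQUIVALENT"
  else "INCONCLUSIVE"
  structure(list(estimate = est_d, conf_int = ci,
                 limits = c(lower = limits[[1]], upper = limits[[2]]),
                 v_g = v_g, verdict = verdict, limits_source = source,
                 df = df, alpha = alpha, mode = mode),
            class = "equivalence_test")
}

#' @export
print.equivalence_test <- function(x, ...) {
  cat("Equivalence test: GMO vs reference population (log scale)\n")
  cat(sprintf("  estimate %.5g, %g%% CI [%.5g, %.5g]\n", x$estimate,
              100 * (1 - 2 * x$alpha), x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  limits [%.5g, %.5g] (%s%s)\n", x$limits[1], x$limits[2],
              x$limits_source,
              if (x$limits_source == "STUDY_SPECIFIC") paste0(", ", x$mode) else ""))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
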