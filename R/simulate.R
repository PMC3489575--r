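#' Simulation configuration
#'
#' Bundles a design, mean structure, variance components and a seed into one
#' reproducible configuration. The seed is recorded on every simulated dataset
#' for provenance.
#'
#' @param design A [build_design()] object.
#' @param means A [mean_structure()].
#' @param varcomps A [variance_components()].
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(design = build_design(4, 4, 6),
                              means = mean_structure(),
                              varcomps = variance_components(),
                              seed = 1L) {
  stopifnot(inherits(design, "trial_design"), inherits(means, "mean_structure"),
            inherits(varcomps, "variance_components"))
  if (!.is_count(seed)) stop("`seed` must be a single integer", call. = FALSE)
  d <- .design_dims(design)
  if (means$reference_mode == "fixed" && length(means$reference_offsets) != d$r)
    stop("`reference_offsets` must have one entry per reference variety (",
         d$r, ")", call. = FALSE)
  structure(list(design = design, means = means, varcomps = varcomps,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default simulation configuration
#'
#' The package's reference study conditions: 4 sites, 4 blocks per site,
#' 6 reference varieties, zero fixed offsets, and the stand-in log-scale
#' variance components (site 0.02, block 0.005, genotype 0.01, residual 0.01,
#' pooled interaction 0).
#'
#' @param seed Integer RNG seed.
#' @inheritParams simulation_config
#' @return A `simulation_config`.
#' @export
default_config <- function(seed = 1L, varcomps = variance_components(),
                           means = mean_structure()) {
  simulation_config(build_design(4, 4, 6), means, varcomps, seed)
}

# draw one dataset's responses; assumes the RNG state has been set.
# Canonical row order: genotype fastest, then block, then site.
.simulate_responses <- function(design, means, vc) {
  d <- .design_dims(design)
  site_eff <- rnorm(d$s, 0, sqrt(vc$site))
  block_eff <- rnorm(d$s * d$b, 0, sqrt(vc$block))          # index (block, site)
  gen_eff <- numeric(d$g)
  gen_eff[d$gmo_idx] <- means$gmo_offset
  gen_eff[d$comp_idx] <- means$comparator_offset
  gen_eff[d$ref_idx] <- if (means$reference_mode == "random")
    rnorm(d$r, 0, sqrt(vc$genotype)) else means$reference_offsets
  int_eff <- rnorm(d$g * d$s) * .interaction_sds(vc, d)      # index (genotype, site)
  resid <- rnorm(d$N, 0, sqrt(vc$residual))
  site_of <- rep(seq_len(d$s), each = d$b * d$g)
  block_in_site <- rep(rep(seq_len(d$b), each = d$g), times = d$s)
  geno <- rep(seq_len(d$g), times = d$s * d$b)
  y <- means$overall + site_eff[site_of] +
    block_eff[(site_of - 1L) * d$b + block_in_site] +
    gen_eff[geno] + int_eff[(site_of - 1L) * d$g + geno] + resid
  list(site = site_of, block = block_in_site, geno = geno, y = y, dims = d)
}

#' Simulate one multi-site trial
#'
#' Generates plot-level responses under the linear mixed model
#' \deqn{Y_{ijk} = \mu + S_i + B_{ij} + G_k + (SG)_{ik} + e_{ijk}}
#' with independent zero-mean normal site, block-within-site, site-by-genotype
#' interaction and plot-error effects at the configured variances. The GMO and
#' comparator carry fixed offsets; reference variety effects are drawn once
#' per dataset from the reference population (variance V_g) unless fixed
#' offsets are supplied.
#'
#' @param config A [simulation_config()].
#' @return A `trial_dataset` with the config's seed attached.
#' @examples
#' sim <- simulate_trial(default_config(seed = 42))
#' head(sim)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  out <- .simulate_trial_nostate(config)
  attr(out, "seed") <- config$seed
  out
}

# core used by batch/power engines (RNG state already positioned)
.simulate_trial_nostate <- function(config) {
  sim <- .simulate_responses(config$design, config$means, config$varcomps)
  glab <- config$design$genotypes$label
  ggrp <- config$design$genotypes$group
  df <- data.frame(site = sim$site, block = sim$block,
                   genotype = glab[sim$geno], group = ggrp[sim$geno],
                   response = sim$y, stringsAsFactors = FALSE)
  structure(df, class = c("trial_dataset", "data.frame"),
            design = config$design, canonical = TRUE)
}

#' Simulate a batch of independent trials
#'
#' Each replicate runs on its own RNG substream: a table of per-replicate
#' seeds is derived deterministically from the master seed, so replicate `r`
#' of a batch can be regenerated in isolation (`reps = r`) and equals
#' replicate `r` of the full batch.
#'
#' @param config A [simulation_config()]; its `seed` is the master seed.
#' @param n_reps Number of replicates (\eqn{\ge 1}).
#' @param reps Optional integer vector selecting which replicates to
#'   materialize (all by default).
#' @return A list of `trial_dataset`s, named `rep<r>`.
#' @export
simulate_batch <- function(config, n_reps, reps = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!.is_count(n_reps) || n_reps < 1)
    stop("`n_reps` must be an integer >= 1", call. = FALSE)
  seeds <- .substream_seeds(config$seed, n_reps)
  if (is.null(reps)) reps <- seq_len(n_reps)
  stopifnot(all(reps >= 1), all(reps <= n_reps))
  out <- lapply(reps, function(r) {
    set.seed(seeds[[r]])
    ds <- .simulate_trial_nostate(config)
    attr(ds, "seed") <- seeds[[r]]
    attr(ds, "replicate") <- r
    ds
  })
  names(out) <- paste0("rep", reps)
  out
}

# deterministic per-replicate seeds from a master seed
.substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
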