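# shared fixtures, all built in code

# deterministic dataset from a cell-value function f(site, block, genotype_index)
make_cell_dataset <- function(design, f) {
  g <- nrow(design$genotypes)
  grid <- expand.grid(genotype = seq_len(g), block = seq_len(design$n_blocks),
                      site = seq_len(design$n_sites), KEEP.OUT.ATTRS = FALSE)
  rec <- data.frame(site = grid$site, block = grid$block,
                    genotype = design$genotypes$label[grid$genotype],
                    group = design$genotypes$group[grid$genotype],
                    response = mapply(f, grid$site, grid$block, grid$genotype))
  trial_dataset(rec, design)
}

# the fixed 2-site, 2-block, 3-genotype toy trial used by the arithmetic oracles
toy_dataset <- function() {
  design <- build_design(2, 2, 1)
  y <- c(4.10, 4.30, 3.90,  4.25, 4.15, 4.05,
         4.60, 4.20, 4.35,  4.50, 4.40, 4.20)
  make_cell_dataset(design, function(s, b, k) y[(s - 1) * 6 + (b - 1) * 3 + k])
}

quick_cfg <- function(seed = 1L, interaction = 0, ...) {
  default_config(seed = seed,
                 varcomps = variance_components(interaction = interaction, ...))
}

# Monte-Carlo null rejection rate of a difference-test variant
null_rejection_rate <- function(seed, ratio, n_reps, test, alpha = 0.1) {
  grid <- study_grid(mu_gmo_values = 0, interaction_ratios = ratio,
                     n_reps = n_reps, alpha = alpha, test = test,
                     base_config = default_config(seed = seed))
  run_power_study(grid)$rate
}
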