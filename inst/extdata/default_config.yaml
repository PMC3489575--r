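# Default simulation configuration (every package default stated literally).
# Responses are on the log scale; all variances are log-scale units squared.
design:
  sites: 4          # >= 2
  blocks: 4         # blocks per site, >= 2
  references: 6     # reference varieties, >= 1
means:
  overall: 0        # grand mean
  gmo_offset: 0     # fixed GM-entry offset (mu_GMO)
  comparator_offset: 0
varcomps:
  site: 0.02
  block: 0.005
  genotype: 0.01    # between-reference-variety variance (V_g)
  interaction: 0    # pooled site x genotype variance; or supply
                    # interaction_test + interaction_reference instead
  residual: 0.01
seed: 1
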