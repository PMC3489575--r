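# gmtrials

Simulation and interaction-aware analysis of multi-site GM crop trials.

## The problem

Compositional safety assessment of a genetically modified (GM) crop variety
rests on multi-site field trials: at each of *s* sites, a randomized
complete block design grows the GM entry, its conventional comparator and a
set of *r* commercial reference varieties once per block. On the log scale
the plot response follows the linear mixed model

    Y_ijk = mu + Site_i + Block_ij + Genotype_k + (Site x Genotype)_ik + e_ijk

with the genotype factor partitioned into a fixed three-level group (GMO /
comparator / reference population) and a random genotype-within-reference
term whose variance V_g measures the reference population's natural
variation.

The package is built around a contested methodological question: what
happens to the GMO-vs-comparator **difference test** and the
reference-based **equivalence test** when the analysis model omits the
site-by-genotype interaction. It provides, for statisticians and
regulatory-science researchers working on trial methodology:

* a **simulator** for plot-level data under the full model (pooled or
  partitioned interaction components, reference effects drawn from the
  reference population),
* a closed-form **balanced ANOVA engine**: stratum sums of squares with the
  genotype and interaction partitions, exact expected mean squares, and
  method-of-moments variance components with zero-truncation flags,
* the **naive** (no-interaction, pooled-error) and **interaction-aware**
  (site-by-test-entry error on (s−1) df) difference tests, plus a
  genotype-by-environment interaction F test that is provably identical
  under fixed- or random-site labelling,
* **equivalence testing** with study-specific limits that put V_g in the
  baseline (TOST geometry; optional interaction-inflated baseline;
  user-fixed limits as a classical fixed-margin TOST),
* a **Monte-Carlo engine** for rejection rates and power curves over a grid
  of true GMO offsets and interaction-to-genotype variance ratios,
* CSV readers/writers and a YAML-configured command line with subcommands
  `simulate`, `analyze`, `power` and `gxe-test`, e.g.

  ```sh
  Rscript "$(Rscript -e 'cat(system.file("exec","gmtrials",package="gmtrials"))')" \
      simulate --seed 1 --out trial.csv
  ```

## Worked example

```r
library(gmtrials)

cfg <- default_config(seed = 2026,
                      varcomps = variance_components(interaction = 0.005))
trial <- simulate_trial(cfg)

decompose_trial(trial)
#> Balanced trial ANOVA decomposition
#>                    stratum df       ss       ms
#>                       site  3 0.908421 0.302807
#>              block_in_site 12 0.628942 0.052412
#>             genotype_group  2 0.099268 0.049634
#>  genotype_within_reference  5 1.361322 0.272264
#>                site_x_test  3 0.176260 0.058753
#>           site_x_reference 15 0.323079 0.021539
#>               site_x_group  3 0.020040 0.006680
#>                   residual 84 0.803155 0.009561
#> total SS 4.32049 on 127 df

difference_test(trial, method = "naive")
#> naive difference test (GMO - comparator, log scale)
#>   estimate -0.10693, SE 0.039679, t = -2.695 on 105 df, p = 0.008202
#>   90% CI: [-0.17278, -0.041082]

difference_test(trial, method = "interaction")
#> interaction-aware difference test (GMO - comparator, log scale)
#>   estimate -0.10693, SE 0.085698, t = -1.248 on 3 df, p = 0.3006
#>   90% CI: [-0.30861, 0.094749]
```

The same simulated trial, two conclusions. The true GMO offset here is zero
and a real site-by-genotype interaction (sigma² = 0.005) is present: the
naive analysis pools that interaction into a 105-df error term, reports
SE 0.040 and "detects" a difference at p = 0.008; the interaction-aware
analysis tests the same estimate against the site-by-test-entry mean square
on 3 df (4 sites, 2 test entries), reports the honest SE 0.086, and finds
nothing. The interaction itself is clearly there:

```r
gxe_interaction_test(trial)
#> Site x test-entry interaction test (site random)
#>   F = 6.1449 on (3, 84) df, p = 0.0007905

equivalence_test(trial)
#> Equivalence test: GMO vs reference population (log scale)
#>   estimate -0.071488, 90% CI [-0.19278, 0.049806]
#>   limits [-0.28392, 0.28392] (STUDY_SPECIFIC, no_interaction)
#>   verdict: EQUIVALENT
```

How often does the naive test cry wolf? Null rejection rates (true offset
0, nominal level 0.1, 1000 replicates per cell) across interaction levels
expressed as ratios of the interaction variance to V_g:

```r
grid <- study_grid(mu_gmo_values = 0, interaction_ratios = c(0, 0.5, 1),
                   n_reps = 1000, base_config = default_config(seed = 11),
                   test = "naive")
power_curve_table(run_power_study(grid))
#>   mu_gmo ratio  rate          se n_reps
#> 1      0   0.0 0.109 0.009854897   1000
#> 2      0   0.5 0.228 0.013267102   1000
#> 3      0   1.0 0.330 0.014869432   1000
```

At its nominal conditions (ratio 0) the naive test is fine; with an
interaction half the size of the genetic variance its false-positive rate
more than doubles, and at equal size it more than triples. The
interaction-aware test under the identical data streams holds its level at
every ratio (0.100, 0.086, 0.113 — all within two binomial SEs of 0.10).
Full power curves over the GMO offset grid come from the same engine
(`study_grid()` defaults), with `plot_power_curves()` for one panel per
ratio.

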