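---
title: "Interaction-aware difference and equivalence testing in multi-site GM crop trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-aware difference and equivalence testing in multi-site GM crop trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmtrials)
```

## The problem

Regulatory compositional assessment of a genetically modified (GM) crop
variety compares it against its near-isogenic conventional comparator and
against the natural variation of commercial non-GM ("reference") varieties.
The standard field layout is a randomized complete block design (RCBD)
replicated at several sites: every genotype — one GM entry, one comparator,
and `r` reference varieties — appears once in each of `b` blocks at each of
`s` sites.

On a log-transformed response the analysis model is the linear mixed model

$$Y_{ijk} = \mu + S_i + B_{ij} + G_k + (SG)_{ik} + e_{ijk},$$

with site \(S_i\), block-within-site \(B_{ij}\), genotype \(G_k\),
site-by-genotype interaction \((SG)_{ik}\) and plot error \(e_{ijk}\). The
genotype factor is split into a three-level fixed *group* factor (GM entry,
comparator, reference population) and a random genotype-within-reference
term whose variance \(V_g\) measures the genetic variation of the reference
population. The interaction splits correspondingly into site-by-test-entry,
site-by-reference-variety and a site-by-group remainder.

The package exists to study a contested methodological point: what happens
to the GM-vs-comparator **difference test** and to reference-based
**equivalence testing** when the analysis model *omits* the interaction
terms. With a real site-by-genotype interaction present, the no-interaction
("naive") analysis pools all interaction variation into the plot error,
understates the standard error of the GMO−comparator contrast, carries far
too many degrees of freedom, and rejects a true null far more often than its
nominal level. The interaction-aware analysis tests the same contrast
against the site-by-test-entry mean square on \((s-1)(t-1)\) df
(with \(t = 2\) test entries: 3 df in a 4-site trial) and holds its level.

## What the simulator emulates

`simulate_trial()` draws every random effect of the model above
independently from zero-mean normal distributions on the log scale. The
model names the scale but not the distribution family; normality is the
natural choice inside a linear-mixed-model framework and makes every
closed-form expectation in the package exact rather than approximate.
Reference-variety effects are redrawn for every simulated dataset — they
are a random sample from the reference population, and holding them fixed
across replicates would understate the study-to-study variability that the
equivalence critique is about. Fixed per-variety offsets are available
(`reference_mode = "fixed"`) for constructing deterministic scenarios.

What the generator does **not** emulate: non-normal or heavy-tailed errors,
limit-of-detection censoring, correlation across analytes (each run is one
endpoint), incomplete or unbalanced layouts, and multi-year structure.
Passing Monte-Carlo checks here therefore shows that the *procedures* behave
as the theory says under the stated model — not that any particular real
trial satisfies that model.

### Default study conditions

The defaults are the package's fixed reference conditions, chosen once:

* **Design: 4 sites, 4 blocks/site, 6 reference varieties** (128 plots).
  Four sites matches the worked df accounting that motivates the 3-df
  interaction test; block and reference counts are typical of compositional
  trials and are freely configurable.
* **Variance components (log scale): site 0.02, block 0.005, genotype
  (V_g) 0.01, residual 0.01, interaction 0.** A residual and genetic
  standard deviation of 0.1 on the natural-log scale corresponds to roughly
  a 10% coefficient of variation — a realistic magnitude for crop
  composition analytes — with site-to-site variation somewhat larger and
  block variation smaller. These are documented stand-ins: the exact
  components used in the published simulation study this package replays
  are recorded only in a companion reference, so
  `varcomp_profile("companion-paper")` is a deliberately empty slot that
  accepts those values when a user has them. Rejection rates under the
  stand-ins reproduce the *qualitative* headline (severe inflation of the
  naive test) rather than any specific printed rate.
* **Interaction levels** are expressed as ratios of
  \(\sigma^2_{SxG}\) to \(V_g\): 0, 0.5 and 1 — the no-interaction world
  plus the two survey-motivated levels.
* **GMO offset grid** `0, 0.02, 0.05, 0.07, 0.10, 0.12, 0.15, 0.17, 0.20,
  0.22, 0.25`: the printed grid ends in an ellipsis after 0.1; it is
  resolved here by continuing the alternating +0.02/+0.03 spacing, and the
  grid is an ordinary argument of `study_grid()` so any other resolution is
  one keystroke away.
* **alpha = 0.1** for the difference test (the contested nominal level) and
  **alpha = 0.05** per one-sided test for equivalence; both are parameters
  everywhere, never constants.

## The ANOVA engine

Because the design is complete and balanced, every stratum sum of squares
is a closed-form function of cell means and the strata are mutually
orthogonal; `decompose_trial()` is pure arithmetic with no iterative
fitting. The strata are: site; block-within-site; genotype-group (2 df);
genotype-within-reference (\(r-1\) df); site-by-test-entry (\(s-1\) df, the
GMO−comparator contrast by site); site-by-reference
(\((s-1)(r-1)\) df); the site-by-group remainder (\(s-1\) df); and residual
(\(s(b-1)(g-1)\) df).

Expected mean squares are not transcribed from a textbook table. For a
stratum with quadratic form \(A\) and a random effect with design matrix
\(Z\), \(\mathrm{E}[Y'AY]\) contains \(\sigma^2 \,\mathrm{tr}(AZZ')\), and
\(\mathrm{tr}(AZZ')\) equals the stratum SS applied column-wise to \(Z\).
`expected_mean_squares()` therefore runs the decomposition arithmetic on
each indicator column of each effect's design matrix — exact coefficients,
by the same code path that decomposes data, with fixed offsets contributing
no noncentrality. This is what makes the EMS both a user-facing feature and
an internal oracle: Monte-Carlo means of every stratum mean square are
checked against it in the test suite.

`estimate_varcomps()` solves the square EMS system for the six components
(site, block, V_g, the two interaction parts, residual) by method of
moments. Balanced method-of-moments is exact, closed-form and unbiased
before truncation, which is why it is primary here; REML adds nothing for
complete balanced data and is out of scope (unbalanced data are refused
with a pointer, not silently mis-decomposed). Negative solutions — expected
in small designs when a true component is near zero — are truncated to zero
and flagged, with the untruncated value retained in the `raw` column so
bias checks can average it.

## The two difference tests

Both variants estimate the same quantity, the difference of the GMO and
comparator raw means \(\hat\delta = \bar y_{GMO} - \bar y_{C}\).

* **Naive** (`method = "naive"`): all interaction SS are pooled into error;
  \(SE^2 = 2\,MSE_{pool}/(sb)\) on the pooled df
  (\((g-1)(sb-1)\) in the default design: 105). This closed form is exactly
  the no-interaction mixed-model test in the balanced case — the test suite
  verifies the equivalence against an independent `lm()` fit — so the
  Monte-Carlo engine never needs an iterative fitter.
* **Interaction-aware** (`method = "interaction"`):
  \(SE^2 = 2\,MS_{SxT}/(sb)\) on \(s-1\) df. Because
  \(\mathrm{Var}(\hat\delta) = 2(\sigma^2_e + b\,\sigma^2_{SxT})/(sb)\) and
  \(MS_{SxT}\) estimates exactly \(\sigma^2_e + b\,\sigma^2_{SxT}\)
  independently of \(\hat\delta\), the statistic is an exact \(t\) on
  \(s-1\) df at **every** interaction level — the formal reason the
  corrected test holds its level where the naive one does not. When
  \(MS_{SxT} < MS_{resid}\) the interaction mean square is still used
  unpooled (the variant's honest error term); `pool_if_smaller = TRUE`
  exposes the pooling alternative rather than hard-coding either policy.

`gxe_interaction_test()` reports \(F = MS_{SxT}/MS_{resid}\). In the
balanced case the statistic is the same whether the site factor is labelled
fixed or random; the two labels run genuinely different code (stratum
arithmetic vs nested fixed-effects `lm()` fits) and are required to agree to
machine precision, turning a conceptual identity into a regression test.

## Equivalence against a reference population

The reference is a *population*, not a single treatment, so the
between-variety variance \(V_g\) belongs in the baseline that sets the
equivalence limits. The exact published limit formulas live in a companion
methodology paper (and were themselves subject to a published correction),
so `equivalence_limits()` implements the stated principle as a documented
stand-in, isolated in one function so the companion formulas can be swapped
in without touching callers:

$$\pm\; t_{1-\alpha,\;r-1}\,\sqrt{\;\hat V_g + \widehat{\mathrm{Var}}(\bar y_{GMO}-\bar y_{REF})\;}.$$

The verdict uses standard two-one-sided-tests geometry at CI level
\(1-2\alpha\): `EQUIVALENT` if the CI is inside the limits,
`NOT_EQUIVALENT` if entirely outside on one side, `INCONCLUSIVE` otherwise.
Three design decisions deserve explanation:

* **Interaction modes.** Should limits reflect that reference varieties
  perform differently at different sites? The question is genuinely open,
  so both answers ship: the default computes the baseline from the
  no-interaction decomposition, and `mode = "interaction_inflated"` adds
  the site-by-reference component to the baseline. Comparing the two is a
  built-in sensitivity analysis.
* **User-fixed limits are a different test.** With
  `fixed_limits = c(lo, hi)` the margin no longer comes from the observed
  references, and the CI deliberately switches to the group-pooled error
  (the residual of the site/block + group model). Consequence: the verdict
  depends on the reference varieties only through their mean — exactly the
  behaviour a pre-specified-margin TOST should have, and a property the
  test suite checks by reshuffling variety labels among reference plots.
* **Study-specificity is observable, not hidden.** Because limits are a
  function of whichever reference set was drawn, two simulated studies with
  identical true parameters can return different verdicts for the same GMO;
  the simulator plus `equivalence_test()` reproduce that disagreement
  directly, which is the point of modelling the reference set as random.

## The Monte-Carlo engine

`run_power_study()` crosses the GMO offset grid with the interaction ratios,
simulates `n_reps` trials per cell (default 1000), applies the chosen
difference-test variant at `alpha`, and reports rejection counts, rates and
the plain binomial standard error \(\sqrt{p(1-p)/n}\) with no continuity
correction. Rows with zero offset estimate the type-I error rate; the rest
trace the power curve, one panel per ratio (`plot_power_curves()`).

Randomness is managed for exact reproducibility: the master seed yields a
table of cell seeds, each cell seed yields a table of replicate seeds
(plain `sample.int()` draws), so a single replicate of a single cell can be
regenerated in isolation and a fixed seed makes the whole study
bit-identical across runs.

## Numerical choices and degenerate inputs

* All decomposition arithmetic is on means; stratum SS are sums of squares
  and non-negative by construction. The site-by-group remainder is obtained
  by orthogonal subtraction and clamped at zero only against floating-point
  dust (the identity "stratum SS sum to total SS" is tested at 1e-9
  relative tolerance).
* Zero configured variances produce exactly degenerate draws (`rnorm` with
  `sd = 0`), so the all-zero configuration returns a constant dataset, not
  a nearly-constant one.
* A zero standard error with a zero estimate reports \(t = 0,\ p = 1\); with
  a nonzero estimate, \(p = 0\) — the plot-for-plot-identical corner cases.
* `alpha` is accepted up to 1; the boundary value is admitted so simulation
  engines can exercise the reject-everything corner (the CI then degenerates
  to a point).
* Validation is report-style where the contract asks for it
  (`validate_dataset()` lists every missing/duplicated/non-finite cell) and
  fail-fast everywhere else, with errors naming the offending argument, row
  or group.

## Problem sizes used by the shipped checks

The package's own test suite runs its Monte-Carlo checks at 1000 replicates
per rejection-rate cell (the convention for rates reported with ±SE near
0.014–0.015), 20,000 replicates for the EMS agreement check, 5,000 for
variance-component unbiasedness, and a few hundred for the cheaper
distributional sanity checks — sizes chosen so three-SE Monte-Carlo bands
are tight enough to be informative while the whole suite stays comfortably
interactive.

## Known limitations

* Complete balanced designs only; unbalanced or incomplete layouts (eg
  different reference sets per site) need REML machinery that is
  deliberately out of scope.
* Single endpoint; no multiplicity handling across analytes.
* The equivalence-limit construction is a principled stand-in for the
  companion methodology's exact formulas (see above).
* Per-site ("individual") difference or equivalence verdicts are not
  provided; both sides of the underlying debate regard their interpretation
  as unresolved.
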