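---
title: "Benchmarking methylation imputation across representations and missingness mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking methylation imputation across representations and missingness mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r load}
library(methylmiss)
```

## The scientific problem

DNA methylation microarrays (Illumina 450K/EPIC and similar platforms) report,
for each CpG site and each sample, the fraction of DNA molecules that carry a
methyl group. Quality filtering — detection p-values, probe masking,
cross-sample harmonisation — removes individual measurements, so real cohort
matrices routinely contain missing entries, and a small set of unreliable CpGs
accounts for a disproportionate share of them. Downstream methods (EWAS
regressions, clustering, clocks) usually need complete matrices, so the missing
entries are imputed.

Two facts make this problem less routine than generic matrix completion:

1. **Two competing representations.** The same measurement can be expressed as
   a *beta-value* in `[0, 1]` (the methylated fraction of total signal) or as
   an *M-value*, its base-2 logit. Beta is bounded and interpretable but
   heteroscedastic; M is unbounded and closer to homoscedastic but stretches
   the extremes. An imputation algorithm can be run on either scale, and the
   choice changes its accuracy.
2. **Structured missingness.** Entries are not removed at random. Probe
   failure correlates with signal intensity, which correlates with the
   methylation level itself — the textbook *missing not at random* (MNAR)
   situation, where the probability of being missing depends on the value that
   is missing.

`methylmiss` packages a controlled study of this interaction: generate
realistic synthetic cohorts where the ground truth is known, remove entries
under explicit mechanisms, impute on both scales with seven algorithms, and
compare accuracy with paired nonparametric tests.

## Representations

`beta_from_intensities()` and `m_from_intensities()` implement the
intensity-level definitions (offsets 100 and 1 respectively, negative
intensities clamped to zero). `beta_to_m()` / `m_to_beta()` implement the
base-2 logit link between the two scales, with `eps = 1e-6` clipping so that
boundary beta-values map to finite M-values:

```{r repr}
beta_to_m(0.8)   # 2
m_to_beta(2)     # 0.8
```

`methyl_matrix()` wraps a numeric matrix (samples in rows, CpGs in columns)
with a scale tag, and `convert_matrix()` changes representation for the
observed entries while leaving `NA`s in place. Whatever scale an imputation
runs on, **evaluation always happens on the beta scale**: predictions made on
the M scale are mapped back through `m_to_beta()` before errors are computed,
so the two pipelines are compared in the same units.

## The synthetic cohort generator

Real reference cohorts cannot ship with a package, and for benchmarking we
need the true value behind every masked entry anyway. `generate_cohort()`
draws cohorts that reproduce the qualitative structure of array beta-values:

* **Bimodality.** Each CpG belongs to one of three classes — unmethylated,
  intermediate, methylated — with mean beta 0.08 / 0.50 / 0.92 and mixture
  proportions 0.40 / 0.20 / 0.40. Class means are jittered on the logit scale
  (`mu_jitter_sd = 0.5`) so the marginal distribution is a smooth two-horned
  density rather than three spikes.
* **Heteroscedasticity.** Per-entry values are drawn from
  `Beta(mu * kappa, (1 - mu) * kappa)`, whose variance `mu(1-mu)/(kappa+1)`
  peaks at mid-range beta and vanishes at the extremes — exactly the pattern
  seen on arrays. `kappa = 60` for "healthy" cohorts; `status = "disease"`
  uses `kappa = 15`, modelling the greater dispersion of tumour methylomes.
* **Inter-sample correlation.** A rank-3 latent factor model
  (`loading_sd = 0.12`) shifts each sample's logit means coherently, giving
  regression-based imputers something real to exploit.
* **Unreliable probes.** A fixed fraction (11%) of CpGs is flagged
  high-propensity with a missingness weight 30 times the baseline. Most of
  them (70%) have their baseline levels re-drawn around beta 0.65 on the
  logit scale (`N(qlogis(0.65), 0.5)`), concentrating frequently-missing CpGs
  in the mid-to-upper beta range — matching the empirical observation that
  probes which fail often sit away from the stable extremes.

These defaults are frozen design choices of the generator, not quantities a
user is expected to tune; they were chosen so that the generator's *emergent*
statistics land where array data does (fraction of chronically missing CpGs,
location of the missing-prone values) while keeping the model minimal. All of
them can still be overridden through `cohort_config()` for sensitivity
analyses.

`apply_baseline_missingness()` overlays propensity-weighted missingness at a
4% overall rate, after which roughly 11% of CpGs are missing in more than 20%
of samples of a 100-sample cohort — the chronic-probe pattern described
above.

## Missingness mechanisms

`simulate_missingness(x, mechanism, fraction)` removes exactly
`round(fraction * n_entries)` observed entries (default fraction 0.03):

* **MCAR** — uniformly at random.
* **MAR** — probability proportional to a per-CpG weight (by default the
  cohort's propensity weights, estimable from observed missingness via
  `estimate_mar_weights()`); depends on which probe, not on the value.
* **MNAR low/mid/high** — each removed entry is, with probability 0.70, drawn
  from the entries whose *true* beta lies in the target range
  ([0, 0.2], [0.4, 0.6], [0.8, 1.0] respectively) and otherwise from anywhere.
  If a range pool is exhausted mid-draw the remaining draws fall back to the
  general pool and are counted in `mechanism$n_redirected`.

Every simulator returns the masked matrix plus a positions table carrying the
ground truth, so scoring never needs the original cohort object.

## Imputation methods

`impute(x, spec)` dispatches on `imputer_spec(method, ...)`:

| method | idea |
|---|---|
| `mean` | column (CpG) mean |
| `knn` | k-nearest CpGs by shared-row RMS distance, inverse-distance weights |
| `svd_iter` | iterate rank-`r` truncated SVD reconstruction |
| `soft_svd` | iterate soft-thresholded SVD (singular values shrunk by a fixed `lambda`) |
| `iter_pca` | EM-style regularised iterative PCA (centred, shrunk eigenvalues) |
| `chained_reg` | per-CpG regression on all other CpGs, cycled until error rises; linear (dual Gram solve) or random-forest learner |
| `methylimp` | multi-output linear model from complete rows via pseudoinverse, grouped by missingness pattern |

All methods accept matrices on either scale; when run on the beta scale,
predictions are clipped back into `[0, 1]`. Columns with no observed values
cannot be imputed by any of these methods and are reported in
`out$unimputable` rather than silently filled.

## Evaluation and comparison

`score_imputation()` computes MAE and RMSE of imputed versus true values on
the beta scale, plus errors binned by the *true* value into ten equal-width
beta ranges (`profile_by_range()` aggregates and plots these — mid-range
entries are consistently the hardest). `summarize_table()` /
`comparison_report` then:

1. average each (method, scale) cell over datasets within a repetition —
   repetitions are the paired unit;
2. run paired Wilcoxon signed-rank tests between the beta and M variants of
   each method, Benjamini–Hochberg-adjusted across methods
   (`paired_wilcoxon()`, `bh_adjust()`, `intra_method_winner()`);
3. compute a relaxed best set: every cell not significantly beaten by any
   other cell (`best_method_set()`).

With fewer than five repetitions the signed-rank test is undefined at any
reasonable size, so reports fall back to summary statistics only.

## The full pipeline

`run_benchmark()` crosses cohorts x mechanisms x scales x methods x
repetitions, with one important invariant: the *same* masked entries are used
for the beta and M variants of a task (the mask seed is derived from cohort,
mechanism and repetition only), so scale comparisons are paired at the entry
level. Per-task failures are isolated and recorded, partial results are cached
as CSV keyed by a design signature, and artifacts (`scores.csv`,
`per_bin.csv`, `range_profile.csv`, `summary_tables.txt`, `report.json`) are
written if `outdir` is set.

```{r pipeline}
cfg <- benchmark_config(
  cohorts = list(demo = cohort_config(n_samples = 30, n_cpgs = 1000)),
  mechanisms = c("MCAR", "MNAR_MID"),
  methods = c("mean", "knn", "methylimp"),
  repetitions = 10
)
res <- run_benchmark(cfg)
res$reports
autoplot(res$profile)
```

The full factorial design at the default settings books 100 repetitions per
mechanism, i.e. 500 runs per (dataset, method) per scale and 1000 per
(dataset, method) overall — sized so each cell supports the signed-rank
comparisons. The problem sizes used throughout the package's own tests
(cohorts of 50 samples x 5000 CpGs, reduced to 40 x 2000 where all seven
methods are crossed with both cohort statuses) are a pragmatic choice: large
enough that binned error profiles and mechanism orderings are stable, small
enough to run on one CPU in minutes.

## What the generator does and does not emulate

The generator reproduces the *statistical* features that drive imputation
difficulty: bimodality, mid-range heteroscedasticity, low-rank inter-sample
correlation, propensity-concentrated missingness, and value-dependent (MNAR)
removal. It does not model genomic context (CpG islands, chromatin state),
probe chemistry (Type I/II bias), batch effects, or sex chromosomes; results
should be read as statements about representations and mechanisms, not about
any particular platform.

Two behavioural notes worth knowing:

* In the high-dispersion disease regime (`kappa = 15`) the advantage of
  regression-based methods over the column mean shrinks and can invert at
  small sample sizes — with that much biological noise there is less
  predictable structure to borrow. The qualitative claim "regression beats
  mean" is a statement about the default (healthy) regime.
* `chained_reg` with the linear learner can overfit when samples barely
  outnumber CpGs; its stop-on-error-increase rule contains, but does not
  eliminate, this.

## Numerical choices

* `m_to_beta()` uses a sign-branched logistic so large `|M|` cannot overflow,
  and clamps its output away from exactly 0 and 1 (floating-point saturation)
  so round trips through `beta_to_m()` stay finite.
* `knn` computes shared-row RMS distances via cross-products rather than
  per-pair loops; ties are broken by column index for determinism.
* `methylimp` and `chained_reg` solve least-squares through a
  ridge-of-last-resort pseudoinverse / PSD solve, so collinear CpGs degrade
  gracefully instead of erroring.
* All stochastic steps take explicit seeds; derived seeds are produced by a
  32-bit FNV-1a hash of the base seed and the task labels, keeping every seed
  below 2^31 and independent across tasks.
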