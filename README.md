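# methylmiss

Benchmarking missing-value imputation for DNA methylation data, across the
two standard representations (beta-values and M-values) and across explicit
missing-data mechanisms.

## The problem

Methylation arrays report, per CpG site and sample, the fraction of DNA
molecules carrying a methyl group. Quality filtering leaves real cohort
matrices full of holes — and the holes are not random: probe failure
correlates with the methylation level itself, the classic *missing not at
random* (MNAR) situation. Before downstream analysis the holes are imputed,
and two design decisions quietly shape the result:

* **Representation.** The same measurement can be expressed as a beta-value
  in `[0, 1]` or as its base-2 logit, the M-value. Imputation can run on
  either scale.
* **Algorithm.** From the column mean up through k-NN, low-rank matrix
  completion, iterative PCA, chained regression and multi-output linear
  models on complete rows.

`methylmiss` makes the interaction between representation, algorithm and
missingness mechanism measurable: it generates synthetic cohorts with known
ground truth that reproduce the bimodal, heteroscedastic, correlated
structure of array beta-values; removes entries under MCAR, MAR and
range-targeted MNAR mechanisms; imputes with seven methods on both scales;
scores everything on the beta scale (MAE, RMSE, per-beta-range profiles);
and compares cells with paired Wilcoxon signed-rank tests under
Benjamini–Hochberg correction.

## Worked example

Generate a cohort, knock out 3% of entries targeting mid-range beta-values,
impute on both scales with the multi-output linear model, and score on the
beta scale:

```r
library(methylmiss)

coh <- generate_cohort(cohort_config(n_samples = 30, n_cpgs = 1500, seed = 11))
md  <- simulate_missingness(coh$data, "MNAR_MID", fraction = 0.03, seed = 12)
nrow(md$positions)
#> [1] 1350

out_beta <- impute(md$matrix, imputer_spec("methylimp"))
out_m    <- impute(convert_matrix(md$matrix, "M"), imputer_spec("methylimp"))

dplyr::bind_rows(
  score_imputation(md, out_beta, method = "methylimp", scale = "beta"),
  score_imputation(md, out_m,    method = "methylimp", scale = "M")
)[, c("method", "scale", "mechanism", "n_scored", "mae", "rmse")]
#> # A tibble: 2 × 6
#>   method    scale mechanism n_scored    mae   rmse
#>   <chr>     <chr> <chr>        <int>  <dbl>  <dbl>
#> 1 methylimp beta  MNAR_MID      1350 0.0486 0.0613
#> 2 methylimp M     MNAR_MID      1350 0.0490 0.0624
```

The full factorial benchmark crosses cohorts × mechanisms × scales ×
methods × repetitions, reuses identical masks across the two scales so
comparisons are paired at the entry level, and reports per-stratum tables:

```r
cfg <- benchmark_config(
  cohorts      = list(demo = cohort_config(n_samples = 25, n_cpgs = 800, seed = 5)),
  mechanisms   = c("MCAR", "MNAR_MID"),
  methods      = c("mean", "knn", "methylimp"),
  repetitions  = 8, base_seed = 42
)
res <- run_benchmark(cfg, quiet = TRUE)
res$reports[[1]]
#> Stratum: MCAR / healthy (alpha = 0.05, 8 repetitions)
#> method     MAE M             MAE beta          RMSE M            RMSE beta       
#> knn        0.040 ±0.002      0.040 ±0.002      0.054 ±0.002      0.054 ±0.002    
#> mean       0.041 ±0.001*     0.041 ±0.001      0.056 ±0.002      0.056 ±0.002*   
#> methylimp  **0.038 ±0.002**  **0.039 ±0.001**  **0.051 ±0.002**  **0.051 ±0.002**
```

A `*` marks the scale that significantly wins within a method; `**bold**`
cells belong to the relaxed best set (never significantly beaten).
`autoplot(res$profile)` plots error against the true beta range — mid-range
entries are consistently the hardest to impute. `tidy()` and `glance()`
methods give tibble views of every result object.

A command-line wrapper around the same pipeline ships in
`inst/scripts/run_benchmark.R` (installed under
`system.file("scripts", package = "methylmiss")`).

See the vignette (`vignettes/methylation-imputation.Rmd`) for the generator's
design, the mechanism definitions, method details and known limitations.

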