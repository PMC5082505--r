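# lesionconn

Quantifying the functional-connectivity consequences of focal brain
lesions from resting-state fMRI — for researchers studying *connectional
diaschisis* (altered coupling between regions distant from a lesion) and
*connectomic diaschisis* (altered whole-network graph properties), in
designs that compare a small patient group (or a single case) against
controls.

## What it computes

**Connectivity.** For every ROI pair, a GLM regresses the target series on
the seed series plus nuisance regressors: the three artifact signals and a
second-order, lag-five Volterra expansion of the relative-displacement
motion index (90 regressors), reduced by SVD to the components explaining
99% of their variance, plus a discrete-cosine set implementing a
0.009–0.1 Hz band-pass by regression (94 components at 148 volumes,
TR = 2 s). Serial correlation is modelled as a mixture of eight
exponential covariance components (half-lives 0.5–64 TRs) plus white
noise, with hyperparameters and coefficients estimated simultaneously by
restricted maximum likelihood:

```
y = β s + X₀γ + ε,   ε ~ N(0, V),   V = Σ λₖ Qₖ,
Qₖ(t,t′) = exp(−ln2 · |t−t′| / hₖ)
```

The seed t statistic is referred to its Satterthwaite effective degrees of
freedom, ν = tr(RV)²/tr(RVRV), and converted to a calibrated standard
normal Z; Z values are symmetrized over seed/target and the cohort's mean
motion is regressed out of every edge.

**Networks and graphs.** Network block means, lesion-to-network profiles,
segregation S = mean(within-network Z) − mean(between-network Z), a group
contrast matrix with Bonferroni families, and percentile-binarized graph
metrics (global clustering, global efficiency, small-worldness = C·E,
isolate fraction) over thresholds P = 85–99% with matched edge counts
across subjects.

**Statistics.** Pooled-variance single-case t
(t = (x_p − x̄_c)/(s_c√(1+1/n_c)), df = n_c − 1), group t with a sex
covariate, Stouffer combination Z = Σzᵢ/√k, percentile-to-z conversion,
Bonferroni adjustment, Wilcoxon rank-sum.

**Synthetic cohorts.** A seeded generator plants the lesion effects
(attenuated lesion signal, reduced thalamic–precuneus coupling, increased
DMN–frontoexecutive coupling, increased within-network coupling) in
cohorts with realistic motion and artifact structure, so the entire chain
is testable without any data download. See the methods vignette
(`vignettes/lesion-connectomics-methods.Rmd`) for the model and the
calibration of its defaults.

## Worked example

```r
library(lesionconn)

spec      <- cohort_spec(n_rois = 40, partition_sizes = rep(5L, 8L),
                         n_volumes = 148)
cohort    <- generate_cohort(spec, 8, 4, seed = 7)   # 8 controls, 4 patients
partition <- generate_partition(spec)
result    <- run_pipeline(cohort, partition, run_config(seed = 7))

round(result$segregation$values[1:4], 3)
#> [1] 0.780 0.782 0.805 0.926
```

Per-subject segregation: each subject's mean within-network Z minus mean
between-network Z — here around 0.8–0.9, i.e. within-network coupling
exceeds between-network coupling by roughly one Z unit.

```r
round(c(control = result$segregation$mean_control,
        patient = result$segregation$mean_patient), 3)
#> control patient
#>   0.869   0.994
round(result$segregation$test$statistic, 2)  # patient - control, sex-adjusted
#> [1] 1.21
round(result$contrast$t_mat["thalamic", "precuneus"], 2)
#> [1] -0.75
result$log$confound_svd_m[1]; result$log$eff_df
#> [1] 14
#> [1] 39
```

Patients trend toward higher segregation (the planted connectomic
effect; at this toy size, 12 subjects and 40 ROIs, it does not reach
significance), the thalamic–precuneus block trends negative (the planted
between-network decrease), the confound SVD kept 14 components and each
edge retains 39 residual degrees of freedom — the df-corrected scale on
which all Z values live. Group tests of the graph-metric sweep are in
`result$sweep_tests` (one row per metric × threshold, Bonferroni over the
15 thresholds).

Single-case and combined statistics:

```r
res <- single_case_t(-2.3, rnorm(40))        # one patient vs 40 controls
c(res$statistic, res$df, res$p_two_tailed)
#> [1] -2.66467011 39.00000000  0.01114987
st <- stouffer_combine(c(-2.1, -1.8, -2.6, -0.9, -1.4, -2.2))
c(st$statistic, st$p_two_tailed)
#> [1] -4.490731e+00  7.097908e-06
```

The `analysis/` directory holds the numbered drivers for the full
desk-scale study (simulate → ROI-level per-edge analysis → network
contrast → connectomic sweep → neuropsychological statistics); each is a
thin script over the package functions and writes its tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_roi_connectivity.R
# ...
```

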