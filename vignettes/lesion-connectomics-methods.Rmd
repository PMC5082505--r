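---
title: "Methods: estimating connectional and connectomic consequences of focal lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating connectional and connectomic consequences of focal lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionconn)
```

# The problem

A focal brain lesion — here, bilateral hippocampal damage causing amnesia —
can alter resting-state functional connectivity far beyond the lesion site:
coupling between intact, distal regions can decrease or increase
("connectional diaschisis"), and whole-connectome graph properties such as
segregation, clustering and small-worldness can shift ("connectomic
diaschisis"). Detecting such effects with a handful of patients requires an
estimator that is honest about its degrees of freedom: resting-state series
are short, heavily confounded by head motion and physiological noise, and
serially correlated, so naive correlation statistics are badly
miscalibrated.

`lesionconn` implements the full chain: confound construction, a
ReML-based connectivity GLM with df-corrected Z statistics, network block
statistics and segregation, percentile-thresholded graph metrics, and the
single-case/group statistics used to compare a small patient group against
controls — together with a synthetic cohort generator that plants the
lesion effects, so every stage is testable end to end without any data
download.

# The connectivity model

For ROIs $i$ (target) and $j$ (seed) with standardized time courses
$y, s \in \mathbb{R}^T$, the edge model is

$$ y = \beta s + X_0 \gamma + \varepsilon, \qquad
   \varepsilon \sim N(0, V), \qquad
   V = \textstyle\sum_k \lambda_k Q_k, $$

where $X_0$ collects the nuisance regressors and the $Q_k$ are a family of
eight exponential autocorrelation components with half-lives
$\{0.5, 1, 2, 4, 8, 16, 32, 64\}$ TRs,
$Q_k(t, t') = \exp(-\ln 2\,|t - t'|/h_k)$, plus an identity (white-noise)
component. An AR(1)-plus-white model is known to be too rigid for
resting-state errors; the exponential family spans time scales from
sub-TR to minutes.

## Nuisance design

* **Motion.** The six rigid-body realignment parameters are collapsed into
  a per-volume root-mean-square relative displacement (RD) using the
  rigid-transform difference between consecutive volumes, with rotations
  weighted by a sphere radius (default 80 mm — a common convention; the
  choice only scales the rotational contribution and is configurable). The
  RD series enters a second-order, lag-five Volterra expansion: the series
  at lags 0–4, the four successive differences between consecutive lagged
  columns, and all 81 ordered products of those nine columns — 90
  regressors capturing linear, delayed (spin-history) and quadratic
  (movement-by-distortion) motion effects. Lagged columns are padded at
  the start with the initial value, so a constant displacement produces
  exactly zero difference columns; duplicate symmetric products are kept
  because the subsequent SVD removes redundancy anyway.
* **Artifact signals.** Three artifact series (white-matter, CSF,
  whole-brain proxies) join the motion block. The stacked columns are
  standardized and reduced by SVD to the smallest number of components
  explaining 99% of their variance (typically 13–15 here, `m` is recorded
  per subject).
* **Band-pass by regression.** A discrete cosine set implements the
  0.009–0.1 Hz band-pass: component $k$ has frequency $f_k = k/(2 T\,
  \mathrm{TR})$, and the nuisance set contains the constant plus every
  component with $f_k$ outside the pass band. At $T = 148$, TR = 2 s this
  is exactly 94 columns (1 + 5 + 88). Whether the constant belongs to the
  set is a convention; this is the only convention that yields 94 columns
  at this geometry, and the count is exposed so other $T$/TR/band choices
  remain self-consistent. Filtering is by projection only — the data are
  never filtered directly, so the df accounting stays exact.

## Estimation and calibration

Hyperparameters $\lambda$ and coefficients are estimated simultaneously by
restricted maximum likelihood (Fisher scoring on the residual-forming
projection). Two numerical choices matter:

* **Log-scale hyperparameters.** $\lambda_k = e^{\gamma_k}$ is optimized in
  $\gamma$. We first implemented free-sign $\lambda$ with an
  eigenvalue-floored projection of $V$ onto the positive-definite cone, and
  found it unusable: the floored projection decouples the evaluated
  likelihood from the scoring gradients, the iterates drift into indefinite
  mixtures, and the floored tiny eigenvalues produce wildly inflated
  precision (observed null false-positive rates above 0.9). The log-scale
  parameterization keeps $V$ a valid positive mixture at every iterate and
  also equalizes the step scales of short- and long-half-life components.
* **Stopping rule.** Iterations stop when the relative hyperparameter
  update falls below $10^{-6}$, when no uphill step exists, or when the
  restricted-likelihood gain per iteration drops below $10^{-3}$: beyond
  that point the likelihood is flat and further iterations only
  redistribute weight among nearly collinear exponentials without changing
  $V$ (the fitted lag-1 ratio is stable to four decimals across this
  tail), while roughly tripling the cost. A cap of 64 iterations applies.

The seed contrast's $t$ statistic is referred to a $t$ distribution at the
Satterthwaite effective degrees of freedom
$\nu = \mathrm{tr}(RV)^2 / \mathrm{tr}(RVRV)$ ($R$ the residual-forming
matrix of the whitened design), then converted to a signed standard-normal
deviate through the two-tailed p-value (computed on the log scale so
$|t| \gtrsim 10$ does not underflow). With the full nuisance stack at
$T = 148$ this leaves about 39–41 residual df per edge. Edge Z statistics
from the two seed/target orderings are averaged, giving a symmetric
connectivity matrix; finally the per-subject mean RD is regressed out of
every edge across subjects (controls and patients combined).

## Pooled and per-edge estimators

The literal procedure fits one ReML per directed ROI pair. At connectome
scale (120 ROIs, 26 subjects, repeated over many simulated cohorts) that is
computationally out of reach, and also statistically wasteful: all edges of
a subject share the same scanner, physiology and motion history. The
default estimator therefore pools the ReML autocorrelation fit across all
of a subject's (standardized) ROI series — the same pooling logic imaging
GLMs use across voxels — applies the shared whitening to series and
nuisance design, projects the nuisance space out once, and reads every
edge's $t$ from the partial correlations of the whitened residuals with
$\nu = T - m_{\mathrm{nuisance}} - 1$. This statistic is symmetric in seed
and target by construction, so the seed/target average is exact. The
per-edge estimator remains available (`method = "per_edge"`) and is used
for ROI-level analyses (e.g. the 8-ROI default-mode set); on such subjects
the two estimators agree closely (edge-wise correlation above 0.95 in the
test suite), and the pooled estimator passes the same null-calibration test
(type-I rate at $|Z| > 1.96$ within $[0.035, 0.065]$) under the full
confound stack.

# Network and graph summaries

* **Block means.** Cell $(k, l)$ of the network block matrix is the mean
  edge Z over unique ROI pairs spanning networks $k$ and $l$; diagonal
  cells use unique within-network pairs, never the (undefined) self-edges.
  Lesion ROIs are excluded from their host network by default so the
  designated lesion effect is summarized separately by the lesion profile
  (mean Z between lesion ROIs and each network); this avoids double
  counting and is configurable.
* **Segregation.** $S$ = mean of diagonal cells − mean of off-diagonal
  cells. The block matrix is symmetric, so averaging the upper triangle
  equals averaging all off-diagonal cells; the unique-pair convention is
  used. $S$ is invariant to adding a constant to every edge.
* **Group contrasts.** Each cell is tested across subjects by a linear
  model with group and sex (patient minus control); Bonferroni families
  follow the analysis design — $K(K-1)/2$ between-network cells, $K$
  diagonal cells, $K$ lesion-row cells — and are configurable.
* **Graph metrics.** Connectivity matrices are binarized by percentile:
  threshold $P$ keeps the top $(100-P)\%$ of edges, with the exact target
  count enforced by rank (ties broken by a fixed total order on value and
  indices), so the retained edge count — hence mean degree — is identical
  across subjects. The phrase "top $P\%$ of values" is ambiguous in common
  usage; the implemented direction makes $P = 99$ a sparse graph, which is
  the only reading consistent with sparse-graph isolates appearing at high
  $P$; the literal reading is available via $P' = 100 - P$. Global
  clustering is the mean nodal clustering (isolates contribute 0, the
  toolbox convention), global efficiency the mean inverse shortest-path
  length (disconnected pairs contribute 0), small-worldness their product,
  and the isolate fraction the proportion of degree-0 nodes. The sweep
  covers $P = 85\ldots99\%$ in 1% steps (15 thresholds), with group tests
  Bonferroni-corrected over the 15 thresholds.

# Statistics for small patient groups

Single patients are compared to their control sample by the pooled-variance
single-case $t$, $t = (x_p - \bar{x}_c)/(s_c\sqrt{1 + 1/n_c})$ with
$n_c - 1$ df — the $1 + 1/n_c$ inflation treats the patient as a sample of
one and keeps the test calibrated at small $n_c$ (verified by simulation).
Group comparisons use the two-sample $t$ with sex as nuisance covariate
(dropped with a warning when degenerate). Domain-level evidence across
patients is combined by Stouffer's method, $Z = \sum z_i/\sqrt{k}$, with
normative percentiles converted through $\Phi^{-1}$; percentile *bands*
are converted at their midpoints (the conversion convention is not
standardized; midpoints are the neutral choice). Bonferroni correction is
the only multiplicity control in this stream. Isolate fractions, which are
far from normal, are compared by the Wilcoxon rank-sum test (exact for
combined $n \le 10$ without ties).

# The synthetic cohort generator

Each of $K$ networks has a latent AR(1) Gaussian signal with coefficient
$\phi$ (default 0.3); cross-network dependence is induced by correlating
the latent innovations with a $K \times K$ correlation matrix (baseline
off-diagonal 0.15), which for stationary series equals the cross-network
latent correlation. ROI $i$ in network $k(i)$ is
$x_i(t) = a_i\,g_{k(i)}(t) + g\,G(t) + \varepsilon_i(t)$ with a shared
global AR(1) signal $G$ and white noise. Patient effects: lesion-ROI
*signal* components are attenuated by $\alpha$ (noise untouched, so the
lesion's SNR and hence its coupling to its network drop); every within
loading gains $\delta_{\mathrm{within}}$; the thalamic–precuneus latent
correlation drops by $\delta_{tp}$ and the DMN–frontoexecutive correlation
rises by $\delta_{df}$ (the modified matrix is floored at eigenvalue
$10^{-6}$ and re-normalized, guaranteeing a valid generator). Motion is a
six-parameter random walk with Poisson-thinned translation spikes;
artifact series are low-pass filtered noise plus the spike indicator — so
the confound model has something real to remove.

## Calibration of the defaults

The desk-scale configuration is 120 ROIs in 8 networks (roles DMN,
frontoexecutive, thalamic, precuneus among them), $T = 148$ volumes at
TR = 2 s (150 acquired, two discarded for T1 equilibration is the standard
protocol this mirrors), 20 controls and 6 patients per cohort. Couplings
were calibrated so that the *output* of the full pipeline matches the
block-mean connectivity scale reported for real lesion cohorts: control
mean within-network Z near 1.05–1.15 and between-network Z near 0.2 at
$\approx 40$ residual df, with $\delta_{\mathrm{within}}$ set from the
reported within-network patient–control gap of 0.10. This puts the
within- and between-network edge distributions in the realistically
overlapping regime that sparse-threshold graph analysis operates in. The
cross-network deltas $\delta_{tp} = \delta_{df} = 0.1$ are not derivable
from reported values and were fixed once. Motion defaults (0.1 mm baseline
RD, 5% spike rate, 1 mm spikes) are asserted, not fitted — the reference
control motion distribution is not described anywhere.

## What the generator does and does not emulate

It reproduces block-structured covariance, serial correlation, global
signal, motion-correlated artifacts and the planted group effects; it does
**not** include hemodynamic forward modelling, spatial structure within
ROIs (beyond the voxel-block fixture used to test SVD extraction),
distance-dependent artifacts, or heterogeneous ROI loadings. Passing
recovery tests therefore demonstrates that the estimator chain recovers
the programmed effects under realistic noise, df and motion conditions —
not that it would detect them in any particular real dataset.

Recovery is measured as the fraction of seeded cohorts (50 by default) in
which the patient−control difference has the programmed sign for: lesion→
DMN coupling (lower), thalamic–precuneus block (lower), DMN–FEN block
(higher), segregation (higher), and clustering at the 99% threshold
(higher). At the calibrated realistic effect sizes the first four recover
in the high 0.7–1.0 range and the sparse-threshold clustering contrast is
the weakest — as in the real study, where it reached significance only at
the single highest threshold. With 120 ROIs a per-subject block mean
averages ~225 edges versus ~1000+ at full connectome scale, so desk-scale
recovery rates for the weaker effects sit near their criterion values
rather than comfortably above them; we report the measured rates rather
than inflating effect sizes beyond the reported magnitudes.

# Degenerate inputs and edge cases

All-constant voxel blocks and zero-variance control samples raise errors;
rank-deficient nuisance columns are dropped with a warning (the seed
regressor is never dropped); a constant RD across subjects makes motion
residualization a warning no-op; singleton networks flag their diagonal
block cell as undefined and segregation refuses to average over them;
all-equal connectivity matrices cannot be ranked and error at
binarization. Ties in binarization are broken by a fixed total order so
edge counts match exactly across subjects. Quantiles in the motion outlier
fence are type-7 (R's default), upper fence only.

# Problem sizes

The shipped analyses and tests run at: 120 ROIs / 148 volumes / 26
subjects for cohort-level analyses (pooled estimator), 8 ROIs for
per-edge ReML analyses, 50 seeded cohorts for recovery rates, 2000+ edges
for null calibration, $T = 1000$ for autocorrelation recovery, and graphs
of up to 15 nodes for brute-force oracle comparisons. These sizes were
chosen so the complete validation chain runs on a single CPU in minutes
while keeping every statistical check adequately powered.

# Known limitations

* Linear dependence only; no nonlinear coupling measures.
* The pooled estimator assumes one autocorrelation structure per subject;
  strong ROI-specific autocorrelation differences would argue for the
  per-edge estimator.
* Small-worldness is the clustering × efficiency approximation, not the
  ratio against degree-matched random graphs.
* The despiker is a simple median/MAD interpolator intended as plumbing,
  not a substitute for wavelet-domain despiking of voxel data.
* Percentile-band-to-z conversion uses band midpoints; extreme bands
  ("<2nd percentile") are inherently censored.
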