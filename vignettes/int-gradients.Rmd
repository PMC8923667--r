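---
title: "Intrinsic neural timescales and FC gradients: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic neural timescales and FC gradients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intgrad)
```

## The problem

Spontaneous (resting-state) brain activity decorrelates at different speeds
in different areas: sensory cortices fluctuate quickly, association and
prefrontal cortices slowly. Two complementary voxelwise summaries of this
organisation are

* the **intrinsic neural timescale (INT)** — a per-voxel statistic of how
  slowly the BOLD signal decorrelates; ordering regions by mean INT yields a
  *timescale hierarchy* from fast, sensory-like areas to slow, associative
  ones; and
* **functional-connectivity (FC) gradients** — low-dimensional spatial axes
  along which voxels' whole connectivity profiles change, obtained by a
  spectral embedding of a connectivity-similarity matrix.

`intgrad` implements both estimators, the analyses that relate them
(best-matching gradient, cross-structure projections such as
cortico-striatal maps), and reliability statistics, together with a
synthetic generator that plants a known timescale hierarchy and a known
1-D connectivity topography so that every stage can be tested against
ground truth.

## The INT estimator

For each run and voxel, the sample autocorrelation function is computed
with the biased-normalisation, mean-subtracted estimator

$$\mathrm{ACF}(k) \;=\; \frac{\sum_{t=1}^{N-k} d_t\, d_{t+k}}
                             {\sum_{t=1}^{N} d_t^2},
  \qquad d_t = y_t - \bar y ,$$

where the lag $k$ is counted in TR steps. The biased (length-$N$)
denominator guarantees $|\mathrm{ACF}| \le 1$ and a positive-semidefinite
curve; it is also what `stats::acf()` computes, which the tests use as an
independent oracle.

The INT is the sum of ACF values over the *initial positive period*:
lags $1, \dots, L-1$, where the zero-crossing lag $L$ is the smallest
$k \ge 1$ with $\mathrm{ACF}(k) \le 0$ (an exact zero counts as crossed,
since the period is defined as strictly positive). The statistic is
unitless — it mixes the number of positive lags with their magnitudes — and
larger values mean slower intrinsic dynamics. A separate time-constant
proxy in seconds is $L \times \mathrm{TR}$.

Choices the definition leaves open, and what this package does:

* **Lag 0.** The lag-0 term is identically 1 and carries no information;
  the default sum starts at lag 1. `include_lag0 = TRUE` adds the constant
  1 for sensitivity analyses; it shifts every voxel equally and cannot
  change any hierarchy or correlation reported here.
* **Censoring.** A voxel whose ACF never crosses zero within `max_lag` has
  no finite positive period. Such voxels are *flagged*, their sum truncated
  at `max_lag`, and by default still included in run- and region-averages
  (with exclusion counts reported); `strict = TRUE` excludes them. At 700
  timepoints and the default `max_lag = min(N - 1, 100)` censoring is rare —
  an ACF still positive after 100 TRs (~110 s) is dominated by drift, and
  100 lags is far beyond where a 700-sample ACF estimate carries signal.
* **Aggregation.** INT maps are computed per run, averaged voxelwise across
  runs within subject, then across subjects; region values are arithmetic
  means over voxels. Maps are never smoothed.

## FC gradients

The gradient pipeline is: voxel-pair Pearson correlation matrix →
(optionally, Fisher-z average across runs and subjects) → row-wise
sparsification → cosine-similarity affinity → diffusion-map embedding.

* **Sparsification** (`sparsify()`, default `density = 0.10`) keeps, per
  row, the top 10% of entries *by signed value* and zeroes the rest. This
  follows the convention of the gradient toolboxes in which the sparsity
  parameter zeroes the complement of the strongest connections; retained
  entries are then the strongest positive correlations, which is what a
  nonnegative diffusion operator needs. The fraction is configurable.
* **Affinity.** `cosine_affinity()` computes the cosine similarity between
  sparsified connectivity profiles (rows); negative similarities — rare
  after positive sparsification — are clipped to 0 so the affinity is a
  valid nonnegative edge-weight matrix. The matrix is exactly symmetric
  with unit diagonal.
* **Diffusion embedding** (`diffusion_embedding()`). With affinity $W$,
  degree $d_i = \sum_j w_{ij}$ and anisotropy exponent $\alpha$ (default
  0.5), the operator is built as
  $w^{(1)}_{ij} = w_{ij} / (d_i^\alpha d_j^\alpha)$, then row-normalised to
  a stochastic matrix $P$. Eigenvectors are obtained through the symmetric
  conjugate $D_1^{-1/2} W^{(1)} D_1^{-1/2}$ for numerical stability, scaled
  by the stationary vector, the trivial constant component is dropped, and
  components are weighted by $\lambda/(1-\lambda)$ (the multi-scale
  convention at diffusion time 0; at $t > 0$, by $\lambda^t$). Components
  are returned in descending-eigenvalue order and their **signs are
  arbitrary** — all downstream comparisons report $|r|$.
* **Degenerate input.** A disconnected affinity graph has no single
  diffusion geometry; the function refuses it and reports the component
  count and sizes rather than silently embedding one block. A uniform
  affinity is rank-1: all nontrivial eigenvalues are ~0.
* **Group aggregation.** FC matrices are averaged on the Fisher-z scale
  (entries clipped to $|r| \le 1 - 10^{-7}$ so unit diagonals stay finite)
  *before* sparsification; gradients are then estimated once from the
  group matrix. Estimating per-run gradients and aligning them afterwards
  is a plausible alternative, but averaging first needs no alignment
  machinery and is the simpler, deterministic choice.
* Gradients are estimated over the full (bilateral) voxel set by default;
  nothing in the code assumes hemispheric structure, so per-hemisphere
  analyses are just calls on subset time series.

## Relating and projecting maps

* `best_gradient()` reports the component with the largest $|r|$ against a
  map (ties to the lower index); only that gradient is interpreted, on the
  assumption that later components reflect other organisational principles.
* `project_gradient()` carries a gradient from structure A to structure B
  by assigning each B-voxel the gradient value of its single most
  positively correlated A-voxel (argmax by signed r, ties to the lower
  index). The field's descriptions of this projection are loose about
  whether one or several top voxels contribute; the single-argmax reading
  is implemented because it is parameter-free and exactly testable against
  a brute-force oracle. No smoothing is applied afterwards.
* `project_int()` reconstructs a map on structure B as, per B-voxel, the
  mean value of its `k = 10` most positively correlated A-voxels. Signed
  (not absolute) correlation is used in both projections: "most strongly
  connected" reads as largest positive r, and anticorrelated voxels should
  not donate values.

## Reliability

Map reliability uses Pearson correlations averaged on the Fisher-z scale
(`atanh`, inputs clipped to $1 - 10^{-7}$ so identical maps give a finite
maximum instead of infinity): intra-subject stability is the mean z over
all run pairs; inter-subject similarity is, per subject, the mean z against
all other subjects' run-averaged maps.

Hierarchy stability re-computes the region hierarchy from every subset of
`subset_size = 4` subjects (region means averaged over the subset) and
takes the Spearman rank correlation — average-rank ties — against the
full-group ordering (the full group, including the subset's members, is
the fixed reference). With 9 subjects this enumerates exactly
$\binom{9}{4} = 126$ subsets, in lexicographic order for reproducibility;
the stability score is the mean correlation.

## The synthetic generator

Real analyses of this kind have no generative model; the generator is a
**synthetic stand-in** whose only purpose is to plant recoverable ground
truth. Voxel $v$ in region $r$ with axis position $a_v \in [0,1]$ is
simulated, per run, as

$$y_v = \sqrt{1-s}\; p_v \;+\; \sqrt{s}\, \sum_{l} W_{vl}\, z_l \;+\;
        \sigma\,\varepsilon_v ,$$

where $p_v$ is a private stationary AR(1) process with the region's
coefficient $\varphi_r$ (unit variance), $z_l$ are shared latent AR(1)
signals, $W_{vl} \propto \exp\{-(a_v - c_l)^2 / 2\beta^2\}$ are
Gaussian-bump mixing weights (row-normalised) centred at equally spaced
axis positions $c_l$, and $\varepsilon_v$ is white observation noise.
Because each latent's own AR(1) coefficient is interpolated from the
planted region coefficients at its centre $c_l$, timescales and
connectivity vary along the *same* axis — the configuration the package's
headline coupling analysis targets. The population INT proxy
$\varphi/(1-\varphi)$ (the sum of the population ACF over all positive
lags) is recorded as ground truth and is strictly increasing in $\varphi$.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| subjects × runs | 9 × 5 | the multi-subject, multi-run design the pipeline targets |
| timepoints, TR | 700, 1.1 s | typical awake-NHP resting-state run length |
| regions | 6 × 30 voxels, $\varphi$ = 0.10…0.85 | spans fast sensory to slow prefrontal-like lag-1 autocorrelations at TR ≈ 1 s |
| `latent_dim` | 10 | enough bumps for a smooth 1-D topography over 180 voxels |
| `mixing_bandwidth` $\beta$ | 0.12 | neighbouring bumps overlap (~spacing 0.11), giving graded, not blocky, FC |
| `latent_strength` $s$ | 0.5 | shared and private variance balanced; FC between neighbours well above noise floor at N = 700 |
| `noise_sd` $\sigma$ | 0.3 | ~8% noise variance, a mild, realistic ACF dilution |
| HRF | off | keeps the AR(1) closed form exact for unit tests; `hrf_enabled = TRUE` convolves with a canonical double-gamma kernel for integration-style checks |

Reproducibility: one master seed expands to a fixed per-(subject, run)
substream seed, so a dataset is bit-identical under regeneration and
unchanged runs are unaffected by how many others are generated.

What the generator does *not* emulate: vascular and physiological noise
spectra, motion and scanner artifacts, spatial autocorrelation beyond the
planted axis, hemispheric structure, and real HRF variability. Passing the
recovery tests therefore shows the estimators are *correct and coherent* —
that they recover a known hierarchy and topography through the full
pipeline — not that real acquisitions meet their assumptions.

## Numerical choices

* ACF by dense vectorised cross-products (exact, no FFT); hand-checkable
  cases are asserted to 1e-12 and random series against `stats::acf`.
* Exact zeros in the ACF count as crossings; ties in sparsification,
  argmax/top-k projections and best-gradient selection resolve to the
  lower index, making every operator deterministic.
* The embedding validates symmetry (to 1e-12), nonnegativity and
  connectivity before decomposing; eigenvalues are returned in guaranteed
  descending order.
* Fisher z clipping constant $10^{-7}$: identical-map comparisons give
  $\mathrm{atanh}(1-10^{-7}) \approx 8.41$ rather than infinity, and the
  inverse transform round-trips to at least $1 - 2\times 10^{-7}$.

## Problem sizes

The test suite and the acceptance script run the recovery analyses at 180
voxels (6 regions × 30), 5 runs of 700 timepoints, with medians over 20
generator seeds; oracle-equivalence checks use 20 random 50-voxel
affinities and 50 random 20×30 FC instances. These sizes give stable
medians while keeping a full run in tens of seconds; all statistics are
computed fresh at run time.

## Known limitations

* The INT statistic is TR-dependent (lags are counted in TR steps);
  comparisons across acquisitions with different TRs should use the
  time-constant proxy, and even that is a coarse, hemodynamically filtered
  quantity.
* Gradient magnitudes are on an arbitrary scale; only orderings along a
  component and correlation magnitudes are interpretable.
* `project_gradient()`'s single-argmax assignment is intentionally
  noise-sensitive; on real data it is usually followed by smoothing, which
  this package leaves to the caller to keep core outputs exact.
* No statistical inference (permutation or spin nulls) is attached to the
  reported correlations; the package reports raw r / $|r|$.
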