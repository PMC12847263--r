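---
title: "Mean mode-amplitude features from resting-state ROI time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean mode-amplitude features from resting-state ROI time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdbold)
```

## The model

A subject's preprocessed resting-state fMRI signal is summarized as an ROI
time-series matrix: T time points (sampled every $\Delta t$ seconds, typically
2 s) by R parcellated brain regions (e.g. 300 Schaefer regions). `dmdbold`
models the one-step evolution of this multivariate series as approximately
linear,

$$X' \approx A X,$$

where the columns of $X$ are the region-space states at times $1 \dots T-1$
and $X'$ is the same sequence shifted one step forward. Exact dynamic mode
decomposition (DMD) diagonalizes the best-fit $A$ without ever forming it:

1. thin SVD $X = U S V^*$, discarding singular values below a relative
   tolerance;
2. projected propagator $\tilde A = U^* X' V S^{-1}$, rescaled as
   $\hat A = S^{-1/2} \tilde A\, S^{1/2}$;
3. eigendecomposition $\hat A \hat W = \hat W \Lambda$, with eigenvectors
   scaled as $W = S^{1/2} \hat W$;
4. modes $\Phi = X' V S^{-1} W$, one column $\varphi_i$ per eigenvalue
   $\lambda_i$.

The rescaling in steps 2-3 is what makes mode magnitudes comparable across
modes, in the manner of a power spectrum: without it the eigenvector
normalization is arbitrary and the amplitudes below would be meaningless.

Each mode carries:

- an oscillation frequency
  $f_i = |\mathrm{Im}\,\log \lambda_i| / (2\pi \Delta t)$ (principal branch),
  bounded by the Nyquist frequency $1/(2\Delta t)$;
- an amplitude $P_i = \lVert \varphi_i \rVert_2^2$, the energy that spatial
  pattern carries in the data;
- per-region powers $P_{ij} = |\varphi_{ij}|^2$ with
  $\sum_j P_{ij} = P_i$.

Real-valued input makes non-real eigenvalues appear in conjugate pairs with
equal frequency and amplitude; both partners are counted as distinct modes
throughout (so the in-band mode count of a real series is even unless a
retained eigenvalue is real).

The explicit signal model

$$x(t) = \Phi\, \Lambda^{t/\Delta t}\, b, \qquad b = \Phi^{+} x(0)$$

reconstructs the signal inside the decomposition window and extrapolates
beyond it. $\Phi$ is rectangular, so $b$ is the least-squares projection via
the Moore-Penrose pseudoinverse; when reconstructing from a mode subset, $b$
is recomputed from the subset's pseudoinverse rather than by zeroing entries
of the full-mode coefficients — the only self-consistent least-squares
projection, and the choice made here wherever band-filtered reconstruction
is used.

## Features, bands, and the infra-slow filter

Resting-state BOLD fluctuations are physiologically meaningful mainly in the
infra-slow 0.01–0.1 Hz band; faster components are dominated by cardiac and
respiratory cycles and slower ones by scanner drift. `band_filter_modes()`
therefore retains modes with $f_i$ in the closed interval [0.01, 0.1] Hz by
default (the band is printed ambiguously in the field's literature; closed
endpoints are the permissive reading, and conjugate partners always travel
together since they share a frequency).

The per-region feature is the mean amplitude
$\text{feature}_j = \sum_{i} P_{ij} / M$ over the $M$ retained modes. For
sub-band features the band is split into $k$ equal-width intervals (for
$k = 3$: [0.01, 0.04], [0.04, 0.07], [0.07, 0.1] Hz), each mode assigned to
exactly one interval (half-open internally, last closed — printed interval
edges in the literature overlap, which would double-count boundary modes),
the per-band means computed with band-specific mode counts, and the $k$
blocks of $R$ regions spliced in ascending frequency order into an
$R \times k$-dimensional feature vector. The band-specific denominator makes
the count-weighted splice identity hold exactly: the weighted average of the
per-band blocks reproduces the full-band feature, which the test suite
asserts algebraically. Empty bands contribute zero blocks with a warning
rather than an error, so sweeps over $k \in [2, 8]$ never abort.

## Selection: repeated LASSO, intersection, permutation screening

Features are standardized (zero mean, unit population variance; constant
columns dropped with a warning) and regressed on the 0/1 group label
(patient = 1) with the L1 penalty

$$\hat\beta = \arg\min_\beta\; \tfrac{1}{2N}\lVert y - X\beta \rVert_2^2
  + \gamma \lVert \beta \rVert_1 ,$$

solved by coordinate descent (glmnet) at fixed $\gamma = 0.2$. Two scalings
of this objective circulate; the one above is adopted because it makes the
univariate solution the soft-threshold of the feature-label covariance at
exactly $\gamma$, which is the closed form the tests check against. With
standardized features and binary labels, $\gamma = 0.2$ corresponds to
requiring a feature-label correlation of about 0.4 before a feature can
enter alone — a deliberately strict filter.

The selection is repeated `n_repeats` times; each repeat reshuffles the
10-fold assignment used to compute a held-out validation MSE, and the
repeat's coefficients are fit on the full data at $\gamma$. Only features
selected in *every* repeat survive (`intersection`); adding repeats can only
shrink this set. With a fixed feature table and a fixed $\gamma$ the
full-data fit is deterministic, so repeats coincide; the machinery exists
because selection variability reappears the moment any per-repeat
perturbation (subsampling, per-fold refitting) is introduced, and because
the intersection semantics are what downstream stages consume. Mean
coefficients $\bar\beta$ across repeats give each surviving feature a
direction (positive = patient group higher) and a severity ranking.

Surviving features are then screened with a two-sided label-permutation test
of the absolute group-mean difference ($p = (\#\{\text{permuted} \ge
\text{observed}\} + 1)/(B+1)$, bounded in $[1/(B+1), 1]$); features with
$p < \alpha = 0.05$ are called *abnormal regions*. Because the screen is run
on the same data that drove the selection, the p-values of selected features
are biased small; the screen is a consistency filter on the intersection,
not an independent discovery test. On pure-noise tables the strict $\gamma$
keeps the abnormal-call rate at the percent level, which the suite checks
across seeds.

## Classification benchmark

A linear SVM (cost $C = 1$) is evaluated under three rounds of stratified
10-fold cross-validation — 30 rows of five metrics (accuracy, precision,
recall, F1, specificity; patient = positive class; zero-denominator ratios
reported as flagged zeros). Four variants share identical fold divisions via
a common seed: `chance` (training labels permuted), `plain` (all features),
`per_fold_lasso` (selection on the training split only), and `fixed_subset`
(the repeated-LASSO intersection). The intersection is computed on all data,
so its CV estimate carries the usual optimistic selection bias; the
per-fold variant is the unbiased counterpart and both are reported. Metric
distributions are compared with an unpaired pooled permutation test of the
absolute mean difference (the folds are shared across variants, but pairing
is not assumed because the metric rows are not exchangeable within a fold in
any obvious sense).

## Connectivity: phiC versus FC

Functional connectivity (FC) is the Pearson correlation matrix of the raw
region time courses. The mode-sequence correlation (phiC) treats region j's
row of the (subset-restricted) mode matrix as that region's signature across
modes and correlates rows with the real part of the *uncentered* conjugate
cosine similarity

$$r_{jk} = \frac{\mathrm{Re} \sum_i \varphi_{ji} \overline{\varphi_{ki}}}
  {\lVert \varphi_{j\cdot} \rVert\, \lVert \varphi_{k\cdot} \rVert}.$$

Not centering the rows is a deliberate choice and the module's main
interpretive decision. Time-domain Pearson correlation removes each region's
temporal mean, and a temporal mean corresponds to a zero-frequency mode —
which band filtering already excludes. Subtracting the row mean *across
modes*, by contrast, removes a quantity with no time-domain analogue (the
rows pair conjugate modes, so their mean is a real-valued artifact of mode
enumeration) and measurably degrades the agreement with FC on noiseless
periodic test cohorts (from $r \approx 0.993$ to $\approx 0.961$ in this
package's prototyping). The uncentered similarity reduces to the time-domain
Pearson correlation exactly when the retained modes carry all signal energy.
Comparisons between matrices use strictly-upper-triangle entries only.

## The synthetic-data generator

The generator is the package's study-condition stand-in for a real cohort,
and its defaults are fixed once:

- dimensions 140 time points x 300 regions at $\Delta t = 2$ s, two groups
  of 68 by default (each parameter overridable);
- nine oscillators evenly spaced at 0.015–0.095 Hz — strictly inside the
  filter band, avoiding boundary ambiguity — with i.i.d. uniform phases per
  subject/region/frequency (subjects must differ: inter-subject mode
  variability is a known property of this kind of data);
- one out-of-band component at 0.15 Hz (amplitude 0.5) and additive i.i.d.
  Gaussian noise (sd 0.5), the minimal noise assumption;
- base amplitude 1.5 per region, which concentrates values in [−10, 10]
  (≥95% of samples) while keeping the full range well inside [−50, 50],
  matching the scale of preprocessed BOLD data;
- planted effects: for patient-group subjects only, the oscillator
  amplitudes of one region inside one frequency band are scaled by
  $1 + \text{direction} \times \text{relative magnitude}$, so with zero
  noise the in-band amplitude ratio is exact by construction;
- a master seed expanded into per-subject streams, so cohorts are bitwise
  reproducible and could be generated in parallel.

The linear-system generator plants an exactly known spectrum: prescribed
eigenvalues (conjugate-closed, modulus ≤ 1) embedded in region space via a
per-subject random orthonormal basis, with the initial state inside the
invariant subspace so the whole trajectory satisfies the dynamics exactly.
It is the oracle for eigenvalue recovery, reconstruction and prediction.

What the generator does *not* emulate: haemodynamic response shapes, motion
and physiological artifacts, spatial autocorrelation between neighbouring
regions, non-stationarity, and any nonlinearity in the dynamics. Passing
tests on these cohorts therefore validate the algorithmic pipeline — not
the clinical claim that mean mode amplitudes separate patient groups in
real data.

## Numerical choices and degenerate inputs

- Singular values below $10^{-12} \sigma_{\max}$ are dropped before
  inverting $S$ (no rank truncation by default — a full-rank 140-point
  subject yields all 139 modes).
- Eigendecomposition of $\hat A$, not an SVD: the diagonal of $\Lambda$
  holds eigenvalues (some presentations of the algorithm conflate the two).
- Principal-branch logarithms and powers throughout; eigenvalues on the
  negative real axis map to the Nyquist frequency and are counted in the
  decomposition's `n_nyquist` field (`mode_frequencies()` warns when called
  directly); zero eigenvalues are an error.
- Mode order is canonical (frequency ascending, then amplitude descending,
  then sign of the imaginary part), making outputs reproducible and keeping
  conjugate partners adjacent.
- All-zero snapshot matrices, empty mode subsets, one-class folds, zero
  margins in balance tables and non-numeric TSV cells raise descriptive
  errors; empty sub-bands and empty intersections warn and continue.
- Permutation p-values use the add-one estimator, never reaching zero.

## Problem sizes used in the checks

The bundled verification runs use cohorts of 10–20 subjects at the full
140 x 300 grid for reconstruction/prediction/connectivity benchmarks, and
five seeds of an 80-subject planted cohort (five effects of relative
magnitude 0.5, mixed directions, 100 selection repeats, 200 permutations)
for end-to-end recovery — sizes at which every stage's behaviour is already
stable. The planted effects are laid out with comparable strengths (one
sub-band each): a single dominant whole-band effect would be absorbed first
by the L1 path and mask weaker true effects — a real property of LASSO on
collinear designs worth remembering when interpreting intersections on real
cohorts.

## Known limitations

- The linear one-step model is a window-local approximation; on real BOLD
  data prediction degrades within a few steps beyond the window, while on
  the marginally-stable synthetic cohorts here it stays at the noise floor
  (flat error curves) — the generator has no nonlinearity to expose.
- The intersection rule is all-or-nothing: a single unlucky repeat can
  empty it. Selection frequencies are reported alongside for softer
  stability analyses.
- The permutation screen after selection is biased (see above); treat
  abnormal calls as ranked candidates, not calibrated discoveries.
- phiC's correlation of complex rows has no unique definition; the
  uncentered real-part convention used here is one defensible choice among
  several (magnitudes, concatenated real/imaginary parts).
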