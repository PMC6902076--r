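---
title: "Sliding-window dynamic connectivity states: methods and design"
author: "dynconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window dynamic connectivity states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

# Overview

`dynconn` implements a complete sliding-window dynamic functional network
connectivity (dFNC) analysis for ROI time series extracted from
resting-state fMRI, together with a synthetic regime-switching cohort
generator that provides ground truth for every stage. The pipeline is:

1. **Signal conditioning** — volume discard, nuisance regression
   (Friston-24 motion expansion plus linear and quadratic trends, with a
   hook for extra confound columns such as WM/CSF signals), and an ideal
   band-pass filter, in that fixed order.
2. **Connectivity** — static Pearson correlation over the whole series and
   windowed correlations over rectangular sliding windows, Fisher
   z-transformed and vectorized along a canonical edge order.
3. **Variability (dFCV)** — the per-edge sample standard deviation of the
   windowed Fisher-z values, compared edgewise between groups with age and
   sex as covariates.
4. **Connectivity states** — k-means over all subjects' pooled window
   vectors under correlation distance, with the number of states chosen by
   three cluster-validity indices, followed by temporal metrics (mean dwell
   time, frequency, total transitions) and Mann-Whitney group tests.
5. **Topology** — static connectivity thresholded into nested binary
   graphs across a sparsity grid, global and local efficiency at every
   threshold, trapezoidal AUC summaries, and two-sample t tests.

# The model and its assumptions

## Windowed connectivity

For a conditioned series of $T$ time points, windows of length $w$ TRs
advanced by $s$ TRs give $W = \lfloor (T-w)/s \rfloor + 1$ windows (130
points with $w=20$, $s=1$ give 111). Within each window the Pearson
correlation $r_{ij}$ of every ROI pair is mapped to
$z_{ij} = \mathrm{atanh}(r_{ij})$ for variance stabilization; $|r|$ is
clamped at $1 - 10^{-7}$ so that degenerate windows remain finite.
Windows are rectangular and untapered: the window length and step are the
only windowing parameters the analysis convention specifies, and tapering
would change the variance of the windowed estimates that the dFCV measure
summarizes.

A windowed correlation estimated from $w$ samples carries sampling noise
with standard deviation approximately $1/\sqrt{w-3}$ on the z scale
($\approx 0.24$ at $w = 20$) per edge. This noise floor, not the scanner
noise, dominates the geometry of the pooled window cloud, and it is the
reason state recovery degrades when planted states are weak or dwell times
are short relative to the window.

## dFCV and the edgewise group test

The dynamic FC variability of an edge is the sample standard deviation
(denominator $W-1$) of its $W$ Fisher-z values. Before group comparison the
dFCV entries are themselves passed through $\mathrm{atanh}$. This step is
mathematically odd — dFCV values are standard deviations, not correlations
— but it reproduces the established convention of this analysis family
literally; entries $\ge 1$ are clamped with a warning. Each edge is then
fit by OLS as `value ~ intercept + group + age + sex`, and the two-sided t
statistic of the group coefficient is reported with uncorrected
thresholding at $\alpha = 0.005$ by default. An optional Benjamini-Hochberg
mask is available but off by default, matching the uncorrected convention
this pipeline mirrors.

## Connectivity states

All subjects' window vectors are pooled and clustered by Lloyd k-means
under correlation distance $d(u,v) = 1 - \mathrm{corr}(u,v)$, which is
sensitive to the connectivity *pattern* regardless of magnitude. Centroid
updates are arithmetic means of the raw member vectors — the standard
k-means update, with correlation distance substituted only in the
assignment step, as the common dFNC toolboxes do. Because that compromise
does not guarantee monotonicity of the correlation-distance objective, an
iteration that fails to decrease the objective terminates the restart; in
practice assignments stabilize first. Seeding is k-means++-style under the
same distance (squared-distance sampling), empty clusters are re-seeded
from the farthest point, and the best of `nInit` restarts (default 100,
`maxIter` 500) by objective is kept. Runs are deterministic given a seed.

## Choosing the number of states

`selectK()` fits every $k$ in 2..10 and computes silhouette,
Calinski-Harabasz (CH) and Davies-Bouldin (DB) indices. The per-index
optima are the argmax of the first two and the argmin of DB; the combined
choice rounds the simple average of the three optima half away from zero
(a `floor` variant is available — the convention's own worked example,
(2,2,2) giving 2, cannot disambiguate the rounding rule).

The indices are computed in squared-Euclidean geometry by default. This
was a genuinely open design choice: the classical CH and DB definitions
are variance decompositions in Euclidean space, and the widely used
clustering-evaluation toolboxes compute them only there, while silhouette
admits any metric. We implemented both geometries and found the DB argmin
under correlation-distance scatter terms unstable on synthetic two-state
cohorts (it often drifted to large $k$), whereas the Euclidean versions
agree unanimously on the planted truth; the correlation variant remains
available via `geometry = "correlation"`.

## Temporal state metrics

From each subject's window label sequence: the *frequency* of a state is
its window count; the *mean dwell time* is the average length of its
maximal runs (0 for a state never visited, consistent with reporting
quartiles of 0 for rarely visited states); *transitions* count adjacent
unequal labels. Exact identities hold by construction: frequencies sum to
$W$; for any state, frequency equals mean dwell times the number of runs;
for $k=2$, transitions equal total runs minus one. Group differences use
two-sided Mann-Whitney tests reporting $U = \min(U_1, U_2)$, with exact
enumeration when $n_1 n_2 \le 400$ and no ties, and the tie-corrected
normal approximation otherwise.

## Graph topology

The Fisher-z static connectivity matrix is binarized at sparsity
thresholds 0.01..0.50 in steps of 0.01: at sparsity $s$ the
$\mathrm{round}(s \cdot N(N-1)/2)$ edges of largest **absolute** weight are
kept (strong negative correlations carry real connections; a positive-only
mode is available since the original convention does not state sign
handling). Ties break deterministically by edge index and `round` is the
usual half-to-even rule, so the graphs are reproducible and nested along
the grid. Global efficiency is the mean inverse BFS shortest-path length
over ordered node pairs (0 for disconnected pairs); local efficiency is
the mean over nodes of the global efficiency of each node's
neighbor-induced subgraph, with degree < 2 nodes contributing 0. Curves
are summarized by the trapezoidal AUC over the grid — with a 0.01 step the
difference from a step-sum is below the grid step times the metric range —
and compared between groups by pooled two-sample t tests on the AUCs.

# The synthetic cohort generator

The generator exists so that every stage has verifiable ground truth
without scan data. Each subject is a regime-switching multivariate
Gaussian: a first-order Markov chain over latent connectivity states (stay
probability per step; the leave mass spread uniformly over the other
states), with each time point drawn from a zero-mean multivariate normal
under the current state's covariance, plus isotropic observation noise.

The two default states mirror the qualitative patterns this analysis
family reports: a **segregated** state with weak positive within-network
blocks (+0.1) on a weakly negative background (−0.05), and an
**integrated** state with moderate positive connectivity (+0.3 within,
+0.2 between) in which a designated default-mode-analog network is
anticorrelated with all others (−0.15). The magnitudes 0.1/0.3 translate
"slight" and "moderate" and are configurable, not asserted. Matrices are
repaired to the nearest unit-diagonal PSD correlation matrix by clipping
negative eigenvalues and rescaling; the sign pattern is re-checked after
repair. Per-subject heterogeneity adds a symmetric Gaussian perturbation
(SD 0.02) to the off-diagonals before repair; observation noise has SD 0.2
— mild relative to the unit-variance signals, chosen once as a realistic
sensor-noise level (the band-pass stage shapes it downstream). Default
cohort: 17 patient-like and 20 control subjects, 130 time points at TR
2 s, 20 ROIs in four equal networks, stay probability 0.9 in both groups,
demographics drawn to approximate a small dementia-versus-control cohort
(patients older and predominantly male). The base seed spawns per-subject
seeds as `seed + subject index`, so cohorts are reproducible under
subsetting.

What the generator does **not** emulate: hemodynamics, spatial structure,
physiological noise spectra, scanner drift, or realistic motion-signal
coupling (motion traces are small random walks, independent of the
signal). Passing tests on synthetic cohorts therefore demonstrate the
correctness and statistical calibration of the machinery, not the
biological validity of any particular finding on real data.

# Numerical choices and degenerate inputs

* Fisher transform clamps $|r|$ at $1-10^{-7}$; `tanh` inverts it to
  1e-9 over $|r| \le 0.999999$.
* Zero-variance ROIs or window segments are **errors** identifying the
  ROI and window, never silent NaNs — silent propagation would corrupt
  the pooled clustering.
* The ideal band-pass retains exactly the DFT bins with $|f|$ in
  [0.01, 0.08] Hz (DC always removed) and is idempotent on filtered data.
* Motion exclusion uses strict inequalities (> 2.0 mm translation or
  > 2.0° rotation on the per-volume absolute parameters); values exactly
  at the limit are retained. Either criterion alone excludes.
* Rank-deficient confound designs and collinear covariates are errors
  naming the offending columns.
* Sliding windows are computed by windowed cumulative sums, agreeing with
  direct per-window correlation to machine precision.
* All validity indices skip a candidate $k$ (with a warning) if the best
  clustering at that $k$ has an empty cluster.

# Problem sizes used by the test-suite simulations

Monte-Carlo checks in the package's tests run at deliberately modest
sizes, chosen as the smallest cohorts at which the tested property is
stable: power and calibration suites use 100–200 replicate cohorts at the
default 17 + 20 subjects; the k-selection recovery checks use 20 replicate
cohorts with restart counts reduced to 20–25 (the planted two-state
separation makes additional restarts redundant); the three-state
recovery property uses 12 subjects per cohort over 10 seeds with
amplitude-0.65 mutually near-orthogonal block patterns and stay 0.97 —
at weaker amplitudes the windowed estimation noise ($1/\sqrt{w-3}$ per
edge) and within-window state mixing genuinely dominate the separation,
which is a real limitation of sliding-window state detection, not of the
implementation.

# Known limitations

* The WM/CSF nuisance signals of a full voxel-space pipeline cannot be
  computed from ROI series; the regression interface accepts them as
  extra confound columns when the user has them.
* Correlation-distance k-means with mean updates is the toolbox-typical
  compromise, not a principled correlation-medoid algorithm.
* Sliding-window state estimation blurs states whose dwell times are
  short relative to the window, and the generator makes the consequences
  visible. dFCV is **not** monotone in the switching rate: when dwell
  times fall far below the window length, every window samples roughly
  the same state mixture and dFCV falls back toward the estimation-noise
  floor, peaking when dwell is comparable to the window. Likewise,
  subjects whose true dwell is a small fraction of the window collapse
  into a single mixture state at clustering time, so estimated dwell
  times saturate at the window count; group differences in state
  persistence are only recoverable end to end when the planted states
  are separable relative to the windowed estimation noise. The
  corresponding test suites therefore compare constant against
  moderately switching regimes, and verify dwell-difference detection
  both on ground-truth label sequences (isolating the Mann-Whitney
  test's power) and through the full pipeline with separable
  high-amplitude states.
* The edgewise dFCV test is reported uncorrected at $\alpha = 0.005$ by
  design fidelity; interpret accordingly or enable the FDR mask.
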