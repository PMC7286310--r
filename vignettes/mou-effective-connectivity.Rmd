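---
title: "Effective connectivity and dynamic flow with MOU network models"
author: "mouflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity and dynamic flow with MOU network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouflow)
```

## The model and its assumptions

`mouflow` treats a multi-region recording as a stationary realization of a
multivariate Ornstein–Uhlenbeck (MOU) process: each region's state decays
with a global time constant τ, receives directed input from other regions
through the effective-connectivity matrix C, and is driven by white noise
with covariance Σ,

$$dx = J\,x\,dt + dW, \qquad J = -I/\tau + C^\top, \qquad
\mathrm{Cov}(dW) = \Sigma\,dt .$$

The orientation convention throughout the package (and in every matrix
file it writes) is `C[i, j]` = weight of the directed connection **from
source i to target j**; the Jacobian uses the transpose so that state
evolution reads target-from-source. The key assumptions are:

* **Linearity and stationarity.** The session is summarized entirely by
  its zero-lag and one-lag covariances (FC0, FC1). Task switching within
  a session, hemodynamic convolution, and nonlinear population dynamics
  are outside the model (deliberately: robustness of estimation over
  biophysical detail).
* **Global τ.** One leakage time constant for all regions, an abstraction
  of the hemodynamic response decay. It is estimated *before* the fit
  from the log-slope of the per-region autocovariance over small lags
  (`estimate_tau()`, pooled as −1/mean(slopes)) and held fixed during the
  fit. For coupled networks the pooled estimate absorbs network slowing
  and is biased upward relative to the generative τ; since the same bias
  applies to every session, downstream comparisons are unaffected, but
  the absolute value should not be over-interpreted.
* **Diagonal Σ.** Inputs are region-specific and uncorrelated; the full
  positive-semidefinite Σ is accepted by the model container and the flow
  analysis, but the estimator only updates the diagonal.
* **Stability.** All Jacobian eigenvalues must have negative real part;
  the package declares a model unstable when the spectral margin exceeds
  −1e−9 and refuses covariance computations on unstable models.

## Estimation

`mou_fit()` minimizes the model error
$E = \tfrac12(\|\Delta Q_0\|_F/\|\widehat{Q}_0\|_F +
\|\Delta Q_1\|_F/\|\widehat{Q}_1\|_F)$ by a natural-gradient-like
iteration: the stationary covariance comes from the continuous Lyapunov
equation (solved spectrally, with a Kronecker-product fallback when the
Jacobian eigenbasis is ill-conditioned; relative residual always below
1e−10), the best-fitting Jacobian update is
$\Delta J^\top = Q_0^{-1}(\Delta Q_0 + \Delta Q_1 e^{-J^\top \mathrm{lag}})$,
and C moves along it on the masked off-diagonal entries only, clipped to
be nonnegative. The Σ diagonal descends the Lyapunov residual
$\mathrm{diag}(J \Delta Q_0 + \Delta Q_0 J^\top)$. The parameters at the
minimum error are returned, mirroring the minimum-model-error selection
of the estimation procedure.

Tunable parameters (`mou_control()`), with defaults and rationale:

| parameter | default | role |
|---|---|---|
| `rate_c` | 0.005 | EC step size; dimensionless because the natural-gradient step is already in Jacobian units (1/s). Chosen so noise-free recovery converges in a few thousand iterations without overshoot. |
| `rate_sigma` | 0.05 | Σ step per unit Lyapunov residual (signal²/s). |
| `max_iter` | 10000 | hard cap; noise-free fits converge well before it. |
| `patience` | 100 | iterations without improving the best error before stopping — the working stopping rule on noisy targets, where the error eventually rises as the descent overfits. |
| `sigma_min` | 1e−6 | positivity floor for diag(Σ). |
| `c_max` | ∞ | optional cap on EC weights. |

Numerical choices: the empirical covariance pair uses one common
overlapping window of length T − lag and denominator T − lag − 1 so FC0
and FC1 are mutually consistent; a quasi-singular FC0 (condition number
above 1e8) receives a ridge jitter of 1e−6·mean(diag) with a logged
message; initialization is deterministic (C = 0, Σ from the decoupled
closed form 2 diag(FC0)/τ) so fits are reproducible without a seed. When
an EC update would destabilize the Jacobian the step is backtracked
(halved up to 8 times from the last stable state); if even the smallest
step crosses the boundary five consecutive times, the fit stops and
returns the best stable parameters — on noisy targets the optimum
regularly sits against the stability boundary, and failing there would
discard a usable estimate.

The `"heuristic"` variant constrains C to be symmetric on the symmetrized
mask and tunes it to reproduce FC0 only (error = single Frobenius ratio).
It fits the zero-lag correlation structure slightly better by
construction but discards directionality; on directed ground truths its
post-hoc error on the (FC0, FC1) pair is worse than the gradient fit's,
which the test suite checks.

**Known limitation — nonconvexity.** The descent is not globally
convergent: for a minority of random ground-truth networks the noise-free
fit settles into a local attractor at model error ≈ 0.2 (the error then
oscillates indefinitely; smaller rates and longer patience do not escape
it), while for most networks it reaches error ≈ 1e−15 and recovery
correlation 1.0. Deterministic initialization makes this reproducible per
network.

## Dynamic communicability, flow, and communities

For a fitted model, `dynamic_communicability()` computes
$\mathcal{C}(t) = (e^{Jt} - e^{J_0 t})/\|J_0\|$ with $J_0 = -I/\tau$: the
network response at integration time *t* beyond pure leakage. The
normalization $\|J_0\| = N/\tau$ (entrywise L1 norm) makes values
dimensionless and comparable across network sizes. `dynamic_flow()`
scales the source side by √Σ, so that with Σ = I flow and communicability
coincide exactly (a structural identity the tests enforce bitwise).
Derived summaries: total flow (sum of all N² interactions), input/output
flow per region (column/row sums — both conserve the total), and flow
diversity (population coefficient of variation of the N² entries,
reported as `NA` when the mean is below 1e−15).

Community detection symmetrizes the flow matrix at one integration time
with the entrywise **minimum** of F and Fᵀ — a pair of regions counts as
strongly connected only if *both* directions carry flow, which is the
conservative reading of bidirectional exchange; the arithmetic mean is
available as an option. The diagonal is zeroed (self-flow is not an
inter-region exchange, though it is retained in the total-flow summaries)
and weighted Louvain modularity maximization runs with seeded restarts
(default 20, best modularity kept, ties to the lowest run index,
resolution 1). Coparticipation across subjects or runs is the fraction of
partitions in which two regions share a community. The default
integration-time grid spans 0–20 TR in 0.5 TR steps, covering the early
near-EC regime through the late homogenized regime where communities
merge.

## Classification pipeline

Sessions are feature vectors: masked EC entries in source-major order, or
the FC upper triangle, with the (source, target) index retained so
biomarkers map back to region pairs. `classify_cv()` standardizes
features on the training fold only and evaluates multinomial logistic
regression (L2 penalty 1.0 — recorded in the result), LDA, or kNN with
1 − Pearson correlation distance. Condition prediction always splits by
*subject* (default 40 repetitions of an 80:20 subject shuffle, or
leave-one-subject-out): sessions of one subject are paired, and session-
level splitting would leak subject identity into the test set. Subject
identification instead splits sessions within each subject. The analytic
collision probability of repeated group draws
(`split_collision_probability()`) quantifies why, with 22 subjects and
4-subject test sets, 100 random splits repeat a split with probability
just under 50% — the motivation for the leave-one-group-out alternative.

`rfe_biomarker()` eliminates 5% of remaining features per iteration by
smallest maximum-absolute MLR coefficient; the cross-validated accuracy
along the path is computed with eliminations *recomputed inside each
training fold* (a sentinel test corrupts a test fold and checks the
training-fold elimination order is unchanged), and the support network is
the smallest top-ranked set achieving the accuracy maximum.
`linkwise_tests()` provides the statistical-testing counterpart:
two-sided Mann-Whitney (or Welch) per link and condition pair, minimum p
over pairs for multi-class designs, Bonferroni threshold α/L and
Benjamini-Hochberg rejections at FDR α; constant features raise an error
rather than being dropped silently.

## The synthetic cohort

`make_cohort()` emulates a passive-viewing study design: by default 10
subjects × (2 rest + 3 movie) sessions of 300 time points at TR = 2 s on
a 20-region network with a 28%-density structural mask and τ = 2 TR; the
`paper_scale` preset switches to 66 regions and 22 subjects (110
sessions). Ground-truth EC weights are lognormal on the mask, globally
rescaled until the spectral margin is at most −0.1/τ; Σ = I. Subject
identity is multiplicative lognormal jitter (sdlog 0.1) on existing links
only, so topology is shared; every non-rest condition multiplies a shared
set of 10 links by 1.5 and boosts the input variance of the designated
sensory regions (the first 20%) by 1.5, and with several task conditions
each gets 5 additional private links so fine contrasts nest the coarse
one. Every session's true parameters are recorded; regeneration from the
same spec is bit-identical. Sessions are integrated by Euler–Maruyama at
dt = TR/20 (compiled core, R RNG) with a 100 τ burn-in.

What the generator does *not* emulate: hemodynamic convolution and
region-specific response shapes, physiological noise and motion,
nonstationarity within sessions, and measurement noise on top of the
process — so passing tests demonstrate correctness of the estimation and
analysis machinery under the model's own assumptions, not robustness to
real-fMRI artifacts.

Desk-scale defaults keep the full test suite in minutes: recovery and
oracle checks use 6–20 regions, the long-sample simulation oracle uses
10⁵ time points, and the end-to-end cohort is the 20-region default. The
66-region preset exists for scale checks (session counts, timing) only.

## What the numbers show

At 300 time points per session — the study-design regime — fitted EC
correlates with the session's ground truth at a median of roughly 0.45,
rising above 0.8 by 5000 points and above 0.95 by 50000; the test suite
asserts this monotone scaling and the long-sample limit. The estimation
noise at 300 points also attenuates per-link condition effects enough
that condition decoding from fitted EC on the default synthetic cohort
stays nearer 55–65% than the high accuracies reachable from the
ground-truth EC (100%) — the acceptance checks report both honestly, and
the contrast itself illustrates why session length and estimation quality
are first-order concerns for connectivity-based biomarkers.

## File formats and the pipeline

Time series travel as TSV (rows = time points, columns = regions, header
of region names) with a JSON sidecar carrying TR, labels, and the format
version; matrices as labeled dense CSV whose first line states the
orientation convention; cohort manifests as JSON. `run_pipeline()` chains
simulate → fit → flow → communities → classify → testlinks from a single
config (validated before any computation), expands one top-level seed
into per-stage seeds, and writes a summary JSON with content hashes —
rerunning the same config reproduces identical hashes.
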