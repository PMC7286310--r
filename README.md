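# mouflow

Whole-brain effective connectivity (EC) from multivariate
Ornstein–Uhlenbeck (MOU) network models, with dynamic communicability /
flow analysis and a connectivity-based classification pipeline.

`mouflow` is aimed at researchers analyzing multi-region time series
(typically BOLD fMRI after parcellation into regions of interest) who want
a *directed*, model-based connectivity estimate rather than correlation
matrices, and who then want to interpret and exploit that estimate — as a
network (propagation of activity across integration time, functional
communities) and as a feature vector (condition decoding, biomarkers).

## The model

Each region's signal follows a noise-driven linear network

dx = J x dt + dW,   J = −I/τ + Cᵀ,   Cov(dW) = Σ dt

where C is the directed EC matrix (`C[i, j]` = connection from source
region *i* to target region *j*, nonnegative, masked by structural
connectivity), τ a global leakage time constant, and Σ the (diagonal)
input covariance. The stationary covariance solves the Lyapunov equation
J Q₀ + Q₀ Jᵀ + Σ = 0 and the lagged covariance is Q_lag = Q₀ exp(Jᵀ lag).
Fitting inverts this map: a Lyapunov-based natural-gradient descent tunes
C (on the mask) and diag(Σ) until the model covariances reproduce the
empirical zero-lag and one-lag covariance pair (FC0, FC1), returning the
parameters at minimum model error

E = ½ ( ‖FC0 − Q₀‖_F / ‖FC0‖_F + ‖FC1 − Q₁‖_F / ‖FC1‖_F ).

On top of a fitted model, dynamic communicability
𝒞(t) = (e^{Jt} − e^{J₀t}) / ‖J₀‖ (J₀ = −I/τ) and dynamic flow
(√Σ-weighted on the source side) quantify pairwise interactions after an
integration time *t*, including indirect network paths; Louvain modularity
on the flow matrix yields time-resolved functional communities. Vectorized
EC/FC/flow feeds subject-grouped cross-validated classifiers (multinomial
logistic regression, LDA, correlation-kNN), recursive feature elimination
biomarkers, and link-wise Mann-Whitney tests with Bonferroni /
Benjamini-Hochberg correction.

## Worked example

Generate a ground-truth network, fit the model to its theoretical
covariances, and analyze the flow:

```r
library(mouflow)
spec   <- cohort_spec(n_rois = 10, density = 0.3, seed = 42)
gt     <- make_ground_truth(spec)
truth  <- gt$model
target <- mou_cov(stationary_cov(truth), lagged_cov(truth, 2), lag = 2)
fit    <- mou_fit(target, mask = gt$mask, tau = truth$tau)
print(fit)
#> MOU-EC fit (gradient optimization)
#>   regions: 10, tau: 4 s, lag: 2 s
#>   model error: 3.552e-15 at iteration 3835/3935 (converged)

links <- gt$mask == 1
cor(truth$ec[links], coef(fit)[links])
#> recovery correlation: 1.000

ft <- dynamic_flow(fit$model, t_grid = seq(0, 40, by = 2))
seq(0, 40, by = 2)[which.max(total_flow(ft))]
#> total flow peaks at t = 6 s
```

The model error of essentially zero and recovery correlation of 1.000 say
that, given noise-free covariances, the descent identifies the directed
weights exactly; the total network flow rising from zero to a peak near
1.5 τ before fading is the stereotypical propagation profile of a stable
MOU network. On finite sessions (300 time points at TR = 2 s) estimates
are noisier — `simulate()` plus `mou_fit()` on a session shows the
realistic regime, and `make_cohort()` builds a full multi-subject,
multi-condition synthetic study with known ground truth.

A thin command-line interface over these functions is installed at
`inst/cli/mouflow.R` (subcommands `simulate`, `fit`, `flow`,
`communities`, `classify`, `testlinks`, `pipeline`).

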