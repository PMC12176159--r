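# wlphmm

Weighted-likelihood **partially hidden Markov models** (PHMMs) for
multivariate time series in which a sparse subset of time steps carries a
behavioural label — the situation of most biologging studies, where a drone
or an animal-borne camera confirms what the animal was doing at a handful
of moments inside hours of sensor data.

A PHMM augments the HMM joint density with a label-emission term: with
hidden states `X_t`, observations `Y_t` and labels `Z_t` (present only on a
labelled index set `T_lab`, with `g(i)(∅) = 1` elsewhere),

```
p(y, z) = δ P(y₁, z₁) ∏_{t≥2} Γ P(y_t, z_t) 1ᵀ ,
P(y_t, z_t) = diag( f(i)(y_t) g(i)(z_t) ) .
```

With fewer than 1% of steps labelled, maximum likelihood barely feels the
labels. The package therefore maximizes the **weighted likelihood**

```
L_α = δ P(y₁,z₁)^{w_α(z₁)} ∏_{t≥2} Γ P(y_t,z_t)^{w_α(z_t)} 1ᵀ ,
w_α(z) = 1 if z is a label, α ∈ [0,1] if z = ∅,
```

so unlabelled observations are down-weighted by `α`: `α = 1` is the
ordinary joint likelihood, `α = 0` treats unlabelled steps as totally
missing, and cross-validation over a small grid (anchored at
`|T_lab| / (T − |T_lab|)`, which balances the two contributions) selects
the weight. The package provides:

* constrained ML fitting with random restarts (`phmm_fit()`), supporting
  transition support masks, parameter ties and fixes, normal / gamma /
  shifted-t / multivariate log-normal emissions, and certain or
  categorical label rules;
* forward–backward and Viterbi decoding (`phmm_posterior()`,
  `phmm_viterbi()`, `terminal_event_probability()`);
* cross-validated α selection with soft sensitivity/specificity and AUC
  (`phmm_cv()`, `candidate_alphas()`, `split_profile()`);
* the full simulation study: a 2-state shifted-t generator with sparse
  exact labels, an 11-experiment grid, misspecified Gaussian fits and
  test-set AUC (`build_sim_params()`, `experiment_grid()`,
  `run_experiment()`);
* biologging feature extraction for 50 Hz tag records: dive segmentation,
  two-second window features (change in depth, heading total variation,
  normalized jerk peak), crunch-based labelling, and a synthetic trace
  generator (`segment_dives()`, `dive_features()`, `synth_tag_trace()`),
  plus ready-made dive-type and foraging model structures
  (`case1_model_spec()`, `case2_model_spec()`).

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fits, `autoplot()` on fits and cross-validation results. A
thin CLI over the same functions lives at `inst/scripts/wlphmm-cli.R`
(subcommands `fit`, `decode`, `cv`, `simulate`, `synthdata`, `features`).

## Worked example

Simulate a sparsely labelled series from the package's generating model,
fit PHMMs at two weights, and compare held-out-style decoding accuracy on
an independent test series:

```r
library(wlphmm)

model <- build_sim_params()            # 2 states, shifted t(4), kappa = 1
train <- sample_series(model, 2000, seed = 3)
z     <- sample_labels(train$state, ell = 0.01, seed = 103)
d     <- data.frame(y = train$y, label = z)

spec <- phmm_spec(2, emission_spec("y", family = c(y = "normal")), init = "free")
fit  <- phmm_fit(d, spec, alpha = 0.01, n_restarts = 3, seed = 3)
glance(fit)
#> # A tibble: 1 × 8
#>   loglik alpha n_states n_series n_obs n_labels n_restarts converged
#>    <dbl> <dbl>    <int>    <int> <int>    <int>      <int> <lgl>
#> 1  -76.9  0.01        2        1  2000       20          3 TRUE

test <- sample_series(model, 2000, seed = 203)
post <- phmm_posterior(data.frame(y = test$y), spec, fit$params)
auc_score(post$state2, test$state == 2)
#> [1] 0.9809041
```

The down-weighted fit keeps two distinct state locations (fitted means
`-0.78` and `0.23` against generating locations `∓0.71`) despite the
Gaussian emission being misspecified against the t(4) noise, and its 20
labels are enough to anchor state identity. Refitting the same data with
`alpha = 1` collapses both means to about `-0.5` (one state absorbs the
heavy tails) and drops the test AUC to `0.727` — the failure mode the
weighting exists to avoid. `phmm_cv()` automates this comparison across a
weight grid with proper held-out decoding per fold.

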