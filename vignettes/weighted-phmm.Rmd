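---
title: "Weighted-likelihood partially hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-likelihood partially hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlphmm)
```

## The model

A hidden Markov model (HMM) describes a multivariate time series
$\mathbf{Y} = (Y_1, \dots, Y_T)$ through an unobserved Markov chain
$X_t \in \{1, \dots, N\}$ with initial distribution $\delta$ and transition
matrix $\Gamma$; given $X_t = i$, the observation $Y_t$ has state-dependent
density $f^{(i)}(\cdot\,; \theta^{(i)})$.

In many biologging studies a sparse subset
$\mathcal{T} \subset \{1, \dots, T\}$ of time steps additionally carries a
behavioural label $Z_t$ — a drone saw the whale resting, a hydrophone
recorded a prey-handling crunch. We model each label as generated from its
hidden state with mass function $g^{(i)}(z_t)$ and write $z_t = \emptyset$
(with $g^{(i)}(\emptyset) = 1$) for unlabelled steps, giving a *partially
hidden Markov model* (PHMM): the joint density is the usual matrix product
$\delta P(y_1, z_1) \prod_{t \ge 2} \Gamma P(y_t, z_t) \mathbf{1}^\top$ with
$P$ diagonal, entry $(i,i) = f^{(i)}(y_t)\, g^{(i)}(z_t)$. Under the
**certain-label rule** (the default here), a labelled step's label equals
its hidden state with probability 1, so $g^{(i)}(z) = \mathbf{1}\{z \in \{i,
\emptyset\}\}$; a categorical rule with estimated per-state label
probabilities $\beta^{(i)}$ is also implemented for less trusted labels.

When labels are rare (often well below 1% of steps), they barely move
maximum-likelihood estimates: the likelihood is dominated by the unlabelled
bulk. The remedy implemented here is a **weighted likelihood**: each step's
diagonal emission–label factor enters raised to the power

$$
w_\alpha(z_t) = \begin{cases} 1 & z_t \in \{1, \dots, N\} \\
\alpha & z_t = \emptyset \end{cases}, \qquad \alpha \in [0, 1],
$$

so unlabelled observations are down-weighted by $\alpha$ while labelled
ones keep full weight. Because $P$ is diagonal, the matrix power is an
element-wise power and the weighted product is still evaluated by a forward
recursion. Three identities anchor the implementation and are enforced by
tests:

* $\alpha = 1$ recovers the log of the standard PHMM joint density;
* $\alpha = 0$ equals the likelihood of an HMM that treats every unlabelled
  observation as totally missing (each such step contributes a bare
  $\Gamma$ factor); with no labels at all it is exactly $0$ on the log
  scale, since the rows of $\Gamma$ sum to one;
* for a fully labelled series the value does not depend on $\alpha$.

Weights above 1 would favour unlabelled over labelled data; `phmm_fit()`
and `phmm_loglik()` reject them unless `allow_alpha_gt1 = TRUE`.

Multiple series (tag deployments, dives) are treated as independent with
shared parameters; the total log-likelihood is the sum of per-series terms.

## Choosing the weight by cross-validation

`candidate_alphas(T, n_labels)` returns
$\{0,\; |\mathcal{T}|/(T - |\mathcal{T}|),\; 1\}$; the middle value
approximately balances the *total* likelihood contribution of labelled and
unlabelled steps. Users may densify the grid with midpoints.
`phmm_cv()` then, for each candidate and each fold (by default every series
is a fold, which keeps training and held-out data independent): fits on the
complement, runs the forward–backward algorithm on the held-out series
*with labels excluded*, and pools the held-out posteriors. Metrics are
soft sensitivity and specificity (class-conditional means of posterior
probabilities over labelled steps, not hard classifications) and AUC in its
Mann–Whitney form (ties count one half), either pooled over all held-out
labels or computed per fold and averaged — both conventions are useful
depending on whether folds are balanced.

Two guard rails:

* at $\alpha = 0$ a state with no labels anywhere (and no tie to a labelled
  state) has no data at all informing its emission parameters, so the model
  is unidentifiable; `guard_identifiability()` errors before such a fit and
  `phmm_cv()` records the failure per cell without aborting other cells;
* `split_profile()` splits one long series into two label-balanced
  subprofiles for use as folds; with an odd label count the two halves
  differ by exactly one label, and the split point is drawn uniformly among
  all points achieving the best balance.

## Fitting

`phmm_fit()` maximizes the weighted log-likelihood directly with BFGS on an
unconstrained *working vector* (`pack()`/`unpack()`):
row-wise multinomial logits over the *supported* transition entries only
(structural zeros are never represented, hence exact), log standard
deviations and log gamma means/sds, `log(df - 2)` for t degrees of freedom,
a log-Cholesky factor for log-normal covariances, and softmax logits for a
free initial distribution and for categorical label probabilities. Tied
states share one coordinate block and fixed parameters are omitted, so
every iterate satisfies every structural constraint exactly. Direct
maximization is used instead of EM because fractional weights break the
complete-data decomposition that EM relies on.

Each of `n_restarts` (default 10) restarts draws a starting point with
emission locations spread over data quantiles, scales near the pooled data
dispersion, and transition rows Dirichlet-perturbed around a diagonally
dominant matrix; restart seeds derive from one user seed through a counter
stream, so any restart can be re-run individually. The per-restart table
(initial and final log-likelihood, convergence flag) is kept on the fit
object so multimodality can be audited. Optimizer settings default to
`maxit = 300`, `reltol = 1e-9`; the achieved optimum, not the optimizer,
is the contract — the final log-likelihood never falls below the starting
point's. When a fit uses no labels and the states are fully exchangeable,
states are reported in increasing order of the first feature's location.

Numerical safety: the forward recursion (C++ for the likelihood, R for
decoding) normalizes per step and accumulates normalizers in log space,
with a per-step max shift before exponentiation, so series of length 20000
evaluate without under- or overflow. A certain-label configuration that is
jointly impossible under the transition support yields $-\infty$ with a
diagnostic rather than an exception. A step whose features are all missing
contributes only its transition (and label) factor.

**Known limitation.** At exactly $\alpha = 0$ with Gaussian emissions and a
single labelled point in some state, the likelihood is unbounded (the
classic supervised-MLE degeneracy $\sigma \to 0$); any $\alpha > 0$
restores boundedness because down-weighted observations still penalize a
collapsing scale. This is a property of the model, not the optimizer; the
simulation design's at-least-two-labels-per-state rule keeps it rare, but
users should expect $\alpha = 0$ to be fragile with very few labels per
state.

## Decoding

Decoding is always *unweighted*: $\alpha$ is an estimation-time concept,
and held-out evaluation runs the plain forward–backward algorithm on the
conditioning evidence. `phmm_posterior()` conditions on observations only
by default; `use_labels = TRUE` additionally conditions on observed labels,
which under the certain rule pins labelled steps to their label. (Whether
full-data reporting should condition on labels is a genuine modelling
choice; it is exposed as a flag rather than decided silently.)
`phmm_viterbi()` returns the jointly most probable path, ties broken toward
the lower state index, plus its log joint probability.
`terminal_event_probability()` sums a series' final posterior row over a
state set — in the foraging model, the probability that a dive ends in
`capture` or `ascent_fish`, i.e. was a successful foraging dive — and
`threshold_events()` hard-labels series at a configurable threshold
(default: strictly above 0.5).

## The simulation study

`build_sim_params()` defines the generating process used throughout the
package's own evaluation: two states,

$$\Gamma = \begin{pmatrix} 0.99 & 0.01 \\ 1 - \gamma & \gamma \end{pmatrix},$$

initial distribution equal to the stationary distribution
$\big((1-\gamma)/(1.01-\gamma),\ 0.01/(1.01-\gamma)\big)$, and shifted-t
emissions $Y_t = \pm \tfrac{\kappa}{2}\sqrt{\nu/(\nu-2)} + \epsilon_t$,
$\epsilon_t \sim t(\nu)$, so the state locations sit $\kappa$ emission
standard deviations apart. The control configuration is $T = 2000$,
$\gamma = 0.95$, $\nu = 4$, label proportion $\ell = 0.01$, $\kappa = 1$;
`experiment_grid()` adds the ten one-setting perturbations
($T \in \{200, 20000\}$, $\gamma \in \{0.75, 0.99\}$,
$\nu \in \{2.5, 100\}$, $\ell \in \{0.001, 0.1\}$,
$\kappa \in \{0.5, 2\}$), eleven experiments in all.

`sample_labels()` draws $\mathrm{round}(\ell T)$ label indices uniformly
without replacement and rejection-resamples until both states carry at
least two labels (when $\mathrm{round}(\ell T)$ is below that minimum —
e.g. $\ell = 0.001$, $T = 2000$ — the count is raised to it, since the
constraint cannot otherwise hold); labels equal the true states exactly.
`run_experiment()` then fits **deliberately misspecified** 2-state
Gaussian-emission PHMMs over the weight grid
$\{0, 0.001, 0.01, 0.1, 0.5, 1\}$, decodes an independently generated test
series of the same length with labels ignored, and scores the state-2
posterior against the true test path with AUC. Each replicate gets its own
test series; fitted models leave $\delta$ free. The heavy t(4) tails are
the point of the exercise: an equally weighted fit tends to spend one
Gaussian state on the tails (a wide near-zero-mean state) rather than on
the true locations, and down-weighting the unlabelled bulk toward
$\alpha \approx \ell$ restores the intended two-location structure.

Problem sizes in this package's own checks: the distributional properties
of the generator use large single draws ($T = 10^5$) or a few thousand
replicates; the headline control experiment is evaluated on 100 replicates
with 3 random restarts per fit, and the secondary comparisons (separation
monotonicity, dense-label behaviour) on smaller replicate counts. These
are the package's choices for a single-machine run; the restart count
matters little here because the sparse labels anchor state identity.

## Biologging features

The feature pipeline mirrors standard practice for suction-cup tag records
sampled at 50 Hz:

* **Dives**: maximal runs with depth > 0.5 m lasting at least 30 s
  (`segment_dives()`); negative depth readings are clipped to 0 and
  counted. Dive-type modelling (`case1_model_spec()`) summarizes each dive
  by maximum depth and duration, jointly bivariate log-normal per state —
  the support truncation induced by the dive definition is knowingly
  ignored, as is common.
* **Foraging dives**: only dives with maximum depth strictly greater than
  30 m enter the within-dive model (`case2_model_spec()`), since prey
  captures concentrate below that depth; the cutoff's strictness at
  exactly 30 m is a convention.
* **Windows**: each dive is tiled with consecutive 2 s (100-sample)
  windows; a final partial window is dropped. Features per window: change
  in depth (last minus first reading), heading total variation (sum of
  absolute successive differences, each wrapped to $(-\pi, \pi]$ first —
  unwrapped differences would spike at the seam), and jerk peak (maximum
  norm of successive acceleration differences), the latter normalized by
  the median jerk peak over the dive's *bottom* windows (mean depth at
  least 70% of maximum depth).
* **Ascent onset**: the sample after the *last* time depth was at least
  70% of the dive maximum. The last-crossing reading is deliberate: a
  first-crossing rule would start "ascent" at the top of the bottom phase
  on the way down, contradicting the descent–bottom–ascent ordering the
  transition structure encodes.
* **Labels**: the first window of every dive is `descent`; crunches more
  than 30 s before ascent onset are ignored; the first remaining crunch
  labels its window `capture` if before ascent, else the final window
  `ascent_fish`; a fully video-covered dive with no crunch and no visual
  foraging labels its final window `ascent_nofish`. At most one
  foraging-related label is emitted per dive, and contradictory
  annotations (foraging seen, yet fully covered and crunch-free) error.

The six-state model fixes $\delta = (1,0,\dots,0)$ (every dive starts in
descent), allows descent→{descent, bottom, ascent}, bottom↔chase,
chase→capture, capture→{capture, ascent with fish}, makes both ascent
states absorbing, pins the change-in-depth means of the bottom, chase and
capture states to 0 (no net vertical movement at the bottom), and ties the
two ascent states' emissions so that foraging discrimination rests on the
capture state rather than on ascent differences.

`synth_tag_trace()` generates scripted 50 Hz traces — square or v-shaped
dives with exactly known sample intervals, a wrapped random-walk heading,
baseline accelerometer noise with bursts at scripted chase times, crunch
timestamps and video intervals — and returns the script as ground truth.
It emulates the *geometry and annotation structure* of real deployments,
not sensor noise, drift, or surface splash artefacts; pipeline tests
passing on it certify the bookkeeping (segmentation, tiling, labelling
rules, invariances), not field robustness.

## Numerical and design choices, in brief

* Gamma emissions are user-parameterized by mean and standard deviation
  and converted exactly to shape/rate (the convention in movement
  ecology); `df > 2` is enforced wherever a finite standard deviation is
  referenced.
* The balance weight printed by `candidate_alphas()` is
  $|\mathcal{T}|/(T - |\mathcal{T}|)$; with $|\mathcal{T}| = 106$ of
  $T = 2169$ steps this is $\approx 0.0514$ (reports sometimes quote
  $|\mathcal{T}|/T \approx 0.049$ for the same data; the ratio-to-unlabelled
  form is the one implemented).
* Viterbi ties break toward the lower state index; `which.max` semantics,
  deterministic.
* All randomness (restarts, splits, simulations, CV cells) derives from
  single user seeds via counter streams; equal seeds give identical
  results, including byte-identical CSV output.
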