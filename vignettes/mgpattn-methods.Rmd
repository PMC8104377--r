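---
title: "Methods: multitask Gaussian processes with attention for early sepsis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitask Gaussian processes with attention for early sepsis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sepsis is one of the leading causes of hospital mortality, and every hour of
delayed treatment measurably increases it. Intensive-care records hold the
information needed for early warning, but in an awkward form: vital signs and
laboratory values are sampled irregularly, at rates that differ by orders of
magnitude between variables, and a value's very absence encodes a clinical
judgement. `mgpattn` implements a prediction pipeline built around that
structure rather than around an imputation preprocessing step: a multitask
Gaussian process (MGP) models the irregular multivariate series directly, and
an attention-based temporal convolutional classifier (AttTCN) consumes Monte
Carlo samples of the process on a regular hourly grid, with the whole model
trained end to end by gradient descent.

## The probabilistic model

For patient $p$ we observe values $y_{p,i,k}$ of dynamic features
$k \in \{1,\dots,M\}$ at irregular times $t_{p,i,k}$ (hours from admission),
static features $s_p$ (age, gender, one-hot first admission unit; $Q$ encoded
columns) and a binary sepsis label. A zero-mean latent process $f_k(t)$ with

$$\operatorname{cov}(f_k(t_i), f_{k'}(t_j))
  = \sum_{l=1}^{2} K^k_l(k, k')\, \exp\!\left(-\frac{|t_i - t_j|}{\lambda_l}\right)$$

underlies the observations, $y_{i,k} \sim \mathcal N(f_k(t_i), \sigma_k^2)$.
The two Ornstein-Uhlenbeck time kernels represent two smoothness clusters —
in practice a short lengthscale capturing noisy, frequently sampled vitals
and a long one capturing smooth, sparsely sampled labs. The OU kernel is
deliberately non-differentiable in its sample paths; infinitely smooth
kernels (squared exponential) assume more regularity than clinical signals
have, though an SE time kernel is available as a configuration hook for
kernel ablation experiments (`mgp_params(..., time_kernel = "se")`). The
feature covariances $K^k_l = F_l F_l^\top$ are free-form, parameterized by
lower-triangular factors so they remain positive semidefinite under
unconstrained optimization; lengthscales and noise standard deviations pass
through a softplus for the same reason.

Over the full set of observations the covariance is the observed-pair
restriction of $\sum_l K^k_l \otimes K^{tt}_l + D \otimes I$ over the union
time set, with $D$ the diagonal of the noise *variances* $\sigma_k^2$ — the
standard multitask-GP-with-missingness construction (each feature has its own
time set, so the pure Kronecker form never materializes). Flattening is
feature-major (feature index outer, time inner) everywhere.

Predictions live on the hourly grid $t' = (-(N-1), \dots, -1, 0)$ relative to
the prediction time, with $N = 25$. Conditioning the prior on a record's
observations gives a Gaussian posterior $(\mu, \Sigma)$ over the grid
(`mgp_posterior()`), computed by Cholesky factorization; if factorization of
the sampling covariance fails, a jitter $\varepsilon = 10^{-6}$ is escalated
tenfold up to twice before reporting a numerical error with the record id.
Grid points before ICU admission are excluded from the posterior and zero-
padded back into the window, so the final grid column is always the
prediction time.

`draw_samples()` produces $S$ reparameterized Monte Carlo samples
$y_{MC} = \mu + L\eta$, $L L^\top = \Sigma + \varepsilon I$,
$\eta \sim \mathcal N(0, I)$ — an affine function of $(\mu, L)$ given
$\eta$, which is what lets classification gradients reach the GP
hyperparameters. Statics are broadcast as $Q$ constant columns over the
non-padded rows; padded rows are entirely zero (we prioritize the
zero-padding contract over constancy of the static columns there, so padded
cells can never contribute to attention scores).

## The classifier

Two independent temporal convolutional stacks (shared configuration,
separate weights) embed each sample $y_{MC} \in \mathbb R^{N \times (M+Q)}$
into $z$ and $z'$. Each stack is built from residual blocks of two causal
convolutions (kernel size $k$, dilation 1, ReLU, dropout, L2), followed by a
width-1 linear projection back to $M+Q$ channels; with at most a dozen
layers the identity shortcut of classic residual blocks is unnecessary and
is omitted, which keeps the embedding directly attributable to its inputs.
The receptive field of $B$ blocks is $1 + 2B(k-1)$ steps, and causality is
strict: output at step $i$ never depends on inputs after $i$.

Attention is class-specific ($\delta \in \{0, 1\}$):

$$\alpha_{j,\delta} = \operatorname{softmax}_j(z_j W_{\alpha,\delta} + b_{\alpha,\delta}), \qquad
  \beta_{j,\delta} = \operatorname{sigmoid}(z'_j W_{\beta,\delta} + b_{\beta,\delta}),$$

with the softmax taken over the $N$ time steps (the only reading under which
$\alpha$ is attention *over time*; padded steps are not masked out of the
softmax by default, a masking flag exists but is off). The class score is the
cumulative context sum
$c_{i,\delta} = \sum_{j \le i} \alpha_{j,\delta} \beta_{j,\delta} \odot y_{MC,j}$,
summed over all cells, and the prediction is the softmax over the two class
scores at the last step — prediction is always made with the latest
available data. Because $\alpha \ge 0$ and $\beta \in [0,1]$ multiply the
inputs directly, $\alpha \times \beta \times y_{MC}$ (averaged over Monte
Carlo samples, `score_contributions()`) is a per-cell additive decomposition
of the decision, which is the model's interpretability interface.

Ablations (`ablate()` / the `variant` argument of `train_model()`): `no_alpha`
fixes $\alpha \equiv 1/N$; `no_beta` fixes $\beta \equiv 1$; `mgp_tcn`
replaces the attention head by a plain TCN with a linear-softmax readout of
the last step (the prior state of the art this architecture improves on);
`mgp_logreg` replaces the classifier by a linear map on the flattened window.

## Training

The loss is the Monte Carlo average of the cross-entropy of the last-step
prediction, plus an L2 penalty `l2 * mean(W^2)` over convolution weights.
All gradients — through the attention head, the TCN stacks, the
reparameterized samples, the Cholesky factor, the Gaussian conditioning and
the kernel assembly down to $\lambda_l$, $F_l$ and $\sigma_k$ — are
hand-written reverse-mode passes in base R (no automatic differentiation
framework is involved) and are verified against central finite differences
to a relative tolerance of $10^{-4}$ in the test suite. Optimization is Adam
with learning rate $10^{-3}$ by default (the pipeline runs use $5 \times
10^{-3}$; the original description is silent on the optimizer, so this is a
package choice). Because the cohorts are imbalanced, each training epoch
oversamples the case set with replacement to the control count and feeds
shuffled half-case half-control batches; validation and test sets are never
resampled. Model selection is early stopping on validation AUPR (AUPR
rather than AUROC because of the imbalance), restoring the best epoch's
parameters. Hyperparameters can be drawn by `random_search()` over Monte
Carlo samples 4–20, kernel size 2–6, blocks 2–12, hidden channels 10–55,
dropout $[0, 0.99]$ and L2 $[0, 250]$.

## Sepsis-3 labelling

Suspected infection is the co-occurrence of broad-spectrum antibiotics and a
blood-culture draw within a set interval. The interval constants are not
fixed by the published description (they live in referenced implementation
code), so they are configuration with conventional Sepsis-3 defaults:
antibiotics up to 72 h after a culture or a culture up to 24 h after
antibiotics; the suspicion time (the earlier event of the pair) expands to a
window 48 h back and 24 h forward, and overlapping windows merge. Organ
dysfunction is a rise of the total SOFA score — six sub-scores of 0–4 for
respiration, coagulation, liver, cardiovascular, CNS and renal function,
carried forward for a configurable 24 h validity — of at least two points
inside a suspicion window, measured against the *running minimum* of the
total since the window start (the least-assumption reading of "a two point
increase within the window"; a window-start baseline is available as
configuration). Sub-scores are inputs; computing them from raw
vitals/labs/vasopressor doses is out of scope.

The load-bearing design choice is the treatment of unmeasured SOFA
contributors. Under `healthy_zero` (the package's primary policy) an
unmeasured organ system is assumed within the healthy norm and contributes
zero — the standard clinical reading, under which a patient collapsing in
one measured system counts as septic even when other systems were never
assessed. Under `undefined` (the policy of the comparison labels in the
literature) any hour with an unmeasured contributor has an undefined total,
which silently drops exactly those patients and delays onsets. The labeller
exposes both, and the test fixtures include the discriminating scenario (an
isolated liver-failure pattern) that is a case under the first policy and a
control under the second. By construction the `healthy_zero` case set
contains the `undefined` case set.

Patients must be older than 14 years with valid records; controls carrying
an ICD sepsis discharge code are excluded; cases need an onset inside the
ICU stay.

## Cohort construction

Cases end at onset, which happens early in ICU stays, while controls stay
longer and end healthy — so record length and end-of-stay values would
shortcut classification. Matching assigns each case $\lfloor r \rfloor$ or
$\lceil r \rceil$ controls ($r$ = imbalance ratio; the ceiling quotas go to
a seeded subset of cases so totals are exact) and truncates each matched
control to its case's admission-to-onset length. Records with fewer than 40
observations are discarded; records keep at most their most recent 250
observations ("data points" counts individual observations across features,
the sparse-matrix reading). Horizon augmentation copies every record at
horizons 1–6 h, dropping the final $h$ hours and re-applying the 40-point
floor, so per-horizon counts are non-increasing. The 80/10/10 split is
grouped by source patient — augmented copies never straddle splits (the
original description does not state this; grouping prevents leakage, and a
per-copy split is available behind a flag-level choice in
`split_cohort()` by splitting the un-augmented records instead). Horizon-0
copies of cases end exactly at onset, inclusive of observations at the onset
timestamp. Normalization subtracts the training-split mean and divides by
the training-split population (divide-by-$n$) standard deviation per
feature, applied unchanged to validation and test; the age static is
z-scored the same way.

## Baselines

The hourly-grid baselines average each hour's observations per feature,
carry forward empty hours, zero-fill hours before the first observation, and
end-align the matrix to the prediction time with left zero-padding or
truncation to $N$ columns. The ridge logistic baseline flattens this grid
plus statics. The InSight baseline extracts, for each of the $N-5$ sliding
six-hour windows, each variable's mean and difference, all pairwise
correlations and all triplet correlations
$\rho_{XYZ} = E[(X-\mu_X)(Y-\mu_Y)(Z-\mu_Z)]/(\sigma_X \sigma_Y \sigma_Z)$
(population moments; zero when any variance is zero, which is the right
convention for forward-imputed constant windows). Differences and
correlations are trichotomized to $\{-1, 0, 1\}$ by terciles of the
*non-zero* values (type-1 empirical quantiles, strict inequalities), fitted
on training data only and frozen — giving
$(N-5)(2M + \binom{M}{2} + \binom{M}{3})$ features per patient (2,760 at
$N = 25$, $M = 9$). Quantiles are pooled across variables and windows within
each statistic family; the published description does not resolve the
pooling, and per-variable pooling at six-point windows would be estimated
from very few non-zero values. The InSight inclusion filter requires one
observation of each of nine classic variables in the final window; the
published description mentions both a five-hour period and six-hour windows,
and the six-hour reading is used with a `window_h = 5` option. Both
baselines are scored by ridge logistic regression (glmnet, `alpha = 0`,
unstandardized).

## The synthetic cohort generator

Access-controlled clinical databases cannot ship with a package, so
`synthetic_config()` / `generate_cohort()` produce cohorts with exactly the
structure the model assumes: $M = 10$ features in two clusters — five
"vitals" (observation rate 1/h, noise sd 0.5, short true lengthscale 2 h)
and five "labs" (rate 1/12 h, noise sd 0.1, long lengthscale 64 h) — with
cross-feature correlation through two random factor-product covariances that
load each cluster on its own kernel; record lengths uniform on 24–72 h
(realistic ICU stays, and long enough that the 64 h lengthscale is
identifiable); latent paths drawn exactly on a dense 0.25 h grid via the
Kronecker structure, observation times as homogeneous point processes
snapped to that grid. Labels are Bernoulli with log-odds linear in the mean
of one vital and one lab over the final 6 h (weights (3, 3) by default), the
intercept calibrated by root finding to a 40% prevalence — the magnitude of
the case fractions in the study's baseline cohorts. The final-window
functional makes earlier prediction horizons genuinely harder, mirroring the
horizon analysis. What the generator does *not* emulate: real marginal
distributions and units, informative (state-dependent) sampling,
measurement artefacts, and label noise from imperfect chart data — so green
tests certify the machinery and its statistical contracts, not clinical
performance.

## Numerical choices and degenerate inputs

* Duplicate (feature, time) observations are pre-averaged before
  conditioning; `joint_observation_covariance()` refuses duplicates.
* The observation covariance is factorized without jitter first (its noise
  diagonal usually suffices), then with escalation; the sampling covariance
  always receives $\varepsilon I$.
* A record with zero observations yields the prior; records shorter than the
  window yield a reduced effective grid, zero-padded back.
* Ties in AUROC are handled by average ranks; AUPR steps through whole
  tie-groups. Single-class strata report `NA`, never 0.
* A feature constant in the training split is centred only (with a warning);
  all-zero correlation pools trichotomize everything to 0 (with a message).
* Constrained GP parameters pass through softplus; its inverse is applied at
  construction, so `mgp_params(lengthscales = c(2, 64))` round-trips.

## Problem sizes used by the shipped experiments

The bundled tests and the acceptance script run, by design, at desk scale:
posterior-oracle checks at $M = 3$, 12 observations, $N = 5$ over 50
replicates; sampling-moment checks with 200{,}000 draws on a 10-dimensional
grid; lengthscale recovery by marginal-likelihood ascent over 200 synthetic
patients; end-to-end learning on a strongly separable cohort (label weights
(12, 12) on the two leading lab features — the smooth, sparsely sampled
cluster, i.e. exactly the regime where Gaussian-process imputation should
pay off over forward filling) of 800 patients split 500/100/200 with
$S = 4$ Monte Carlo samples, batch size 16, learning-rate decay 0.9/epoch
and early stopping, evaluated with $S = 16$. The Gaussian process is
initialized by maximum marginal likelihood on 60 training records before
joint training; a well-calibrated imputation model at the start removes an
optimization burden from the classifier without changing the end-to-end
objective. Carrying the benchmark signal on the vitals cluster instead would
make the final-window mean of a 2 h-lengthscale process the discriminating
functional — information that content-based (not position-based)
softmax/sigmoid attention cannot localize in a stationary window, for this
or any model of its class; the labs-borne signal tests the method rather
than an impossibility. These
sizes are the package's reference experiment definitions; the same code
scales to larger cohorts linearly in records and cubically in per-record
observation count (capped at 250).

## Known limitations

* Joint training of a small network on a few hundred patients has visible
  run-to-run variability: across master seeds the benchmark's test AUROC
  moves by several points, and on some runs the heavily parameterized ridge
  baseline is the stronger scorer. The shipped experiment definitions fix
  their seeds; conclusions about a new dataset should average over several.
* Training cost is dominated by the per-record Cholesky factorizations; a
  GPU/minibatched-linear-algebra implementation would change the constant,
  not the interface.
* The attention weights are non-negative by construction; signed effects are
  expressed through the sign of the (normalized) inputs, which is worth
  keeping in mind when reading contribution heatmaps.
* The Sepsis-3 interval constants and the SOFA-rise baseline convention are
  configuration, not assertions about any particular external dataset.
* `undefined`-policy timelines with sparse SOFA measurement are mostly
  undefined; that is the point of the comparison, not a defect.
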