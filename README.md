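# mgpattn

Early sepsis prediction from irregularly sampled intensive-care time series,
with an interpretable end-to-end model: a **multitask Gaussian process**
(MGP) imputes vitals and labs onto a regular hourly grid, and an
**attention-based temporal convolutional classifier** (AttTCN) turns Monte
Carlo samples of the posterior into class probabilities — trained jointly by
gradient descent, so the imputation model is optimized for the prediction
task rather than for data fit alone.

The package is aimed at researchers working on clinical early-warning
models: it provides the model, the Sepsis-3 labelling machinery, the cohort
construction pipeline, the classic baselines (InSight window statistics,
ridge logistic regression on the hourly grid, MGP + logistic regression and
attention ablations), and a synthetic cohort generator so everything can be
developed and tested without credentialed access to clinical databases.

## The model

Observations `y[i,k]` of feature `k` at irregular time `t[i]` are noisy
draws from a latent process with covariance

    cov(f_k(t_i), f_k'(t_j)) = sum_{l=1,2} K_l[k,k'] * exp(-|t_i - t_j| / lambda_l)

— two Ornstein-Uhlenbeck smoothness clusters (short lengthscale: noisy,
frequent vitals; long: smooth, sparse labs) with free-form feature
covariances `K_l = F_l F_l'`. Conditioning on a record's observations gives
a Gaussian posterior on the hourly grid `t' = -(N-1), ..., 0` (N = 25)
ending at the prediction time; reparameterized samples `y_MC = mu + L eta`
feed two causal-convolution stacks that produce class-specific attention
over time (`alpha`, softmax) and over features (`beta`, sigmoid). The class
score is `sum_j alpha_j * beta_j . y_MC,j`, and `alpha * beta * y_MC` is a
per-cell decomposition of the decision — the interpretability output.
All gradients (through the Cholesky factor and the kernels down to
`lambda`, `F_l` and the noise) are hand-written reverse-mode passes,
verified against finite differences in the test suite.

## Worked example

```r
library(mgpattn)

# a synthetic cohort with the structure the model assumes
cfg <- synthetic_config()            # 5 vitals + 5 labs, lengthscales 2 h / 64 h
cohort <- generate_cohort(cfg, n_patients = 60, seed = 1)
mean(vapply(cohort, `[[`, integer(1), "label"))
#> [1] 0.4166667

# impute one record onto the hourly grid
roster <- cfg$roster
params <- mgp_params(roster$M, lengthscales = c(2, 64),
                     factors = cfg$factors,
                     noise_sd = as.numeric(cfg$noise_sd))
post <- mgp_posterior(params, cohort[[1]], roster)
round(tail(matrix(post$mean, post$n_eff, roster$M)[, 1], 3), 2)
#> [1] 2.28 1.40 0.82     # posterior mean of vital_1 over the last three hours
batch <- draw_samples(post, cohort[[1]]$statics, S = 4, seed = 2)
dim(batch$samples)
#> [1] 25 15  4      # N x (M + Q) x S

# label an event table under the Sepsis-3 rules
fx <- generate_event_fixtures(8)
head(label_cohort(fx$events, missing_policy = "healthy_zero"), 4)
#>   patient_id   class onset_time        exclusion_reason
#> 1    fix_001 control         NA                    <NA>
#> 2    fix_002    case         14                    <NA>
#> 3    fix_003 control         NA                    <NA>
#> 4    fix_004    case         10                    <NA>
```

The `fix_004` patient is the discriminating scenario: an isolated liver
sub-score rise with every other organ system unmeasured — a **case** under
the missing-contributor-as-healthy policy, a control under the comparison
`undefined` policy.

A full run (generate, match, filter, augment, split, normalize, train,
evaluate, baselines) is one call:

```r
res <- run_pipeline(tempfile(), n_patients = 200, epochs = 4, seed = 1)
res$report        # per-horizon AUROC / AUPR on the test split
```

A thin command-line wrapper with the same stages lives in
`inst/cli/mgpattn.R` (`Rscript mgpattn.R synth-generate --n 200 --out dir`).

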