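# InSight features: window statistics, pair/triplet correlations,
# adjusted-quantile trichotomization, feature-matrix width, ridge scorer.

grid_from_matrix <- function(V, statics = c(age = 0)) {
  structure(list(values = V, statics = statics,
                 mask = rep(FALSE, nrow(V)), label = 0L,
                 horizon = NA_integer_, patient_id = "g"),
            class = "dense_grid")
}

test_that("window statistics cover N - 5 windows with mean and difference", {
  V <- matrix(5, 25, 2)
  ws <- window_stats(grid_from_matrix(V))
  expect_equal(dim(ws$means), c(20, 2))
  expect_true(all(ws$means == 5))
  expect_true(all(ws$diffs == 0))

  V2 <- matrix(1:6, 6, 1)
  ws2 <- window_stats(grid_from_matrix(V2))
  expect_equal(ws2$means[1, 1], 3.5)
  expect_equal(ws2$diffs[1, 1], 5)
  expect_error(window_stats(grid_from_matrix(matrix(0, 4, 1))), "fewer")
})

test_that("pair correlation uses population moments and the zero convention", {
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(pair_correlation(x, x), 1)
  expect_equal(pair_correlation(x, -x), -1)
  expect_equal(pair_correlation(rep(2, 6), x), 0)
})

test_that("triplet correlation is symmetric and matches the skewness oracle", {
  set.seed(17)
  # x = y = z reduces to the population skewness
  for (rep in 1:5) {
    x <- rnorm(6)
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    skew <- mean((x - m)^3) / s^3
    expect_equal(triplet_correlation(x, x, x), skew, tolerance = 1e-12)
  }
  # symmetry under argument permutation
  x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
  base <- triplet_correlation(x, y, z)
  for (p in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    args <- list(x, y, z)[p]
    expect_equal(do.call(triplet_correlation, args), base, tolerance = 1e-12)
  }
  # a periodic pattern symmetric about its mean has zero third moment
  expect_equal(triplet_correlation(c(1, 2, 3, 1, 2, 3), c(1, 2, 3, 1, 2, 3),
                                   c(1, 2, 3, 1, 2, 3)), 0, tolerance = 1e-12)
  expect_equal(triplet_correlation(rep(1, 6), y, z), 0)
})

test_that("adjusted-quantile trichotomization uses type-1 terciles of nonzeros", {
  tri <- fit_trichotomizer(c(0, 0, 1:9, 0))
  expect_equal(tri$lo, 3)
  expect_equal(tri$hi, 6)
  expect_equal(trichotomize(tri, c(7, 2, 4, 0)), c(1L, -1L, 0L, 0L))

  single <- fit_trichotomizer(c(0, 5, 0))
  expect_equal(trichotomize(single, 5), 0L)   # strict inequalities

  mixed <- fit_trichotomizer(c(-3, -2, -1, 1, 2, 3))
  expect_true(mixed$lo <= 0 && mixed$hi >= 0)
  expect_equal(trichotomize(mixed, 0), 0L)

  expect_message(allz <- fit_trichotomizer(rep(0, 5)), "zero")
  expect_equal(trichotomize(allz, c(-1, 0, 1)), c(-1L, 0L, 1L))
})

test_that("the feature matrix has the closed-form width", {
  set.seed(19)
  mk <- function(N, M) grid_from_matrix(matrix(rnorm(N * M), N, M))
  fm <- build_feature_matrix(list(mk(25, 9), mk(25, 9)))
  expect_equal(fm$n_features, 20 * (18 + 36 + 84))
  expect_equal(fm$n_features, 2760)
  fm2 <- build_feature_matrix(list(mk(6, 2)))
  expect_equal(fm2$n_features, 1 * (4 + 1 + 0))
  expect_error(build_feature_matrix(list(mk(6, 2), mk(6, 3))),
               "inconsistent")
  # deterministic column layout: recomputing reproduces the matrix exactly
  g <- list(mk(10, 3), mk(10, 3))
  expect_identical(build_feature_matrix(g)$X, build_feature_matrix(g)$X)
})

test_that("trichotomization thresholds freeze on the training split", {
  set.seed(20)
  mk <- function() grid_from_matrix(matrix(rnorm(18), 6, 3))
  grids <- replicate(6, mk(), simplify = FALSE)
  train <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  fm <- build_feature_matrix(grids, train = train)
  # transforming new data with the frozen thresholds is a pure function
  fm_test <- build_feature_matrix(grids[4:6],
                                  trichotomizers = fm$trichotomizers)
  expect_identical(fm$X[4:6, ], fm_test$X, ignore_attr = TRUE)
})

test_that("the inclusion filter requires recent observations of each variable", {
  roster <- feature_roster(c("heartrate", "ph_bloodgas"), c("vital", "lab"),
                           units = "U1")
  base <- function(id, feats, times) patient_record(
    id, data.frame(feature = feats, time_h = times, value = 1),
    statics = stats::setNames(c(60, 1, 1), roster$static_features),
    label = 0L, end_time = 10)
  with_ph <- base("a", c("heartrate", "ph_bloodgas"), c(9, 8))
  without_ph <- base("b", c("heartrate", "heartrate"), c(9, 8))
  stale_ph <- base("c", c("heartrate", "ph_bloodgas"), c(9, 1))
  keep <- insight_inclusion_filter(list(with_ph, without_ph, stale_ph),
                                   required = c("age", "heartrate",
                                                "ph_bloodgas"))
  expect_equal(keep, c(TRUE, FALSE, FALSE))
  expect_true(all(insight_inclusion_filter(list(without_ph),
                                           required = character(0))))
})

test_that("ridge logistic matches an independent IRLS solver", {
  set.seed(22)
  n <- 20; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5)))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  lambda <- 0.05
  fit <- fit_ridge_logistic(X, y, penalty = lambda)
  beta_glmnet <- as.numeric(coef(fit$fit))
  # independent penalized IRLS on the same objective:
  # minimize -(1/n) loglik + lambda/2 ||beta||^2 (intercept unpenalized)
  Z <- cbind(1, X)
  beta <- numeric(p + 1)
  for (it in 1:200) {
    eta <- Z %*% beta
    mu <- plogis(eta)
    W <- as.numeric(mu * (1 - mu))
    g <- -crossprod(Z, y - mu) / n + lambda * c(0, beta[-1])
    Hm <- crossprod(Z, Z * W) / n + lambda * diag(c(0, rep(1, p)))
    step <- solve(Hm, g)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  expect_lt(max(abs(beta - beta_glmnet)), 1e-4)

  # separable toy reaches perfect training accuracy under a weak penalty
  Xs <- matrix(c(rep(-2, 10), rep(2, 10)), ncol = 1)
  ys <- rep(c(0, 1), each = 10)
  fs <- fit_ridge_logistic(Xs, ys, penalty = 1e-6)
  expect_equal(as.numeric(predict(fs, Xs) > 0.5), ys)

  # infinite penalty shrinks to the prevalence
  fb <- fit_ridge_logistic(X, y, penalty = 1e6)
  expect_equal(mean(abs(predict(fb, X) - mean(y))), 0, tolerance = 1e-2)
  expect_error(fit_ridge_logistic(X, rep(1, n)), "single class")
})

test_that("the MGP-logistic ablation scores in [0, 1] and is seeded", {
  cfg <- synthetic_config(n_vitals = 1, n_labs = 1,
                          record_length_range = c(6, 10),
                          label_weights = c(6, 6))
  cohort <- generate_cohort(cfg, 30, seed = 23)
  roster <- cfg$roster
  split <- rep(c("train", "test"), c(22, 8))
  norm <- normalize_cohort(cohort, split, roster)
  dataset <- list(records = norm$records, split = split, roster = roster)
  mgp <- mgp_params(2, lengthscales = c(2, 64), factors = cfg$factors,
                    noise_sd = as.numeric(cfg$noise_sd))
  r1 <- mgp_logreg_baseline(dataset, mgp, S = 3, seed = 4, N = 11)
  expect_true(all(r1$scores >= 0 & r1$scores <= 1))
  r2 <- mgp_logreg_baseline(dataset, mgp, S = 3, seed = 4, N = 11)
  expect_identical(r1$scores, r2$scores)
})
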