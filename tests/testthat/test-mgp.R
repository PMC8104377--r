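# Multitask GP layer: kernels, joint covariance assembly, posterior
# conditioning against a brute-force oracle, sampling, marginal likelihood.

test_that("the OU kernel has unit diagonal, closed-form decay and is PSD", {
  expect_equal(ou_kernel(0, 0, lengthscale = 3)[1, 1], 1)
  expect_equal(ou_kernel(0, 2, lengthscale = 2)[1, 1], exp(-1))
  K <- ou_kernel(c(0, 1, 3), lengthscale = 2)
  expect_true(isSymmetric(K))
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >=
                -1e-10)
  expect_error(ou_kernel(0:2, lengthscale = 0), "> 0")
  expect_error(se_kernel(0:2, lengthscale = -1), "> 0")
})

test_that("joint observation covariance matches elementwise evaluation", {
  set.seed(21)
  M <- 4
  params <- random_mgp(M, seed = 21)
  feat <- sample(1:M, 15, replace = TRUE)
  tt <- sort(runif(15, 0, 20))
  A <- joint_observation_covariance(params, feat, tt)
  lam <- mgp_lengthscales(params); Kk <- mgp_feature_cov(params)
  sig <- mgp_noise_sd(params)
  for (i in 1:15) for (j in 1:15) {
    expect_lt(abs(A[i, j] -
      (Kk[[1]][feat[i], feat[j]] * exp(-abs(tt[i] - tt[j]) / lam[1]) +
       Kk[[2]][feat[i], feat[j]] * exp(-abs(tt[i] - tt[j]) / lam[2]) +
       (i == j) * sig[feat[i]]^2)), 1e-12)
  }
  # PSD after jitter: Cholesky succeeds
  expect_no_error(chol(A + diag(1e-6, 15)))
  expect_error(joint_observation_covariance(params, c(1, 1), c(2, 2)),
               "pre-averaged")
})

test_that("with one feature the covariance reduces to the scalar form", {
  params <- mgp_params(1, lengthscales = c(2, 8),
                       factors = list(matrix(0.9), matrix(0.4)),
                       noise_sd = 0.3)
  tt <- c(0, 1, 2.5)
  A <- joint_observation_covariance(params, rep(1, 3), tt)
  expected <- 0.81 * ou_kernel(tt, lengthscale = 2) +
    0.16 * ou_kernel(tt, lengthscale = 8) + diag(0.09, 3)
  expect_equal(A, expected, tolerance = 1e-12)
})

test_that("the posterior matches the brute-force conditioning oracle", {
  set.seed(31)
  roster <- feature_roster(c("a", "b", "c"), c("vital", "vital", "lab"),
                           units = "U1")
  for (rep in 1:10) {
    params <- random_mgp(3, seed = 30 + rep)
    n <- 12
    feat <- sample(1:3, n, replace = TRUE)
    tt <- sort(runif(n, 0, 10))
    rec <- patient_record(
      "o", data.frame(feature = roster$dynamic_features[feat], time_h = tt,
                      value = rnorm(n)),
      statics = encode_tiny_statics(roster), label = 0L, end_time = 10)
    post <- mgp_posterior(params, rec, roster, grid_spec(5))
    ob <- mgpattn:::record_obs(rec, roster)
    orc <- oracle_posterior(params, ob$feat, ob$t, ob$y,
                            rep(1:3, each = 5), rep(-4:0, 3))
    expect_lt(max(abs(post$mean - orc$mu)), 1e-8)
    expect_lt(max(abs(post$cov - orc$Sigma)), 1e-8)
  }
})

test_that("no observations returns the prior; zero noise interpolates", {
  roster <- tiny_roster()
  params <- random_mgp(2, seed = 5)
  rec <- patient_record("e", data.frame(feature = character(0),
                                        time_h = numeric(0),
                                        value = numeric(0)),
                        statics = encode_tiny_statics(roster), label = 0L,
                        end_time = 10)
  post <- mgp_posterior(params, rec, roster, grid_spec(4))
  expect_equal(post$mean, rep(0, 8))
  Kk <- mgp_feature_cov(params); lam <- mgp_lengthscales(params)
  prior <- kronecker(Kk[[1]], ou_kernel(-3:0, lengthscale = lam[1])) +
    kronecker(Kk[[2]], ou_kernel(-3:0, lengthscale = lam[2]))
  expect_equal(post$cov, prior, tolerance = 1e-12)

  params0 <- mgp_params(2, lengthscales = c(2, 8),
                        factors = list(diag(1, 2), diag(0.5, 2)),
                        noise_sd = c(1e-8, 1e-8))
  rec1 <- patient_record("one", data.frame(feature = "f1", time_h = 8,
                                           value = 1.7),
                         statics = encode_tiny_statics(roster), label = 0L,
                         end_time = 10)
  post1 <- mgp_posterior(params0, rec1, roster, grid_spec(4))
  # the grid runs (-3, -2, -1, 0); t' = -2 (index 2) is the observation time
  expect_lt(abs(post1$mean[2] - 1.7), 1e-6)
})

test_that("posterior variance never exceeds the prior variance", {
  set.seed(8)
  roster <- tiny_roster()
  params <- random_mgp(2, seed = 8)
  for (rep in 1:5) {
    n <- sample(3:15, 1)
    rec <- patient_record(
      "v", data.frame(feature = sample(c("f1", "f2"), n, replace = TRUE),
                      time_h = sort(runif(n, 0, 12)), value = rnorm(n)),
      statics = encode_tiny_statics(roster), label = 0L, end_time = 12)
    post <- mgp_posterior(params, rec, roster, grid_spec(5))
    prior_rec <- rec
    prior_rec$observations <- prior_rec$observations[0, ]
    prior <- mgp_posterior(params, prior_rec, roster, grid_spec(5))
    expect_true(all(diag(post$cov) <= diag(prior$cov) + 1e-8))
  }
})

test_that("samples are seeded, statics broadcast and padding zeroed", {
  roster <- tiny_roster()
  params <- random_mgp(2, seed = 2)
  rec <- tiny_record(times = c(0.5, 1.5, 2.5), feats = rep("f1", 3),
                     values = c(1, 2, 1), end_time = 3, label = 0L)
  post <- mgp_posterior(params, rec, roster, grid_spec(6))
  st <- encode_tiny_statics(roster)
  b1 <- draw_samples(post, st, S = 3, seed = 11)
  b2 <- draw_samples(post, st, S = 3, seed = 11)
  expect_identical(b1$samples, b2$samples)
  expect_equal(dim(b1$samples), c(6, 2 + roster$Q, 3))
  # padded prefix rows (grid times before admission) are zero
  expect_equal(sum(b1$mask), 2)
  expect_true(all(b1$samples[b1$mask, , ] == 0))
  # statics columns constant over the un-padded rows
  for (s in 1:3) {
    sub <- b1$samples[!b1$mask, 3:(2 + roster$Q), s]
    expect_equal(sub, matrix(st, nrow(sub), roster$Q, byrow = TRUE),
                 ignore_attr = TRUE)
  }
})

test_that("a near-degenerate posterior reproduces its mean", {
  roster <- tiny_roster()
  params <- mgp_params(2, lengthscales = c(2, 8),
                       factors = list(diag(1e-4, 2), diag(1e-4, 2)),
                       noise_sd = c(0.3, 0.3), jitter = 1e-10)
  rec <- tiny_record(times = c(1, 2), feats = c("f1", "f2"), end_time = 3,
                     label = 0L)
  post <- mgp_posterior(params, rec, roster, grid_spec(3))
  b <- draw_samples(post, encode_tiny_statics(roster), S = 4, seed = 1)
  mu_mat <- matrix(post$mean, post$n_eff, 2)
  for (s in 1:4)
    expect_lt(max(abs(b$samples[, 1:2, s] - mu_mat)), 10 * sqrt(1e-6))
})

test_that("the log marginal likelihood matches its closed forms", {
  roster <- tiny_roster()
  # single observation: -0.5 log(2 pi (v + sigma^2))
  params <- mgp_params(2, lengthscales = c(2, 8),
                       factors = list(diag(0.8, 2), diag(0.5, 2)),
                       noise_sd = c(0.3, 0.3))
  rec <- patient_record("s", data.frame(feature = "f1", time_h = 1, value = 0),
                        statics = encode_tiny_statics(roster), label = 0L,
                        end_time = 2)
  v <- 0.8^2 + 0.5^2
  expect_equal(log_marginal_likelihood(params, rec, roster),
               -0.5 * log(2 * pi * (v + 0.09)), tolerance = 1e-10)

  # random instance vs. dense oracle
  set.seed(12)
  params2 <- random_mgp(2, seed = 12)
  n <- 9
  feat <- sample(1:2, n, replace = TRUE)
  tt <- sort(runif(n, 0, 8)); y <- rnorm(n)
  rec2 <- patient_record("r", data.frame(feature = c("f1", "f2")[feat],
                                         time_h = tt, value = y),
                         statics = encode_tiny_statics(roster), label = 0L,
                         end_time = 8)
  A <- joint_observation_covariance(params2, feat, tt)
  oracle <- -0.5 * t(y) %*% solve(A, y) - 0.5 * determinant(A)$modulus -
    n / 2 * log(2 * pi)
  expect_equal(log_marginal_likelihood(params2, rec2, roster),
               as.numeric(oracle), tolerance = 1e-8)
})

test_that("the marginal likelihood prefers the generating lengthscales", {
  cfg <- synthetic_config(n_vitals = 1, n_labs = 1, lengthscales = c(2, 16),
                          record_length_range = c(20, 20))
  cohort <- generate_cohort(cfg, 40, seed = 6)
  roster <- cfg$roster
  true_p <- mgp_params(2, lengthscales = c(2, 16), factors = cfg$factors,
                       noise_sd = as.numeric(cfg$noise_sd))
  wrong_p <- mgp_params(2, lengthscales = c(20, 160), factors = cfg$factors,
                        noise_sd = as.numeric(cfg$noise_sd))
  lml_true <- mean(vapply(cohort, log_marginal_likelihood,
                          numeric(1), params = true_p, roster = roster))
  lml_wrong <- mean(vapply(cohort, log_marginal_likelihood,
                           numeric(1), params = wrong_p, roster = roster))
  expect_gt(lml_true, lml_wrong)
})

test_that("the squared-exponential ablation kernel is accepted end to end", {
  roster <- tiny_roster()
  params <- mgp_params(2, lengthscales = c(2, 8),
                       factors = list(diag(0.8, 2), diag(0.4, 2)),
                       noise_sd = c(0.3, 0.2), time_kernel = "se")
  rec <- tiny_record(times = c(0.5, 1.5, 2.2), feats = c("f1", "f2", "f1"),
                     end_time = 3, label = 0L)
  post <- mgp_posterior(params, rec, roster, grid_spec(4))
  expect_true(all(is.finite(post$mean)))
  b <- draw_samples(post, encode_tiny_statics(roster), S = 2, seed = 3)
  expect_true(all(is.finite(b$samples)))
})
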