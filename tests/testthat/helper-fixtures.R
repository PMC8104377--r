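# shared fixtures: tiny rosters, records and parameter sets built in code

tiny_roster <- function() {
  feature_roster(c("f1", "f2"), c("vital", "lab"), units = "U1")
}

tiny_record <- function(id = "p1", times = c(0.5, 1.5), feats = c("f1", "f1"),
                        values = NULL, roster = tiny_roster(), label = NA,
                        end_time = NULL, onset = NA_real_) {
  values <- values %||% seq_along(times)
  patient_record(
    id,
    data.frame(feature = feats, time_h = times, value = values),
    statics = encode_tiny_statics(roster),
    label = label, onset_time = onset, end_time = end_time
  )
}

encode_tiny_statics <- function(roster = tiny_roster(), age = 50) {
  stats::setNames(c(age, 1, rep(0, roster$Q - 3), 1)[1:roster$Q],
                  roster$static_features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# record with n observations spread uniformly, single feature
bulk_record <- function(id, n, end_time = n, feat = "f1",
                        roster = tiny_roster(), label = 0L, onset = NA_real_) {
  tt <- seq(0, end_time, length.out = n)
  patient_record(id, data.frame(feature = feat, time_h = tt,
                                value = sin(tt)),
                 statics = encode_tiny_statics(roster),
                 label = label, onset_time = onset, end_time = end_time)
}

# small random mgp parameter set with dense lower-triangular factors
random_mgp <- function(M, seed = 1, lengthscales = c(1.5, 8),
                       noise_sd = NULL) {
  noise_sd <- noise_sd %||% stats::runif(M, 0.2, 0.5)
  factors <- with_test_seed(seed, lapply(1:2, function(l) {
    Fm <- matrix(stats::rnorm(M * M, sd = 0.3), M, M)
    Fm[upper.tri(Fm)] <- 0
    diag(Fm) <- stats::runif(M, 0.6, 1.2)
    Fm
  }))
  mgp_params(M, lengthscales = lengthscales, factors = factors,
             noise_sd = noise_sd)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent brute-force Gaussian conditioning oracle: elementwise kernel
# evaluation and dense solves, no shared code with the package internals
oracle_posterior <- function(params, feat, t_obs, y, grid_feat, grid_t) {
  lam <- mgp_lengthscales(params)
  Kk <- mgp_feature_cov(params)
  sig <- mgp_noise_sd(params)
  kf <- function(k1, t1, k2, t2)
    Kk[[1]][k1, k2] * exp(-abs(t1 - t2) / lam[1]) +
    Kk[[2]][k1, k2] * exp(-abs(t1 - t2) / lam[2])
  n <- length(t_obs); G <- length(grid_t)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- kf(feat[i], t_obs[i], feat[j], t_obs[j]) +
      (i == j) * sig[feat[i]]^2
  Kxo <- matrix(0, G, n); Kxx <- matrix(0, G, G)
  for (i in seq_len(G)) {
    for (j in seq_len(n))
      Kxo[i, j] <- kf(grid_feat[i], grid_t[i], feat[j], t_obs[j])
    for (j in seq_len(G))
      Kxx[i, j] <- kf(grid_feat[i], grid_t[i], grid_feat[j], grid_t[j])
  }
  list(mu = as.numeric(Kxo %*% solve(A, y)),
       Sigma = Kxx - Kxo %*% solve(A, t(Kxo)))
}
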