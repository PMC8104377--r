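# training machinery: loss, autodiff against finite differences, balanced
# batching, metrics, random search

test_that("the Monte-Carlo cross-entropy has its closed-form values", {
  expect_equal(loss_mc_cross_entropy(matrix(0.5, 2, 2), 1), log(2),
               tolerance = 1e-12)
  expect_equal(loss_mc_cross_entropy(matrix(c(1e-12, 1), 1), 1), 0,
               tolerance = 1e-6)
  expect_error(loss_mc_cross_entropy(matrix(c(0.9, 0.9), 1), 1), "simplex")
})

test_that("analytic gradients match finite differences on a tiny model", {
  # full joint path: kernel parameters -> conditioning -> Cholesky ->
  # reparameterized samples -> TCN -> attention -> cross-entropy
  set.seed(42)
  M <- 2; N <- 4; S <- 2
  roster <- tiny_roster()
  params <- init_mgp_params(M, seed = 3, lengthscales = c(1.5, 6),
                            noise_sd = c(0.4, 0.3))
  cfg <- tcn_config(kernel_size = 2, n_blocks = 1, n_hidden = 5,
                    dropout = 0, l2 = 0)
  net <- atttcn_init(M + roster$Q, N, cfg, "full", seed = 4)
  inp <- list(ob = list(feat = c(1L, 1L, 2L, 2L, 1L),
                        t = c(-3.2, -1.1, -2.5, -0.4, 0),
                        y = c(0.5, -0.2, 0.3, 0.8, -0.1)),
              statics = encode_tiny_statics(roster), label = 1L,
              end_time = 3.8)
  eta <- matrix(rnorm(M * N * S), M * N, S)
  loss_of <- function(mgp, net)
    mgpattn:::record_forward(mgp, net, inp, N, S, eta = eta,
                             grad = FALSE)$loss
  rf <- mgpattn:::record_forward(params, net, inp, N, S, eta = eta,
                                 grad = TRUE)
  h <- 1e-5
  rel_err <- function(fd, ana) max(abs(fd - ana) / pmax(abs(fd), 1e-4))

  # MGP lengthscales, noise, covariance factors
  for (field in c("theta_lambda", "theta_sigma")) {
    v <- params[[field]]
    fd <- vapply(seq_along(v), function(i) {
      pp <- params; pp[[field]][i] <- v[i] + h
      pm <- params; pm[[field]][i] <- v[i] - h
      (loss_of(pp, net) - loss_of(pm, net)) / (2 * h)
    }, numeric(1))
    expect_lt(rel_err(fd, rf$mgp_grads[[field]]), 1e-4)
  }
  for (l in 1:2) {
    idx <- which(lower.tri(diag(M), diag = TRUE))
    fd <- vapply(idx, function(i) {
      pp <- params; pp$factors[[l]][i] <- pp$factors[[l]][i] + h
      pm <- params; pm$factors[[l]][i] <- pm$factors[[l]][i] - h
      (loss_of(pp, net) - loss_of(pm, net)) / (2 * h)
    }, numeric(1))
    expect_lt(rel_err(fd, rf$mgp_grads$factors[[l]][idx]), 1e-4)
  }

  # classifier weights (spot-check a deterministic subset for speed)
  fl <- mgpattn:::flatten_params(mgpattn:::extract_net_weights(net))
  gfl <- mgpattn:::flatten_params(rf$net_grads)
  pick <- seq(1, length(fl$vec), by = 7)
  fd <- vapply(pick, function(i) {
    vp <- fl$vec; vp[i] <- vp[i] + h
    vm <- fl$vec; vm[i] <- vm[i] - h
    (loss_of(params, mgpattn:::inject_net_weights(
       net, mgpattn:::unflatten_params(vp, fl$skeleton))) -
     loss_of(params, mgpattn:::inject_net_weights(
       net, mgpattn:::unflatten_params(vm, fl$skeleton)))) / (2 * h)
  }, numeric(1))
  expect_lt(rel_err(fd, gfl$vec[pick]), 1e-4)
})

test_that("balanced batches oversample cases and are seeded", {
  labels <- c(rep(1L, 10), rep(0L, 100))
  b <- balanced_batches(labels, batch_size = 8, seed = 3)
  stream <- unlist(b)
  expect_equal(sum(labels[stream] == 1), 100)
  expect_equal(sum(labels[stream] == 0), 100)
  full <- b[lengths(b) == 8]
  for (bt in full[1:5])
    expect_equal(sum(labels[bt] == 1), 4)
  expect_identical(b, balanced_batches(labels, batch_size = 8, seed = 3))
  expect_error(balanced_batches(rep(0L, 5), 4), "no cases")
})

test_that("AUROC and AUPR have the right degenerate values and oracle", {
  expect_equal(auroc(rep(0.7, 10), c(rep(1, 4), rep(0, 6))), 0.5)
  y <- c(rep(1, 5), rep(0, 15))
  expect_equal(auroc(y, y), 1)
  expect_equal(aupr(y, y), 1)
  expect_true(is.na(auroc(1:5, rep(1, 5))))
  expect_true(is.na(aupr(1:5, rep(0, 5))))

  # brute-force all-pairs concordance oracle, with tie handling
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    pos <- which(labels == 1); neg <- which(labels == 0)
    conc <- 0
    for (i in pos) for (j in neg)
      conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    expect_lt(abs(auroc(scores, labels) -
                    conc / (length(pos) * length(neg))), 1e-10)
  }
})

test_that("training on a small separable cohort reduces the loss", {
  cfg <- synthetic_config(n_vitals = 1, n_labs = 1, lengthscales = c(2, 16),
                          record_length_range = c(8, 12),
                          signal_features = c("vital_1", "lab_1"),
                          label_weights = c(6, 6))
  cohort <- generate_cohort(cfg, 40, seed = 15)
  roster <- cfg$roster
  split <- rep(c("train", "val"), c(32, 8))
  norm <- normalize_cohort(cohort, split, roster)
  dataset <- list(records = norm$records, split = split, roster = roster)
  fit <- train_model(dataset, variant = "full",
                     tcn = tcn_config(n_hidden = 8, dropout = 0, l2 = 0),
                     N = 13, S = 2, epochs = 4, batch_size = 8, lr = 5e-3,
                     patience = 10, seed = 5)
  h <- fit$history
  expect_lt(h$train_loss[4], h$train_loss[1])
  # same seed end to end reproduces the run exactly
  fit2 <- train_model(dataset, variant = "full",
                      tcn = tcn_config(n_hidden = 8, dropout = 0, l2 = 0),
                      N = 13, S = 2, epochs = 4, batch_size = 8, lr = 5e-3,
                      patience = 10, seed = 5)
  expect_identical(fit$history, fit2$history)
  # gradients reach the GP parameters: lengthscales moved during training
  expect_false(isTRUE(all.equal(mgp_lengthscales(fit$mgp), c(1, 24))))
})

test_that("random search draws inside the published bounds and is seeded", {
  dummy_fit <- function(dataset, tcn, S, seed, epochs, batch_size, ...) {
    stopifnot(tcn$kernel_size >= 2, tcn$kernel_size <= 6,
              tcn$n_blocks >= 2, tcn$n_blocks <= 12,
              tcn$n_hidden >= 10, tcn$n_hidden <= 55,
              tcn$dropout >= 0, tcn$dropout <= 0.99,
              tcn$l2 >= 0, tcn$l2 <= 250, S >= 4, S <= 20)
    list(history = data.frame(val_aupr = tcn$dropout))
  }
  rs <- random_search(dataset = NULL, n_trials = 12, seed = 9,
                      train_fun = dummy_fit)
  expect_equal(nrow(rs$trials), 12)
  expect_true(all(rs$trials$S %in% 4:20))
  expect_true(all(rs$trials$kernel_size %in% 2:6))
  expect_true(all(rs$trials$n_blocks %in% 2:12))
  expect_true(all(rs$trials$n_hidden %in% 10:55))
  expect_equal(rs$best$val_aupr, max(rs$trials$val_aupr))
  rs2 <- random_search(dataset = NULL, n_trials = 12, seed = 9,
                       train_fun = dummy_fit)
  expect_identical(rs$trials, rs2$trials)
  rs1 <- random_search(dataset = NULL, n_trials = 1, seed = 2,
                       train_fun = dummy_fit)
  expect_equal(rs1$best$trial, 1)
})

test_that("identical scores collapse AUPR to the prevalence", {
  labels <- c(rep(1L, 3), rep(0L, 7))
  expect_equal(aupr(rep(0.4, 10), labels), 0.3)
  # a perfect ranking with one tie-group at the top stays at 1
  expect_equal(aupr(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), labels), 1)
})
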