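#' Multitask Gaussian process parameters
#'
#' The prior over the latent clinical time series: two smoothness clusters,
#' each combining a free-form feature covariance `K_l = F_l %*% t(F_l)`
#' (parameterized by its lower-triangular factor, so it stays positive
#' semidefinite under unconstrained gradient descent) with a time kernel of
#' lengthscale `lambda_l`; plus per-feature observation noise. Lengthscales
#' and noise standard deviations are parameterized through softplus.
#'
#' @param M number of dynamic features.
#' @param lengthscales positive lengthscales in hours (length 2).
#' @param factors list of two `M x M` lower-triangular feature-covariance
#'   factors; defaults to scaled identity factors.
#' @param noise_sd per-feature observation noise standard deviations.
#' @param jitter diagonal jitter used when factorizing the posterior
#'   covariance for sampling (escalated x10 up to twice on failure).
#' @param time_kernel `"ou"` (default) or `"se"` — the squared-exponential
#'   hook exists for kernel-ablation experiments.
#' @return an object of class `mgp_params`.
#' @export
mgp_params <- function(M, lengthscales = c(2, 64), factors = NULL,
                       noise_sd = rep(0.3, M), jitter = 1e-6,
                       time_kernel = c("ou", "se")) {
  time_kernel <- match.arg(time_kernel)
  stopifnot(all(lengthscales > 0), length(lengthscales) == 2,
            length(noise_sd) == M, all(noise_sd >= 0), jitter > 0)
  if (is.null(factors))
    factors <- list(diag(0.7, M), diag(0.7, M))
  for (Fm in factors) {
    stopifnot(is.matrix(Fm), nrow(Fm) == M, ncol(Fm) == M)
    if (any(Fm[upper.tri(Fm)] != 0))
      stop("feature-covariance factors must be lower triangular")
  }
  structure(list(
    M = M,
    theta_lambda = inv_softplus(lengthscales),
    factors = factors,
    theta_sigma = inv_softplus(pmax(noise_sd, 1e-4)),
    jitter = jitter,
    time_kernel = time_kernel
  ), class = "mgp_params")
}

#' @export
print.mgp_params <- function(x, ...) {
  cat(sprintf("<mgp_params> M = %d, lengthscales = (%.3g, %.3g) h, kernel = %s\n",
              x$M, mgp_lengthscales(x)[1], mgp_lengthscales(x)[2],
              x$time_kernel))
  invisible(x)
}

#' Accessors for constrained MGP parameters
#' @param params an [mgp_params()].
#' @return `mgp_lengthscales`: the positive lengthscales;
#'   `mgp_noise_sd`: the per-feature noise standard deviations;
#'   `mgp_feature_cov`: list of the two feature covariance matrices.
#' @export
mgp_lengthscales <- function(params) softplus(params$theta_lambda)

#' @rdname mgp_lengthscales
#' @export
mgp_noise_sd <- function(params) softplus(params$theta_sigma)

#' @rdname mgp_lengthscales
#' @export
mgp_feature_cov <- function(params) lapply(params$factors, tcrossprod)

#' Random initialization for joint training
#'
#' @param M number of features.
#' @param seed integer seed.
#' @param lengthscales initial lengthscales (defaults to 1 h and 24 h, one
#'   fast and one slow cluster).
#' @param noise_sd initial noise level.
#' @param ... passed on to [mgp_params()].
#' @return an [mgp_params()].
#' @export
init_mgp_params <- function(M, seed = 1, lengthscales = c(1, 24),
                            noise_sd = rep(0.3, M), ...) {
  factors <- with_seed(seed, lapply(1:2, function(l) {
    Fm <- matrix(stats::rnorm(M * M, sd = 0.05), M, M)
    Fm[upper.tri(Fm)] <- 0
    diag(Fm) <- 0.7
    Fm
  }))
  mgp_params(M, lengthscales = lengthscales, factors = factors,
             noise_sd = noise_sd, ...)
}

#' Hourly prediction grid
#'
#' The model window: `N` hourly grid points ending at the prediction time,
#' expressed relative to it, i.e. `-(N-1), ..., -1, 0`.
#'
#' @param N window length (default 25).
#' @return object of class `grid_spec` with `N` and `times`.
#' @export
grid_spec <- function(N = 25) {
  stopifnot(N >= 1)
  structure(list(N = as.integer(N), times = as.numeric(-(N - 1):0)),
            class = "grid_spec")
}

# extract model-facing observations from a record: integer feature index,
# times re-expressed relative to the prediction time (end_time -> 0),
# duplicate (feature, time) pairs averaged
record_obs <- function(record, roster) {
  obs <- record$observations
  feat <- match(obs$feature, roster$dynamic_features)
  if (anyNA(feat))
    stop("record ", record$patient_id, " has features outside the roster")
  t_rel <- obs$time_h - record$end_time
  key <- paste(feat, format(t_rel, digits = 15))
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(obs$value, by = list(key = key), FUN = mean)
    first <- !duplicated(key)
    ord <- match(key[first], agg$key)
    list(feat = feat[first], t = t_rel[first], y = agg$x[ord])
  } else {
    list(feat = feat, t = t_rel, y = obs$value)
  }
}

#' Joint observation covariance
#'
#' The covariance of the observed values under the multitask prior: for
#' observation pairs `(k, t_i)` and `(k', t_j)` the entry is
#' `sum_l K_l[k, k'] * k_time(|t_i - t_j|; lambda_l)`, plus the feature's
#' noise variance on the diagonal. This is the observed-pair restriction of
#' the full Kronecker form `sum_l K_l ox K_l^tt + D ox I` over the union time
#' set, the standard multitask-GP-with-missingness construction.
#'
#' @param params an [mgp_params()].
#' @param features integer feature indices (one per observation).
#' @param times observation times (hours).
#' @return symmetric covariance matrix of dimension `length(times)`.
#' @export
joint_observation_covariance <- function(params, features, times) {
  stopifnot(length(features) == length(times), length(times) >= 1)
  if (anyDuplicated(paste(features, format(times, digits = 15))))
    stop("duplicate (feature, time) pairs must be pre-averaged")
  lam <- mgp_lengthscales(params)
  sig <- mgp_noise_sd(params)
  Kk <- mgp_feature_cov(params)
  D <- abs(outer(times, times, "-"))
  A <- matrix(0, length(times), length(times))
  for (l in 1:2)
    A <- A + Kk[[l]][features, features] *
      time_kernel_eval(D, lam[l], params$time_kernel)
  diag(A) <- diag(A) + sig[features]^2
  (A + t(A)) / 2
}

# core conditioning: everything the forward and backward passes need.
# feat/t_obs/y describe observations with times relative to prediction time;
# t_grid is the (effective) grid, also relative.
mgp_condition <- function(params, feat, t_obs, y, t_grid) {
  M <- params$M
  lam <- softplus(params$theta_lambda)
  sig <- softplus(params$theta_sigma)
  Kk <- lapply(params$factors, tcrossprod)
  n <- length(t_obs)
  ng <- length(t_grid)
  G <- M * ng
  gridfeat <- rep(seq_len(M), each = ng)
  gridtime <- rep(seq_len(ng), M)
  Dgg <- abs(outer(t_grid, t_grid, "-"))
  Tgg <- lapply(1:2, function(l)
    time_kernel_eval(Dgg, lam[l], params$time_kernel))
  Kxx <- kronecker(Kk[[1]], Tgg[[1]]) + kronecker(Kk[[2]], Tgg[[2]])
  cache <- list(params = params, feat = feat, t_obs = t_obs, y = y,
                t_grid = t_grid, lam = lam, sig = sig, Kk = Kk,
                gridfeat = gridfeat, gridtime = gridtime,
                Dgg = Dgg, Tgg = Tgg, n = n, ng = ng, G = G, M = M)
  if (n == 0) {
    mu <- numeric(G)
    Sigma <- (Kxx + t(Kxx)) / 2
    return(c(cache, list(mu = mu, Sigma = Sigma)))
  }
  Doo <- abs(outer(t_obs, t_obs, "-"))
  Dgo <- abs(outer(t_grid, t_obs, "-"))
  Too <- lapply(1:2, function(l)
    time_kernel_eval(Doo, lam[l], params$time_kernel))
  Tgo <- lapply(1:2, function(l)
    time_kernel_eval(Dgo, lam[l], params$time_kernel))
  A <- Kk[[1]][feat, feat] * Too[[1]] + Kk[[2]][feat, feat] * Too[[2]]
  diag(A) <- diag(A) + sig[feat]^2
  A <- (A + t(A)) / 2
  L_A <- chol_obs(A, params$jitter)
  U_A <- t(L_A)
  b <- backsolve(U_A, forwardsolve(L_A, y))
  Kxo <- Kk[[1]][gridfeat, feat] * Tgo[[1]][gridtime, , drop = FALSE] +
         Kk[[2]][gridfeat, feat] * Tgo[[2]][gridtime, , drop = FALSE]
  V <- backsolve(U_A, forwardsolve(L_A, t(Kxo)))   # n x G
  mu <- as.numeric(Kxo %*% b)
  Sigma <- Kxx - Kxo %*% V
  Sigma <- (Sigma + t(Sigma)) / 2
  c(cache, list(mu = mu, Sigma = Sigma, A = A, L_A = L_A, U_A = U_A,
                b = b, Kxo = Kxo, V = V,
                Doo = Doo, Dgo = Dgo, Too = Too, Tgo = Tgo))
}

# Cholesky of the (noise-regularized) observation covariance: attempted
# without jitter first, then with escalation for near-noise-free cases
chol_obs <- function(A, eps) {
  U <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(U)) return(t(U))
  chol_jitter(A, eps, "observation covariance")
}

#' Posterior of the latent process on the hourly grid
#'
#' Standard Gaussian conditioning of the multitask prior on a record's
#' observations, evaluated at the hourly grid ending at the prediction time
#' (the record's `end_time`). Grid points falling before ICU admission are
#' padding and are excluded from the posterior (the sample batch zero-pads
#' them back). With zero observations the prior is returned.
#'
#' @param params an [mgp_params()].
#' @param record a [patient_record()].
#' @param roster the [feature_roster()] fixing feature order.
#' @param grid a [grid_spec()] (default `N = 25`).
#' @return object of class `grid_posterior` with `mean` (length
#'   `n_eff * M`, feature-major), `cov`, `grid_times` (relative to
#'   prediction), `n_eff`, and the conditioning cache used by the training
#'   backward pass.
#' @export
mgp_posterior <- function(params, record, roster, grid = grid_spec()) {
  ob <- record_obs(record, roster)
  t_grid <- grid$times[grid$times >= -record$end_time]
  if (!length(t_grid)) t_grid <- 0
  cond <- tryCatch(
    mgp_condition(params, ob$feat, ob$t, ob$y, t_grid),
    error = function(e)
      stop("posterior failed for record ", record$patient_id, ": ",
           conditionMessage(e))
  )
  structure(list(mean = cond$mu, cov = cond$Sigma,
                 grid_times = t_grid, n_eff = length(t_grid),
                 N = grid$N, M = params$M, cond = cond),
            class = "grid_posterior")
}

#' Monte Carlo samples from a grid posterior
#'
#' Draws `S` reparameterized samples `mu + L eta` with `L` the Cholesky factor
#' of the posterior covariance plus jitter and `eta` standard normal — an
#' affine function of `(mu, L)` given `eta`, which is what lets classification
#' gradients flow back into the Gaussian-process parameters. Each sample is
#' reshaped to an `N x (M+Q)` matrix: `M` dynamic columns, `Q` static columns
#' broadcast over the non-padded rows; padded rows (grid points before
#' admission) are zero.
#'
#' @param posterior a [mgp_posterior()].
#' @param statics encoded static vector (length `Q`).
#' @param S number of samples (>= 1).
#' @param seed integer seed; the same seed gives an identical batch.
#' @param eta optional `(n_eff * M) x S` matrix of standard-normal draws,
#'   overriding the seeded draw (used by deterministic gradient checks).
#' @return object of class `sample_batch`: `samples` (array
#'   `N x (M+Q) x S`), `mask` (logical length `N`, `TRUE` on padded rows),
#'   plus the draw internals (`eta`, `L`).
#' @export
draw_samples <- function(posterior, statics, S, seed = 1, eta = NULL) {
  stopifnot(S >= 1)
  G <- length(posterior$mean)
  L <- chol_jitter(posterior$cov, posterior$cond$params$jitter,
                   "posterior covariance")
  if (is.null(eta))
    eta <- with_seed(seed, matrix(stats::rnorm(G * S), G, S))
  samp <- posterior$mean + L %*% eta
  N <- posterior$N
  n_eff <- posterior$n_eff
  M <- posterior$M
  Q <- length(statics)
  arr <- array(0, dim = c(N, M + Q, S))
  rows <- (N - n_eff + 1):N
  for (s in seq_len(S)) {
    arr[rows, 1:M, s] <- matrix(samp[, s], n_eff, M)
    arr[rows, M + seq_len(Q), s] <- matrix(statics, n_eff, Q, byrow = TRUE)
  }
  mask <- rep(TRUE, N)
  mask[rows] <- FALSE
  structure(list(samples = arr, mask = mask, eta = eta, L = L,
                 n_eff = n_eff, M = M, Q = Q, statics = statics),
            class = "sample_batch")
}

#' Gaussian log marginal likelihood of a record
#'
#' Log density of the observed values under the multitask prior plus noise —
#' the quantity maximized when fitting the Gaussian-process hyperparameters
#' on their own (the joint model instead trains them through the classifier).
#'
#' @param params an [mgp_params()].
#' @param record a [patient_record()] with at least one observation.
#' @param roster the [feature_roster()].
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(params, record, roster) {
  ob <- record_obs(record, roster)
  if (!length(ob$y)) stop("log marginal likelihood requires >= 1 observation")
  lml_core(params, ob$feat, ob$t, ob$y)$value
}

lml_core <- function(params, feat, t_obs, y, grad = FALSE) {
  cond <- mgp_condition(params, feat, t_obs, y, t_grid = 0)
  n <- length(y)
  quad <- sum(y * cond$b)
  value <- -0.5 * quad - sum(log(diag(cond$L_A))) - n / 2 * log(2 * pi)
  out <- list(value = value)
  if (grad) {
    Ainv <- chol2inv(cond$U_A)
    dA <- 0.5 * (tcrossprod(cond$b) - Ainv)
    out$grads <- mgp_kernel_param_grads(cond, dA = dA, dKxo = NULL, dKxx = NULL)
  }
  out
}

#' Fit MGP lengthscales by maximum marginal likelihood
#'
#' Maximizes the summed log marginal likelihood over a set of records with
#' respect to the two lengthscales (all other parameters held fixed), using
#' L-BFGS-B with the analytic gradient. Used for lengthscale-recovery
#' diagnostics; the end-to-end model instead learns all MGP parameters jointly
#' with the classifier.
#'
#' @param params starting [mgp_params()].
#' @param records list of [patient_record()]s.
#' @param roster the [feature_roster()].
#' @param maxit L-BFGS-B iteration budget.
#' @return list with `params` (updated), `lengthscales`, and the `optim`
#'   convergence info.
#' @export
fit_mgp_lengthscales <- function(params, records, roster, maxit = 60) {
  fit_mgp_objective(params, records, roster, maxit, lengthscales_only = TRUE)
}

#' Fit all MGP hyperparameters by maximum marginal likelihood
#'
#' Maximizes the summed log marginal likelihood with respect to the
#' lengthscales, the feature-covariance factors and the noise levels, with
#' analytic gradients. Useful as an initialization for joint end-to-end
#' training: the classifier then starts from a well-calibrated imputation
#' model and gradient descent continues to adapt all parameters.
#'
#' @inheritParams fit_mgp_lengthscales
#' @param n_records optional cap on the number of records used (subsampled
#'   deterministically from the head of the list).
#' @return list with `params`, `lengthscales`, `convergence`, `value`.
#' @export
fit_mgp_mle <- function(params, records, roster, maxit = 30,
                        n_records = NULL) {
  if (!is.null(n_records) && length(records) > n_records)
    records <- records[seq_len(n_records)]
  fit_mgp_objective(params, records, roster, maxit, lengthscales_only = FALSE)
}

fit_mgp_objective <- function(params, records, roster, maxit,
                              lengthscales_only) {
  obs <- lapply(records, record_obs, roster = roster)
  obs <- Filter(function(o) length(o$y) > 0, obs)
  if (lengthscales_only) {
    pack <- function(p) p$theta_lambda
    unpack <- function(v) { p <- params; p$theta_lambda <- v; p }
    pick <- function(g) g$theta_lambda
  } else {
    skel <- extract_mgp_weights(params)
    fl0 <- flatten_params(skel)
    pack <- function(p) flatten_params(extract_mgp_weights(p))$vec
    unpack <- function(v)
      inject_mgp_weights(params, unflatten_params(v, fl0$skeleton))
    pick <- function(g)
      flatten_params(g[c("theta_lambda", "factors", "theta_sigma")])$vec
  }
  objective <- function(v) {
    p <- unpack(v)
    -sum(vapply(obs, function(o)
      lml_core(p, o$feat, o$t, o$y)$value, numeric(1)))
  }
  gradient <- function(v) {
    p <- unpack(v)
    g <- NULL
    for (o in obs)
      g <- add_mgp_grads(g, lml_core(p, o$feat, o$t, o$y,
                                     grad = TRUE)$grads)
    -pick(g)
  }
  fit <- stats::optim(pack(params), objective, gradient,
                      method = "L-BFGS-B", control = list(maxit = maxit))
  params <- unpack(fit$par)
  list(params = params, lengthscales = softplus(params$theta_lambda),
       convergence = fit$convergence, value = -fit$value)
}
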