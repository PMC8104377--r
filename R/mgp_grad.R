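# Hand-written reverse-mode gradients through the MGP layer.
#
# The forward map is: kernel matrices (from lengthscales, feature-covariance
# factors, noise) -> Gaussian conditioning (mu, Sigma) -> Cholesky factor L of
# Sigma + eps I -> reparameterized samples mu + L eta. The backward pass takes
# gradients w.r.t. (mu, L) and returns gradients w.r.t. the unconstrained
# parameters (theta_lambda, factors, theta_sigma). All formulas are standard
# matrix-calculus results; chol_backward is in utils.R.

# gradients w.r.t. kernel parameters given gradients w.r.t. the assembled
# matrices A (obs covariance incl. noise), Kxo (grid x obs cross covariance)
# and Kxx (grid prior covariance). Any of dA/dKxo/dKxx may be NULL.
mgp_kernel_param_grads <- function(cond, dA = NULL, dKxo = NULL, dKxx = NULL) {
  p <- cond$params
  M <- cond$M
  lam <- cond$lam
  sig <- cond$sig
  type <- p$time_kernel
  n <- cond$n
  dtheta_lambda <- numeric(2)
  dfactors <- list(matrix(0, M, M), matrix(0, M, M))
  dtheta_sigma <- numeric(M)

  Zo <- NULL
  if (!is.null(dA) || !is.null(dKxo)) {
    Zo <- matrix(0, n, M)
    Zo[cbind(seq_len(n), cond$feat)] <- 1
  }
  Zg <- NULL
  if (!is.null(dKxo) || !is.null(dKxx)) {
    Zg <- matrix(0, cond$G, M)
    Zg[cbind(seq_len(cond$G), cond$gridfeat)] <- 1
  }

  for (l in 1:2) {
    Gk <- matrix(0, M, M)   # gradient w.r.t. feature covariance K_l
    dlam <- 0
    if (!is.null(dA)) {
      Tm <- cond$Too[[l]]
      W <- dA * Tm
      Gk <- Gk + crossprod(Zo, W %*% Zo)
      fac <- time_kernel_lambda_factor(cond$Doo, lam[l], type)
      dlam <- dlam + sum(dA * (cond$Kk[[l]][cond$feat, cond$feat] * Tm * fac))
    }
    if (!is.null(dKxo)) {
      Tm <- cond$Tgo[[l]][cond$gridtime, , drop = FALSE]
      W <- dKxo * Tm
      Gk <- Gk + crossprod(Zg, W %*% Zo)
      fac <- time_kernel_lambda_factor(cond$Dgo, lam[l], type)[cond$gridtime, ,
                                                               drop = FALSE]
      dlam <- dlam +
        sum(dKxo * (cond$Kk[[l]][cond$gridfeat, cond$feat] * Tm * fac))
    }
    if (!is.null(dKxx)) {
      Tm <- cond$Tgg[[l]][cond$gridtime, cond$gridtime]
      W <- dKxx * Tm
      Gk <- Gk + crossprod(Zg, W %*% Zg)
      fac <- time_kernel_lambda_factor(cond$Dgg, lam[l],
                                       type)[cond$gridtime, cond$gridtime]
      dlam <- dlam +
        sum(dKxx * (cond$Kk[[l]][cond$gridfeat, cond$gridfeat] * Tm * fac))
    }
    dF <- (Gk + t(Gk)) %*% p$factors[[l]]
    dF[upper.tri(dF)] <- 0
    dfactors[[l]] <- dF
    dtheta_lambda[l] <- dlam * d_softplus(p$theta_lambda[l])
  }
  if (!is.null(dA)) {
    dvar <- as.numeric(rowsum(diag(dA), cond$feat,
                              reorder = TRUE))
    idx <- sort(unique(cond$feat))
    dsig2 <- numeric(M)
    dsig2[idx] <- dvar
    dtheta_sigma <- dsig2 * 2 * sig * d_softplus(p$theta_sigma)
  }
  list(theta_lambda = dtheta_lambda, factors = dfactors,
       theta_sigma = dtheta_sigma)
}

# backward through conditioning + Cholesky + reparameterized sampling.
# cond: the conditioning cache from mgp_condition; L: Cholesky factor used for
# sampling; dmu: gradient w.r.t. the posterior mean (length G); dL: gradient
# w.r.t. L (G x G, lower). Returns unconstrained parameter gradients.
mgp_sample_backward <- function(cond, L, dmu, dL) {
  dSigma <- chol_backward(L, dL)
  if (cond$n == 0) {
    return(mgp_kernel_param_grads(cond, dA = NULL, dKxo = NULL, dKxx = dSigma))
  }
  b <- cond$b
  V <- cond$V                     # n x G, equals A^{-1} t(Kxo)
  dmu <- matrix(dmu, ncol = 1)
  dKxx <- dSigma
  dKxo <- dmu %*% t(b) - 2 * (dSigma %*% t(V))
  dA <- V %*% dSigma %*% t(V) - (V %*% dmu) %*% t(b)
  dA <- (dA + t(dA)) / 2
  mgp_kernel_param_grads(cond, dA = dA, dKxo = dKxo, dKxx = dKxx)
}

# elementwise addition of two gradient structures (same shapes)
add_mgp_grads <- function(a, b) {
  if (is.null(a)) return(b)
  a$theta_lambda <- a$theta_lambda + b$theta_lambda
  a$factors[[1]] <- a$factors[[1]] + b$factors[[1]]
  a$factors[[2]] <- a$factors[[2]] + b$factors[[2]]
  a$theta_sigma <- a$theta_sigma + b$theta_sigma
  a
}

zero_mgp_grads <- function(M) {
  list(theta_lambda = numeric(2),
       factors = list(matrix(0, M, M), matrix(0, M, M)),
       theta_sigma = numeric(M))
}

scale_mgp_grads <- function(g, s) {
  g$theta_lambda <- g$theta_lambda * s
  g$factors <- lapply(g$factors, function(x) x * s)
  g$theta_sigma <- g$theta_sigma * s
  g
}
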