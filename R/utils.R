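# numeric helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable softplus and its inverse
#'
#' Positivity transform used for Gaussian-process lengthscales and noise
#' standard deviations, so gradient descent can run unconstrained.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' @rdname softplus
#' @keywords internal
inv_softplus <- function(x) {
  stopifnot(all(x > 0))
  out <- x
  small <- x < 30
  out[small] <- log(expm1(x[small]))
  out
}

# derivative of softplus
d_softplus <- function(x) stats::plogis(x)

#' Cholesky factorization with jitter escalation
#'
#' Attempts `chol(S + eps * I)`, escalating the jitter by factors of 10 up to
#' twice before failing. Returns the lower-triangular factor.
#'
#' @param S symmetric matrix.
#' @param eps initial jitter on the diagonal.
#' @param context character used in the error message.
#' @return lower-triangular matrix `L` with `L %*% t(L) = S + jitter * I`.
#' @keywords internal
chol_jitter <- function(S, eps = 1e-6, context = "matrix") {
  n <- nrow(S)
  for (e in c(eps, 10 * eps, 100 * eps)) {
    U <- tryCatch(chol(S + diag(e, n)), error = function(err) NULL)
    if (!is.null(U)) return(t(U))
  }
  stop("Cholesky factorization failed after jitter escalation for ", context)
}

# gradient of a scalar through L = chol(Sigma) (lower), given Lbar = dloss/dL.
# Returns the symmetric dloss/dSigma. Standard blocked-free formulation:
# Sigma_bar = L^{-T} Phi(L^T Lbar) L^{-1}, Phi = lower triangle w/ halved diagonal.
chol_backward <- function(L, Lbar) {
  P <- crossprod(L, Lbar)            # t(L) %*% Lbar
  P[upper.tri(P)] <- 0
  diag(P) <- diag(P) / 2
  U <- t(L)
  X <- backsolve(U, t(backsolve(U, t(P))))  # L^{-T} P L^{-1}
  (X + t(X)) / 2
}

# flatten a nested list of numerics into one vector + skeleton for relist()
flatten_params <- function(params) {
  vec <- unlist(params, use.names = FALSE)
  list(vec = vec, skeleton = params)
}

# inverse of flatten_params; preserves dim/dimnames (relist drops them for
# arrays beyond matrices)
unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  walk(skeleton)
}

# Adam optimizer state and update (operates on flat numeric vectors)
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# seeded RNG scope: evaluates expr with a temporary seed, restoring RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a stream of child seeds from one integer seed (keeps values < 2^31)
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 11 * as.numeric(k)) %% 2147483647
}
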