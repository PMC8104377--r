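#' TCN / classifier configuration
#'
#' Hyperparameters of the causal-convolution embedding stacks and their
#' regularization. The search ranges used by [random_search()] are: kernel
#' size 2--6, residual blocks 2--12, hidden channels 10--55, dropout
#' `[0, 0.99)`, L2 coefficient `[0, 250]`.
#'
#' @param kernel_size causal convolution kernel width (>= 1).
#' @param n_blocks number of residual blocks (each two causal conv layers).
#' @param n_hidden hidden channels.
#' @param dropout dropout rate in `[0, 1)` (training only).
#' @param l2 L2 regularization coefficient on convolution weights; the
#'   penalty enters the loss as `l2 * mean(W^2)` over all conv weights.
#' @return object of class `tcn_config`.
#' @export
tcn_config <- function(kernel_size = 3, n_blocks = 2, n_hidden = 16,
                       dropout = 0.1, l2 = 1e-3) {
  if (kernel_size < 1) stop("kernel size must be >= 1")
  if (n_blocks < 1) stop("need at least one block")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(kernel_size = as.integer(kernel_size),
                 n_blocks = as.integer(n_blocks),
                 n_hidden = as.integer(n_hidden),
                 dropout = dropout, l2 = l2),
            class = "tcn_config")
}

# ---- causal convolution primitives ------------------------------------------

shift_down <- function(X, d) {
  if (d == 0) return(X)
  n <- nrow(X)
  rbind(matrix(0, d, ncol(X)), X[seq_len(n - d), , drop = FALSE])
}

shift_up <- function(X, d) {
  if (d == 0) return(X)
  n <- nrow(X)
  rbind(X[(d + 1):n, , drop = FALSE], matrix(0, d, ncol(X)))
}

# out[t, ] = b + sum_d X[t - d, ] %*% W[d + 1, , ]; left zero padding keeps
# length N and makes the map strictly causal
conv_causal_forward <- function(X, W, b) {
  k <- dim(W)[1]
  out <- matrix(b, nrow(X), length(b), byrow = TRUE)
  for (d in seq_len(k)) {
    Wd <- matrix(W[d, , ], dim(W)[2], dim(W)[3])
    out <- out + shift_down(X, d - 1) %*% Wd
  }
  out
}

conv_causal_backward <- function(dOut, X, W) {
  k <- dim(W)[1]
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (d in seq_len(k)) {
    Wd <- matrix(W[d, , ], dim(W)[2], dim(W)[3])
    dW[d, , ] <- crossprod(shift_down(X, d - 1), dOut)
    dX <- dX + shift_up(dOut, d - 1) %*% t(Wd)
  }
  list(dW = dW, db = colSums(dOut), dX = dX)
}

# ---- network construction ---------------------------------------------------

new_conv_layer <- function(k, c_in, c_out, relu, dropout, scale = NULL) {
  scale <- scale %||% sqrt(2 / (k * c_in))
  list(W = array(stats::rnorm(k * c_in * c_out, sd = scale),
                 dim = c(k, c_in, c_out)),
       b = numeric(c_out), relu = relu, dropout = dropout)
}

# a TCN stack: n_blocks x (two causal convs with ReLU + dropout), then a
# width-1 linear projection back to n_input channels. No identity skip: with
# at most a dozen layers the residual shortcut is unnecessary and omitting it
# keeps the embedding directly attributable to its inputs.
new_tcn_stack <- function(n_input, cfg) {
  layers <- list()
  c_in <- n_input
  for (b in seq_len(cfg$n_blocks)) {
    layers[[length(layers) + 1]] <- new_conv_layer(cfg$kernel_size, c_in,
                                                   cfg$n_hidden, TRUE, TRUE)
    layers[[length(layers) + 1]] <- new_conv_layer(cfg$kernel_size,
                                                   cfg$n_hidden, cfg$n_hidden,
                                                   TRUE, TRUE)
    c_in <- cfg$n_hidden
  }
  layers[[length(layers) + 1]] <- new_conv_layer(1, c_in, n_input,
                                                 FALSE, FALSE, scale = 0.3)
  layers
}

#' Initialize an AttTCN classifier
#'
#' @param n_input number of input columns `M + Q`.
#' @param N window length.
#' @param config a [tcn_config()].
#' @param variant `"full"`, `"no_alpha"` (attention over time fixed uniform),
#'   `"no_beta"` (feature attention fixed to one), `"mgp_tcn"` (plain TCN with
#'   a linear-softmax readout of the last step), or `"mgp_logreg"` (linear
#'   logits on the flattened window).
#' @param seed integer seed for weight initialization.
#' @return object of class `atttcn_net` holding all classifier parameters.
#' @export
atttcn_init <- function(n_input, N, config = tcn_config(),
                        variant = c("full", "no_alpha", "no_beta",
                                    "mgp_tcn", "mgp_logreg"),
                        seed = 1) {
  variant <- match.arg(variant)
  net <- with_seed(seed, {
    if (variant == "mgp_logreg") {
      list(readout = list(W = array(stats::rnorm(N * n_input * 2, sd = 0.05),
                                    dim = c(N, n_input, 2)),
                          b = numeric(2)))
    } else if (variant == "mgp_tcn") {
      list(tcn_a = new_tcn_stack(n_input, config),
           readout = list(W = matrix(stats::rnorm(n_input * 2, sd = 0.1),
                                     n_input, 2),
                          b = numeric(2)))
    } else {
      list(tcn_a = new_tcn_stack(n_input, config),
           tcn_b = new_tcn_stack(n_input, config),
           attn = list(W_alpha = matrix(stats::rnorm(n_input * 2, sd = 0.1),
                                        n_input, 2),
                       b_alpha = numeric(2),
                       W_beta = array(stats::rnorm(n_input * n_input * 2,
                                                   sd = 0.1),
                                      dim = c(n_input, n_input, 2)),
                       b_beta = matrix(0, n_input, 2)))
    }
  })
  structure(c(net, list(config = config, variant = variant,
                        n_input = n_input, N = as.integer(N))),
            class = "atttcn_net")
}

#' Switch a classifier to an ablation variant
#'
#' `no_alpha` fixes the attention over time to uniform `1/N` for both classes;
#' `no_beta` fixes the feature attention to one; `mgp_tcn` replaces the
#' attention head with a plain TCN plus a final linear-softmax readout over
#' the last step (re-initializing the parameters accordingly).
#'
#' @param net an [atttcn_init()] network.
#' @param variant one of `"no_alpha"`, `"no_beta"`, `"mgp_tcn"`.
#' @param seed seed for any re-initialized weights.
#' @return an `atttcn_net` of the requested variant.
#' @export
ablate <- function(net, variant, seed = 1) {
  if (!variant %in% c("no_alpha", "no_beta", "mgp_tcn"))
    stop("unknown ablation variant: ", variant)
  if (variant %in% c("no_alpha", "no_beta") &&
      net$variant %in% c("mgp_tcn", "mgp_logreg"))
    stop("cannot ablate attention of a model without an attention head")
  if (variant == "mgp_tcn")
    return(atttcn_init(net$n_input, net$N, net$config, "mgp_tcn", seed))
  net$variant <- variant
  net
}

# ---- forward / backward -----------------------------------------------------

tcn_stack_forward <- function(layers, X, masks = NULL) {
  cache <- vector("list", length(layers))
  H <- X
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    pre <- conv_causal_forward(H, lay$W, lay$b)
    cache[[li]] <- list(input = H, pre = pre)
    H <- if (lay$relu) pmax(pre, 0) else pre
    if (lay$dropout && !is.null(masks) && !is.null(masks[[li]])) {
      H <- H * masks[[li]]
      cache[[li]]$mask <- masks[[li]]
    }
  }
  list(out = H, cache = cache)
}

tcn_stack_backward <- function(layers, cache, dOut) {
  grads <- vector("list", length(layers))
  dH <- dOut
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    if (!is.null(cache[[li]]$mask)) dH <- dH * cache[[li]]$mask
    dPre <- if (lay$relu) dH * (cache[[li]]$pre > 0) else dH
    cb <- conv_causal_backward(dPre, cache[[li]]$input, lay$W)
    grads[[li]] <- list(W = cb$dW, b = cb$db)
    dH <- cb$dX
  }
  list(grads = grads, dX = dH)
}

#' Causal TCN embedding
#'
#' Runs one input window through a causal convolution stack; the output at
#' time step `i` depends only on inputs at steps `<= i`.
#'
#' @param x input matrix `N x n_input`.
#' @param layers a TCN stack (e.g. `net$tcn_a` from [atttcn_init()]).
#' @return embedding matrix `N x n_input`.
#' @export
tcn_embed <- function(x, layers) {
  tcn_stack_forward(layers, x)$out
}

#' Attention heads
#'
#' Time attention `alpha` (softmax over the `N` steps, per class) and feature
#' attention `beta` (elementwise sigmoid), computed from the two embeddings.
#'
#' @param z,zp embedding matrices `N x n_input` (from the two TCN stacks).
#' @param attn attention parameter list (`W_alpha`, `b_alpha`, `W_beta`,
#'   `b_beta`), e.g. `net$attn`.
#' @param pad_mask optional logical vector of length `N`; `TRUE` rows
#'   (zero-padded grid steps) are excluded from the time softmax. Off by
#'   default: padded rows carry zero inputs, so they cannot contribute to
#'   the class scores either way.
#' @return list with `alpha` (`N x 2`, columns summing to one) and `beta`
#'   (`N x n_input x 2`, entries in `[0, 1]`).
#' @export
attention_heads <- function(z, zp, attn, pad_mask = NULL) {
  N <- nrow(z)
  e <- sweep(z %*% attn$W_alpha, 2, attn$b_alpha, "+")
  if (!is.null(pad_mask)) e[pad_mask, ] <- -Inf
  alpha <- apply(e, 2, function(col) {
    w <- exp(col - max(col)); w / sum(w)
  })
  beta <- array(0, dim = c(N, ncol(z), 2))
  for (d in 1:2)
    beta[, , d] <- stats::plogis(sweep(zp %*% attn$W_beta[, , d], 2,
                                       attn$b_beta[, d], "+"))
  list(alpha = alpha, beta = beta)
}

#' Context scores and prediction
#'
#' Per-class context contributions `c[j, m, d] = alpha[j, d] beta[j, m, d]
#' x[j, m]`; the step-`i` class score is the cumulative sum over `j <= i` and
#' all columns, and the prediction is its softmax over the two classes. Only
#' the last step is used for training (prediction with the latest data).
#'
#' @param alpha `N x 2` time attention.
#' @param beta `N x n_input x 2` feature attention.
#' @param x the input window `N x n_input` (one Monte Carlo sample).
#' @return list with `context` (`N x n_input x 2`), `scores_by_step`
#'   (`N x 2` cumulative class scores), `lhat_by_step` (`N x 2` softmax per
#'   step) and `lhat` (the last step's class probabilities).
#' @export
context_and_predict <- function(alpha, beta, x) {
  N <- nrow(x)
  context <- array(0, dim = dim(beta))
  for (d in 1:2) context[, , d] <- alpha[, d] * beta[, , d] * x
  step_scores <- cbind(apply(context[, , 1, drop = FALSE], 1, sum),
                       apply(context[, , 2, drop = FALSE], 1, sum))
  scores_by_step <- apply(step_scores, 2, cumsum)
  if (N == 1) scores_by_step <- matrix(scores_by_step, 1, 2)
  lhat_by_step <- t(apply(scores_by_step, 1, function(s) {
    w <- exp(s - max(s)); w / sum(w)
  }))
  list(context = context, scores_by_step = scores_by_step,
       lhat_by_step = lhat_by_step, lhat = lhat_by_step[N, ])
}

#' Per-cell score contributions
#'
#' The interpretability output: for each time point, feature and class, the
#' contribution `alpha * beta * y_MC`, averaged over the Monte Carlo samples
#' of a batch.
#'
#' @param net a (trained) [atttcn_init()] network with an attention head.
#' @param batch a [draw_samples()] batch.
#' @return array `N x n_input x 2` of averaged contributions.
#' @export
score_contributions <- function(net, batch) {
  if (net$variant %in% c("mgp_tcn", "mgp_logreg"))
    stop("score contributions require an attention head")
  S <- dim(batch$samples)[3]
  acc <- array(0, dim = c(net$N, net$n_input, 2))
  for (s in seq_len(S)) {
    x <- batch$samples[, , s]
    fw <- classifier_forward(net, x)
    acc <- acc + fw$cp$context
  }
  acc / S
}

# full forward pass for one sample; masks: list(a = ..., b = ...) dropout masks
classifier_forward <- function(net, x, masks = NULL) {
  variant <- net$variant
  N <- nrow(x)
  if (variant == "mgp_logreg") {
    s <- c(sum(x * net$readout$W[, , 1]), sum(x * net$readout$W[, , 2])) +
      net$readout$b
    w <- exp(s - max(s))
    return(list(lhat = w / sum(w), scores = s, variant = variant, x = x))
  }
  fa <- tcn_stack_forward(net$tcn_a, x, masks$a)
  if (variant == "mgp_tcn") {
    z_last <- fa$out[N, ]
    s <- as.numeric(z_last %*% net$readout$W) + net$readout$b
    w <- exp(s - max(s))
    return(list(lhat = w / sum(w), scores = s, variant = variant,
                fa = fa, x = x))
  }
  fb <- tcn_stack_forward(net$tcn_b, x, masks$b)
  z <- fa$out; zp <- fb$out
  if (variant == "no_alpha") {
    alpha <- matrix(1 / N, N, 2)
  } else {
    e <- sweep(z %*% net$attn$W_alpha, 2, net$attn$b_alpha, "+")
    alpha <- apply(e, 2, function(col) { w <- exp(col - max(col)); w / sum(w) })
  }
  if (variant == "no_beta") {
    beta <- array(1, dim = c(N, net$n_input, 2))
  } else {
    beta <- array(0, dim = c(N, net$n_input, 2))
    for (d in 1:2)
      beta[, , d] <- stats::plogis(sweep(zp %*% net$attn$W_beta[, , d], 2,
                                         net$attn$b_beta[, d], "+"))
  }
  cp <- context_and_predict(alpha, beta, x)
  list(lhat = cp$lhat, scores = cp$scores_by_step[N, ], variant = variant,
       fa = fa, fb = fb, z = z, zp = zp, alpha = alpha, beta = beta,
       cp = cp, x = x)
}

# backward pass: ds is dloss/dscores (length 2). Returns parameter gradients
# in the same shape as the net, plus dloss/dx.
classifier_backward <- function(net, fw, ds) {
  variant <- net$variant
  x <- fw$x
  N <- nrow(x)
  if (variant == "mgp_logreg") {
    dW <- array(0, dim = dim(net$readout$W))
    dW[, , 1] <- ds[1] * x
    dW[, , 2] <- ds[2] * x
    dx <- ds[1] * net$readout$W[, , 1] + ds[2] * net$readout$W[, , 2]
    return(list(grads = list(readout = list(W = dW, b = ds)), dx = dx))
  }
  if (variant == "mgp_tcn") {
    z_last <- fw$fa$out[N, ]
    dW <- outer(z_last, ds)
    dZ <- matrix(0, N, net$n_input)
    dZ[N, ] <- as.numeric(net$readout$W %*% ds)
    tb <- tcn_stack_backward(net$tcn_a, fw$fa$cache, dZ)
    return(list(grads = list(tcn_a = tb$grads,
                             readout = list(W = dW, b = ds)),
                dx = tb$dX))
  }
  alpha <- fw$alpha; beta <- fw$beta
  dx <- matrix(0, N, net$n_input)
  dalpha <- matrix(0, N, 2)
  dbeta <- array(0, dim = dim(beta))
  for (d in 1:2) {
    r <- rowSums(beta[, , d] * x)
    dalpha[, d] <- ds[d] * r
    dbeta[, , d] <- ds[d] * alpha[, d] * x
    dx <- dx + ds[d] * alpha[, d] * beta[, , d]
  }
  # gradient structure mirrors extract_net_weights() order: tcn_a, tcn_b, attn
  attn_grads <- list(W_alpha = matrix(0, net$n_input, 2),
                     b_alpha = numeric(2),
                     W_beta = array(0, dim = dim(net$attn$W_beta)),
                     b_beta = matrix(0, net$n_input, 2))
  dZ <- matrix(0, N, net$n_input)
  dZp <- matrix(0, N, net$n_input)
  if (variant != "no_alpha") {
    for (d in 1:2) {
      a <- alpha[, d]
      de <- a * (dalpha[, d] - sum(a * dalpha[, d]))   # softmax backward
      attn_grads$W_alpha[, d] <- as.numeric(crossprod(fw$z, de))
      attn_grads$b_alpha[d] <- sum(de)
      dZ <- dZ + outer(de, net$attn$W_alpha[, d])
    }
  }
  if (variant != "no_beta") {
    for (d in 1:2) {
      dpre <- dbeta[, , d] * beta[, , d] * (1 - beta[, , d])
      attn_grads$W_beta[, , d] <- crossprod(fw$zp, dpre)
      attn_grads$b_beta[, d] <- colSums(dpre)
      dZp <- dZp + dpre %*% t(net$attn$W_beta[, , d])
    }
  }
  ta <- tcn_stack_backward(net$tcn_a, fw$fa$cache, dZ)
  tb <- tcn_stack_backward(net$tcn_b, fw$fb$cache, dZp)
  dx <- dx + ta$dX + tb$dX
  list(grads = list(tcn_a = ta$grads, tcn_b = tb$grads, attn = attn_grads),
       dx = dx)
}

# dropout masks for one training step (inverted dropout)
make_dropout_masks <- function(net) {
  p <- net$config$dropout
  if (is.null(net$tcn_a) || p <= 0) return(NULL)
  gen <- function(layers)
    lapply(layers, function(lay) {
      if (!lay$dropout) return(NULL)
      c_out <- dim(lay$W)[3]
      matrix((stats::runif(net$N * c_out) >= p) / (1 - p), net$N, c_out)
    })
  m <- list(a = gen(net$tcn_a))
  if (!is.null(net$tcn_b)) m$b <- gen(net$tcn_b)
  m
}
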