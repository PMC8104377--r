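# Joint end-to-end training: gradient descent on the MGP hyperparameters and
# the classifier weights through reparameterized Monte Carlo samples.

# ---- weight bookkeeping -----------------------------------------------------

extract_net_weights <- function(net) {
  w <- list()
  for (nm in c("tcn_a", "tcn_b"))
    if (!is.null(net[[nm]]))
      w[[nm]] <- lapply(net[[nm]], function(lay) list(W = lay$W, b = lay$b))
  if (!is.null(net$attn)) w$attn <- net$attn
  if (!is.null(net$readout)) w$readout <- net$readout
  w
}

inject_net_weights <- function(net, w) {
  for (nm in c("tcn_a", "tcn_b"))
    if (!is.null(w[[nm]]))
      for (li in seq_along(w[[nm]])) {
        net[[nm]][[li]]$W <- w[[nm]][[li]]$W
        net[[nm]][[li]]$b <- w[[nm]][[li]]$b
      }
  if (!is.null(w$attn)) net$attn <- w$attn
  if (!is.null(w$readout)) net$readout <- w$readout
  net
}

extract_mgp_weights <- function(mgp) {
  list(theta_lambda = mgp$theta_lambda, factors = mgp$factors,
       theta_sigma = mgp$theta_sigma)
}

inject_mgp_weights <- function(mgp, w) {
  mgp$theta_lambda <- w$theta_lambda
  mgp$factors <- w$factors
  mgp$theta_sigma <- w$theta_sigma
  mgp
}

# L2 penalty on convolution weights: l2 * mean(W^2) over all conv entries
net_l2_penalty <- function(net) {
  if (net$config$l2 <= 0) return(list(value = 0, n = 1))
  ssq <- 0; n <- 0
  for (nm in c("tcn_a", "tcn_b"))
    if (!is.null(net[[nm]]))
      for (lay in net[[nm]]) { ssq <- ssq + sum(lay$W^2); n <- n + length(lay$W) }
  if (n == 0) return(list(value = 0, n = 1))
  list(value = net$config$l2 * ssq / n, n = n)
}

# ---- per-record forward/backward through MGP + classifier -------------------

prepare_inputs <- function(records, roster) {
  lapply(records, function(r) {
    ob <- record_obs(r, roster)
    list(ob = ob, statics = r$statics, label = r$label,
         end_time = r$end_time, horizon = r$horizon, id = r$patient_id)
  })
}

build_sample_matrix <- function(samp_vec, n_eff, M, N, statics) {
  Q <- length(statics)
  x <- matrix(0, N, M + Q)
  rows <- (N - n_eff + 1):N
  x[rows, 1:M] <- matrix(samp_vec, n_eff, M)
  x[rows, M + seq_len(Q)] <- matrix(statics, n_eff, Q, byrow = TRUE)
  x
}

# forward (and optionally backward) for one record: S Monte Carlo samples.
# eta may be supplied for deterministic gradient checks.
record_forward <- function(mgp, net, inp, N, S, eta = NULL, masks = NULL,
                           grad = TRUE) {
  t_grid <- as.numeric(-(N - 1):0)
  t_grid <- t_grid[t_grid >= -inp$end_time]
  cond <- mgp_condition(mgp, inp$ob$feat, inp$ob$t, inp$ob$y, t_grid)
  G <- cond$G
  L <- chol_jitter(cond$Sigma, mgp$jitter, "posterior covariance")
  if (is.null(eta)) eta <- matrix(stats::rnorm(G * S), G, S)
  samp <- cond$mu + L %*% eta
  n_eff <- length(t_grid)
  M <- mgp$M
  loss <- 0
  lhat_sum <- c(0, 0)
  net_grads <- NULL
  dmu <- numeric(G)
  dL <- matrix(0, G, G)
  onehot <- c(inp$label == 0, inp$label == 1)
  for (s in seq_len(S)) {
    x <- build_sample_matrix(samp[, s], n_eff, M, N, inp$statics)
    fw <- classifier_forward(net, x, masks)
    lh <- pmax(fw$lhat, 1e-12)
    loss <- loss - log(lh[inp$label + 1]) / S
    lhat_sum <- lhat_sum + fw$lhat
    if (grad) {
      ds <- (fw$lhat - onehot) / S
      bk <- classifier_backward(net, fw, ds)
      net_grads <- add_weight_grads(net_grads, bk$grads)
      dxs <- bk$dx[(N - n_eff + 1):N, 1:M, drop = FALSE]
      dvec <- as.numeric(dxs)
      dmu <- dmu + dvec
      dL <- dL + tcrossprod(dvec, eta[, s])
    }
  }
  out <- list(loss = loss, lhat = lhat_sum / S)
  if (grad) {
    dL[upper.tri(dL)] <- 0
    out$net_grads <- net_grads
    out$mgp_grads <- mgp_sample_backward(cond, L, dmu, dL)
  }
  out
}

# recursive elementwise addition of nested numeric-gradient lists
add_weight_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (i in seq_along(b)) a[[i]] <- add_weight_grads(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

scale_weight_grads <- function(a, s) {
  if (is.list(a)) return(lapply(a, scale_weight_grads, s = s))
  a * s
}

#' Monte-Carlo cross-entropy loss
#'
#' Mean over Monte Carlo samples of the cross-entropy of the predicted class
#' probabilities against the label; the training objective adds the TCN's L2
#' penalty on top.
#'
#' @param preds matrix `S x 2` of per-sample class probabilities.
#' @param label 0 or 1.
#' @return scalar loss.
#' @export
loss_mc_cross_entropy <- function(preds, label) {
  preds <- pmax(preds, 1e-12)
  if (any(abs(rowSums(preds) - 1) > 1e-6))
    stop("predictions must lie in the probability simplex")
  mean(-log(preds[, label + 1]))
}

#' Balanced oversampled batches
#'
#' Training only: the case set is resampled with replacement to the control
#' count, and each batch holds equal numbers of cases and controls, shuffled.
#' Validation and test are never resampled.
#'
#' @param labels 0/1 vector over the training records.
#' @param batch_size total batch size (cases + controls).
#' @param seed integer seed.
#' @return list of integer index vectors, one per batch.
#' @export
balanced_batches <- function(labels, batch_size, seed = 1) {
  cases <- which(labels == 1)
  controls <- which(labels == 0)
  if (!length(cases)) stop("training split has no cases")
  if (!length(controls)) stop("training split has no controls")
  half <- max(1L, floor(batch_size / 2))
  with_seed(seed, {
    n <- max(length(controls), length(cases))
    case_stream <- if (length(cases) >= n) sample(cases, n)
                   else sample(cases, n, replace = TRUE)
    ctrl_stream <- if (length(controls) >= n) sample(controls, n)
                   else sample(controls, n, replace = TRUE)
    n_batches <- ceiling(n / half)
    lapply(seq_len(n_batches), function(bi) {
      idx <- ((bi - 1) * half + 1):min(bi * half, n)
      sample(c(case_stream[idx], ctrl_stream[idx]))
    })
  })
}

#' Train the joint MGP + classifier model
#'
#' Joint first-order gradient descent (Adam) on the Gaussian-process
#' hyperparameters, the TCN stacks and the attention head, through
#' reparameterized Monte Carlo samples of the posterior. Balanced oversampled
#' batches; early stopping on validation AUPR.
#'
#' @param dataset a [build_horizon_dataset()]-style list (`records`, `split`,
#'   `roster`).
#' @param variant model variant: `"full"`, `"no_alpha"`, `"no_beta"`,
#'   `"mgp_tcn"` or `"mgp_logreg"`.
#' @param tcn a [tcn_config()].
#' @param N window length (default 25).
#' @param S Monte Carlo samples per record during training.
#' @param epochs,batch_size,lr,lr_decay,patience optimizer settings;
#'   `lr_decay` multiplies the learning rate once per epoch; `patience` is in
#'   epochs of non-improving validation AUPR (ignored when no validation
#'   split exists).
#' @param seed integer seed controlling initialization, batching, dropout and
#'   sampling; the same seed reproduces the run exactly.
#' @param eval_S Monte Carlo samples used for the per-epoch validation score.
#' @param mgp_init optional starting [mgp_params()].
#' @param keep_epoch_params keep a snapshot of the parameters after every
#'   epoch (for invariant checks).
#' @param verbose print per-epoch progress.
#' @return object of class `mgp_atttcn_model`: `mgp`, `net`, `roster`, `N`,
#'   `history` (per-epoch data.frame), `best_epoch`, and optionally
#'   `epoch_params`.
#' @export
train_model <- function(dataset, variant = "full", tcn = tcn_config(),
                        N = 25, S = 4, epochs = 10, batch_size = 32,
                        lr = 1e-3, lr_decay = 1, patience = 3, seed = 1,
                        eval_S = 4,
                        mgp_init = NULL, keep_epoch_params = FALSE,
                        verbose = FALSE) {
  roster <- dataset$roster
  M <- roster$M
  train_idx <- which(dataset$split == "train")
  val_idx <- which(dataset$split == "val")
  if (!length(train_idx)) stop("dataset has no training split")
  inputs <- prepare_inputs(dataset$records, roster)
  labels <- vapply(inputs, function(i) i$label, integer(1))
  if (anyNA(labels[train_idx])) stop("training records must be labelled")

  mgp <- mgp_init %||% init_mgp_params(M, seed = derive_seed(seed, 21))
  net <- atttcn_init(M + roster$Q, N, tcn, variant,
                     seed = derive_seed(seed, 22))
  weights <- list(mgp = extract_mgp_weights(mgp),
                  net = extract_net_weights(net))
  fl <- flatten_params(weights)
  opt <- adam_init(length(fl$vec))
  n_l2 <- net_l2_penalty(net)$n

  history <- list()
  epoch_params <- list()
  best <- list(aupr = -Inf, vec = fl$vec, epoch = 0)
  bad_epochs <- 0

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      batches <- balanced_batches(labels[train_idx], batch_size,
                                  seed = derive_seed(seed, 100 + ep))
      ep_loss <- 0; n_seen <- 0
      for (bt in batches) {
        idx <- train_idx[bt]
        g_net <- NULL
        g_mgp <- zero_mgp_grads(M)
        b_loss <- 0
        for (i in idx) {
          masks <- make_dropout_masks(net)
          rf <- record_forward(mgp, net, inputs[[i]], N, S, masks = masks)
          b_loss <- b_loss + rf$loss
          g_net <- add_weight_grads(g_net, rf$net_grads)
          g_mgp <- add_mgp_grads(g_mgp, rf$mgp_grads)
        }
        nb <- length(idx)
        g_net <- scale_weight_grads(g_net, 1 / nb)
        g_mgp <- scale_mgp_grads(g_mgp, 1 / nb)
        # L2 on conv weights
        if (net$config$l2 > 0) {
          for (nm in c("tcn_a", "tcn_b"))
            if (!is.null(g_net[[nm]]))
              for (li in seq_along(g_net[[nm]]))
                g_net[[nm]][[li]]$W <- g_net[[nm]][[li]]$W +
                  2 * net$config$l2 * net[[nm]][[li]]$W / n_l2
        }
        gfl <- flatten_params(list(mgp = g_mgp[c("theta_lambda", "factors",
                                                 "theta_sigma")],
                                   net = g_net))
        if (!all(is.finite(gfl$vec))) stop("training diverged (non-finite gradient)")
        opt <- adam_step(opt, gfl$vec, lr = lr * lr_decay^(ep - 1))
        fl$vec <- fl$vec + opt$delta
        weights <- unflatten_params(fl$vec, fl$skeleton)
        mgp <- inject_mgp_weights(mgp, weights$mgp)
        net <- inject_net_weights(net, weights$net)
        ep_loss <- ep_loss + b_loss
        n_seen <- n_seen + nb
      }
      ep_loss <- ep_loss / n_seen + net_l2_penalty(net)$value
      val_auroc <- NA_real_; val_aupr <- NA_real_
      if (length(val_idx)) {
        vs <- predict_inputs(mgp, net, inputs[val_idx], N, eval_S,
                             seed = derive_seed(seed, 500 + ep))
        val_auroc <- auroc(vs, labels[val_idx])
        val_aupr <- aupr(vs, labels[val_idx])
      }
      history[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss,
                                  val_auroc = val_auroc, val_aupr = val_aupr)
      if (keep_epoch_params)
        epoch_params[[ep]] <- list(mgp = mgp, net = net)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val AUROC %.3f, val AUPR %.3f",
                        ep, ep_loss, val_auroc, val_aupr))
      metric <- if (is.na(val_aupr)) -ep_loss else val_aupr
      if (metric > best$aupr + 1e-9) {
        best <- list(aupr = metric, vec = fl$vec, epoch = ep)
        bad_epochs <- 0
      } else {
        bad_epochs <- bad_epochs + 1
        if (length(val_idx) && bad_epochs >= patience) break
      }
    }
  })
  weights <- unflatten_params(best$vec, fl$skeleton)
  mgp <- inject_mgp_weights(mgp, weights$mgp)
  net <- inject_net_weights(net, weights$net)
  structure(list(mgp = mgp, net = net, roster = roster, N = N, S = S,
                 history = do.call(rbind, history), best_epoch = best$epoch,
                 epoch_params = if (keep_epoch_params) epoch_params),
            class = "mgp_atttcn_model")
}

#' @export
print.mgp_atttcn_model <- function(x, ...) {
  cat(sprintf("<mgp_atttcn_model> variant %s, N = %d, best epoch %d\n",
              x$net$variant, x$N, x$best_epoch))
  invisible(x)
}

# mean predicted case probability over S samples, per prepared input
predict_inputs <- function(mgp, net, inputs, N, S, seed = 1) {
  with_seed(seed, vapply(inputs, function(inp) {
    rf <- record_forward(mgp, net, inp, N, S, grad = FALSE)
    rf$lhat[2]
  }, numeric(1)))
}

#' Predict case probabilities
#'
#' The score of a record is the mean over `S` Monte Carlo samples of the
#' predicted probability of the positive class at the last grid step.
#'
#' @param model a [train_model()] fit.
#' @param records list of (normalized) records.
#' @param S Monte Carlo samples (default: the model's training `S`).
#' @param seed integer seed for the posterior draws.
#' @return numeric vector of case probabilities.
#' @export
predict_model <- function(model, records, S = model$S, seed = 1) {
  inputs <- prepare_inputs(records, model$roster)
  predict_inputs(model$mgp, model$net, inputs, model$N, S, seed = seed)
}

#' Attention-based explanation for one record
#'
#' Draws Monte Carlo samples, runs the classifier, and averages the time
#' attention, the feature attention, and the per-cell score contributions
#' over the samples.
#'
#' @param model a [train_model()] fit with an attention head.
#' @param record one (normalized) record.
#' @param S,seed Monte Carlo settings.
#' @return list with `alpha` (`N x 2`), `beta` (`N x (M+Q) x 2`),
#'   `contributions` (`N x (M+Q) x 2`), and the mean prediction `lhat`.
#' @export
explain_record <- function(model, record, S = model$S, seed = 1) {
  if (model$net$variant %in% c("mgp_tcn", "mgp_logreg"))
    stop("explanations require an attention head")
  inp <- prepare_inputs(list(record), model$roster)[[1]]
  N <- model$N
  t_grid <- as.numeric(-(N - 1):0)
  t_grid <- t_grid[t_grid >= -inp$end_time]
  cond <- mgp_condition(model$mgp, inp$ob$feat, inp$ob$t, inp$ob$y, t_grid)
  L <- chol_jitter(cond$Sigma, model$mgp$jitter, "posterior covariance")
  eta <- with_seed(seed, matrix(stats::rnorm(cond$G * S), cond$G, S))
  samp <- cond$mu + L %*% eta
  alpha <- matrix(0, N, 2)
  beta <- array(0, dim = c(N, model$net$n_input, 2))
  contrib <- array(0, dim = c(N, model$net$n_input, 2))
  lhat <- c(0, 0)
  for (s in seq_len(S)) {
    x <- build_sample_matrix(samp[, s], length(t_grid), model$mgp$M, N,
                             inp$statics)
    fw <- classifier_forward(model$net, x)
    alpha <- alpha + fw$alpha / S
    beta <- beta + fw$beta / S
    contrib <- contrib + fw$cp$context / S
    lhat <- lhat + fw$lhat / S
  }
  list(alpha = alpha, beta = beta, contributions = contrib, lhat = lhat,
       grid_times = t_grid)
}
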