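#' Area under the ROC curve
#'
#' Rank-statistic implementation (Mann-Whitney), ties handled by average
#' ranks. Returns `NA` when only one class is present.
#'
#' @param scores numeric scores, larger = more case-like.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: the PR curve is stepped through the distinct score
#' thresholds (descending), and precision is accumulated against recall
#' increments, whole tie-groups at a time.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`, or `NA` when only one class is present.
#' @export
aupr <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  groups <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(groups, fromLast = TRUE)   # end of each tie group
  tp_g <- tp[last]; fp_g <- fp[last]
  prec <- tp_g / (tp_g + fp_g)
  rec <- tp_g / n1
  sum(diff(c(0, rec)) * prec)
}

#' Per-horizon evaluation report
#'
#' Scores a split with the model (mean class-1 probability over `S` Monte
#' Carlo samples) and reports AUROC and AUPR stratified by prediction
#' horizon. A horizon with a single class reports `NA` metrics, never 0.
#'
#' @param model a [train_model()] fit.
#' @param dataset a dataset list (`records`, `split`, `roster`).
#' @param split which split to evaluate (default `"test"`).
#' @param horizons horizons to report (default: those present).
#' @param S,seed Monte Carlo settings.
#' @return data.frame with columns `horizon, n, n_cases, auroc, aupr`, plus a
#'   final row `horizon = NA` pooling all records.
#' @export
evaluate_model <- function(model, dataset, split = "test", horizons = NULL,
                           S = model$S, seed = 1) {
  idx <- which(dataset$split == split)
  if (!length(idx)) stop("no records in split '", split, "'")
  records <- dataset$records[idx]
  scores <- predict_model(model, records, S = S, seed = seed)
  labels <- vapply(records, function(r) r$label, integer(1))
  hor <- vapply(records, function(r)
    if (is.na(r$horizon)) 0L else r$horizon, integer(1))
  horizons <- horizons %||% sort(unique(hor))
  rows <- lapply(horizons, function(h) {
    sel <- hor == h
    data.frame(horizon = h, n = sum(sel), n_cases = sum(labels[sel] == 1),
               auroc = auroc(scores[sel], labels[sel]),
               aupr = aupr(scores[sel], labels[sel]))
  })
  pooled <- data.frame(horizon = NA_integer_, n = length(idx),
                       n_cases = sum(labels == 1),
                       auroc = auroc(scores, labels),
                       aupr = aupr(scores, labels))
  rbind(do.call(rbind, rows), pooled)
}

#' Random hyperparameter search
#'
#' Uniform draws over the classifier search space — Monte Carlo samples
#' 4--20, kernel size 2--6, residual blocks 2--12, hidden channels 10--55
#' (integers), dropout `[0, 0.99]` and L2 `[0, 250]` (continuous) — training
#' one model per trial and selecting the best by validation AUPR.
#'
#' @param dataset dataset list passed to [train_model()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; the draw sequence is a pure function of it.
#' @param epochs,batch_size,... forwarded to [train_model()] (use small
#'   budgets for search).
#' @param train_fun the training function, replaceable for dry runs; it
#'   receives `(dataset, tcn, S, seed, ...)` and must return an object whose
#'   `history` has a `val_aupr` column.
#' @return list with `best` (the winning trial's settings), `trials`
#'   (data.frame of all draws and their validation AUPR), and `model` (the
#'   refitted best model, when `refit = TRUE`).
#' @param refit refit the best configuration on exit.
#' @export
random_search <- function(dataset, n_trials, seed = 1, epochs = 2,
                          batch_size = 16, train_fun = train_model,
                          refit = FALSE, ...) {
  stopifnot(n_trials >= 1)
  draws <- with_seed(seed, data.frame(
    trial = seq_len(n_trials),
    S = sample(4:20, n_trials, replace = TRUE),
    kernel_size = sample(2:6, n_trials, replace = TRUE),
    n_blocks = sample(2:12, n_trials, replace = TRUE),
    n_hidden = sample(10:55, n_trials, replace = TRUE),
    dropout = stats::runif(n_trials, 0, 0.99),
    l2 = stats::runif(n_trials, 0, 250)
  ))
  draws$val_aupr <- NA_real_
  for (i in seq_len(n_trials)) {
    cfg <- tcn_config(draws$kernel_size[i], draws$n_blocks[i],
                      draws$n_hidden[i], draws$dropout[i], draws$l2[i])
    fit <- train_fun(dataset, tcn = cfg, S = draws$S[i],
                     seed = derive_seed(seed, 1000 + i),
                     epochs = epochs, batch_size = batch_size, ...)
    h <- fit$history
    draws$val_aupr[i] <- if (!is.null(h) && any(is.finite(h$val_aupr)))
      max(h$val_aupr, na.rm = TRUE) else NA_real_
  }
  best_i <- if (all(is.na(draws$val_aupr))) 1L else which.max(draws$val_aupr)
  out <- list(best = draws[best_i, ], trials = draws)
  if (refit) {
    cfg <- tcn_config(draws$kernel_size[best_i], draws$n_blocks[best_i],
                      draws$n_hidden[best_i], draws$dropout[best_i],
                      draws$l2[best_i])
    out$model <- train_fun(dataset, tcn = cfg, S = draws$S[best_i],
                           seed = derive_seed(seed, 999), epochs = epochs,
                           batch_size = batch_size, ...)
  }
  out
}
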