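# The InSight baseline: six-hour window statistics (means, differences,
# pair and triplet correlations), adjusted-quantile trichotomization fitted on
# the training split, and a ridge logistic scorer. Also the plain ridge
# logistic regression on the flattened hourly grid and the MGP-log.reg.
# ablation.

#' Sliding six-hour window statistics
#'
#' For each of the `N - 5` sliding windows of six consecutive hours and each
#' variable: the window mean and the difference (last value minus first).
#'
#' @param grid a [hourly_grid_impute()] dense grid (`values` is `N x M`).
#' @param window window length in hours (default 6).
#' @return list with `means` and `diffs`, each `(N - window + 1) x M`.
#' @export
window_stats <- function(grid, window = 6) {
  V <- grid$values
  N <- nrow(V)
  if (N < window) stop("grid has fewer than ", window, " hours")
  n_win <- N - window + 1
  means <- matrix(0, n_win, ncol(V))
  diffs <- matrix(0, n_win, ncol(V))
  for (w in seq_len(n_win)) {
    block <- V[w:(w + window - 1), , drop = FALSE]
    means[w, ] <- colMeans(block)
    diffs[w, ] <- block[window, ] - block[1, ]
  }
  list(means = means, diffs = diffs)
}

#' Pair correlation with the zero-variance convention
#'
#' Pearson correlation with population moments; returns 0 when either input
#' has zero variance (forward-imputed windows are often constant, and those
#' are scored as "no correlation" rather than undefined).
#'
#' @param x,y numeric vectors of equal length (six-hour windows).
#' @return correlation in `[-1, 1]`.
#' @export
pair_correlation <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  sx <- sqrt(mean(cx^2)); sy <- sqrt(mean(cy^2))
  if (sx == 0 || sy == 0) return(0)
  mean(cx * cy) / (sx * sy)
}

#' Triplet correlation
#'
#' Third-order standardized cross moment
#' `E[(X - muX)(Y - muY)(Z - muZ)] / (sX sY sZ)` with population moments — a
#' relaxation of the Pearson correlation to variable triplets; 0 when any
#' input has zero variance. Symmetric under any permutation of its arguments,
#' and equal to the (population) skewness when all three arguments coincide.
#'
#' @param x,y,z numeric vectors of equal length.
#' @return triplet correlation.
#' @export
triplet_correlation <- function(x, y, z) {
  cx <- x - mean(x); cy <- y - mean(y); cz <- z - mean(z)
  sx <- sqrt(mean(cx^2)); sy <- sqrt(mean(cy^2)); sz <- sqrt(mean(cz^2))
  if (sx == 0 || sy == 0 || sz == 0) return(0)
  mean(cx * cy * cz) / (sx * sy * sz)
}

#' Adjusted-quantile trichotomization
#'
#' Because forward imputation produces many exactly-zero correlations, the
#' tercile thresholds are computed over the *non-zero* values only (type-1
#' empirical quantiles, i.e. the inverse empirical CDF), then applied with
#' strict inequalities: `1` above the upper threshold, `-1` below the lower,
#' `0` otherwise. Thresholds are fitted on training data and frozen.
#'
#' @param values numeric vector of training values.
#' @return object of class `trichotomizer`: list with `lo`, `hi`.
#' @export
fit_trichotomizer <- function(values) {
  nz <- values[values != 0 & is.finite(values)]
  if (!length(nz)) {
    message("all values zero; trichotomization maps everything to 0")
    return(structure(list(lo = 0, hi = 0), class = "trichotomizer"))
  }
  q <- stats::quantile(nz, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  structure(list(lo = q[1], hi = q[2]), class = "trichotomizer")
}

#' @rdname fit_trichotomizer
#' @param tri a fitted `trichotomizer`.
#' @param x values to map to `{-1, 0, 1}`. Exact zeros always map to 0: they
#'   were excluded from the threshold fit as "no signal" and stay negligible.
#' @export
trichotomize <- function(tri, x) {
  out <- integer(length(x))
  out[x > tri$hi] <- 1L
  out[x < tri$lo] <- -1L
  out[x == 0] <- 0L
  out
}

# raw (un-trichotomized) window features of one grid, in the documented
# column order: windows outer; within a window means, diffs, pair
# correlations (combn order), triplet correlations
insight_raw_features <- function(grid, window = 6) {
  V <- grid$values
  M <- ncol(V)
  ws <- window_stats(grid, window)
  n_win <- nrow(ws$means)
  pairs <- if (M >= 2) utils::combn(M, 2) else matrix(0, 2, 0)
  triplets <- if (M >= 3) utils::combn(M, 3) else matrix(0, 3, 0)
  out <- list(means = ws$means, diffs = ws$diffs,
              pair = matrix(0, n_win, ncol(pairs)),
              triplet = matrix(0, n_win, ncol(triplets)))
  for (w in seq_len(n_win)) {
    block <- V[w:(w + window - 1), , drop = FALSE]
    if (ncol(pairs))
      out$pair[w, ] <- apply(pairs, 2, function(ij)
        pair_correlation(block[, ij[1]], block[, ij[2]]))
    if (ncol(triplets))
      out$triplet[w, ] <- apply(triplets, 2, function(ijk)
        triplet_correlation(block[, ijk[1]], block[, ijk[2]], block[, ijk[3]]))
  }
  out
}

#' InSight feature matrix
#'
#' Per patient, the concatenation over the `N - 5` windows of the window
#' means (continuous), the trichotomized differences, and the trichotomized
#' pair and triplet correlations — in total
#' `(N - 5) * (2M + choose(M, 2) + choose(M, 3))` features. Trichotomization
#' thresholds (one per statistic family, pooled over variables and windows)
#' are fitted on the training grids only and frozen for the other splits.
#'
#' @param grids list of [hourly_grid_impute()] dense grids.
#' @param train logical vector marking the training grids (thresholds are
#'   fitted there); ignored when `trichotomizers` is supplied.
#' @param window window length (default 6).
#' @param trichotomizers optional frozen thresholds (list with `diffs`,
#'   `pair`, `triplet`).
#' @return list with `X` (feature matrix, patients x features),
#'   `trichotomizers`, and `n_features`.
#' @export
build_feature_matrix <- function(grids, train = rep(TRUE, length(grids)),
                                 window = 6, trichotomizers = NULL) {
  M <- ncol(grids[[1]]$values)
  if (any(vapply(grids, function(g) ncol(g$values), integer(1)) != M))
    stop("inconsistent number of variables across patients")
  raw <- lapply(grids, insight_raw_features, window = window)
  if (is.null(trichotomizers)) {
    pool <- function(field)
      unlist(lapply(raw[train], function(r) as.numeric(r[[field]])))
    trichotomizers <- list(diffs = fit_trichotomizer(pool("diffs")),
                           pair = fit_trichotomizer(pool("pair")),
                           triplet = fit_trichotomizer(pool("triplet")))
  }
  X <- t(vapply(raw, function(r) {
    n_win <- nrow(r$means)
    as.numeric(t(cbind(
      r$means,
      matrix(trichotomize(trichotomizers$diffs, r$diffs), n_win),
      matrix(trichotomize(trichotomizers$pair, r$pair), n_win),
      matrix(trichotomize(trichotomizers$triplet, r$triplet), n_win)
    )))
  }, numeric((nrow(raw[[1]]$means)) *
               (2 * M + choose(M, 2) + choose(M, 3)))))
  list(X = X, trichotomizers = trichotomizers, n_features = ncol(X))
}

#' InSight inclusion filter
#'
#' Keeps only patients with at least one observation of every required
#' variable within the final window before prediction (statics such as age
#' count as always observed).
#'
#' @param records list of records.
#' @param required character vector of required variable names; defaults to
#'   the classic InSight roster (age, systolic blood pressure, pulse transit
#'   time, heart rate, temperature, respiration rate, white blood cell count,
#'   pH, pulse oximetry).
#' @param window_h width of the final window checked (default 6 h; set 5 for
#'   the stricter five-hour reading).
#' @return logical vector, `TRUE` for kept records.
#' @export
insight_inclusion_filter <- function(records,
                                     required = c("age", "sysbp", "ptt",
                                                  "heartrate", "tempc",
                                                  "resprate", "wbc",
                                                  "ph_bloodgas",
                                                  "spo2_pulsoxy"),
                                     window_h = 6) {
  vapply(records, function(r) {
    dyn <- setdiff(required, names(r$statics))
    if (!length(dyn)) return(TRUE)
    obs <- r$observations
    recent <- obs[obs$time_h > r$end_time - window_h, , drop = FALSE]
    all(dyn %in% unique(recent$feature))
  }, logical(1))
}

#' Ridge logistic regression
#'
#' L2-penalized logistic fit (via glmnet with `alpha = 0`, unstandardized,
#' fixed penalty); the linear scorer behind both the InSight feature matrix
#' and the flattened hourly-grid baseline.
#'
#' @param X feature matrix (patients x features).
#' @param y 0/1 labels.
#' @param penalty ridge penalty `lambda` (default 1e-3).
#' @return object of class `ridge_logistic` with the fitted glmnet object.
#' @export
fit_ridge_logistic <- function(X, y, penalty = 1e-3) {
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  p_orig <- ncol(X)
  if (p_orig < 2) X <- cbind(X, 0)   # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = penalty, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  structure(list(fit = fit, penalty = penalty, p_orig = p_orig),
            class = "ridge_logistic")
}

#' @rdname fit_ridge_logistic
#' @param object a `ridge_logistic` fit.
#' @param newx new feature matrix.
#' @param ... unused.
#' @return `predict`: case probabilities in `[0, 1]`.
#' @export
predict.ridge_logistic <- function(object, newx, ...) {
  if (object$p_orig < 2) newx <- cbind(newx, 0)
  as.numeric(stats::predict(object$fit, newx = newx, type = "response"))
}

# flatten dense grids (+statics) into the hourly-grid baseline design matrix
flatten_grids <- function(grids) {
  t(vapply(grids, function(g) c(as.numeric(g$values), as.numeric(g$statics)),
           numeric(length(grids[[1]]$values) + length(grids[[1]]$statics))))
}

#' Hourly-grid ridge logistic baseline
#'
#' Imputes every record onto the hourly grid, flattens window and statics
#' into one vector per patient, fits the ridge logistic regression on the
#' training split and scores another split.
#'
#' @param dataset dataset list (`records`, `split`, `roster`).
#' @param N window length.
#' @param penalty ridge penalty.
#' @param eval_split split to score (default `"test"`).
#' @return list with `scores`, `labels`, `auroc`, `aupr`, `fit`.
#' @export
grid_logreg_baseline <- function(dataset, N = 25, penalty = 1e-2,
                                 eval_split = "test") {
  grids <- lapply(dataset$records, hourly_grid_impute,
                  roster = dataset$roster, N = N)
  X <- flatten_grids(grids)
  y <- vapply(dataset$records, function(r) r$label, integer(1))
  tr <- dataset$split == "train"
  ev <- dataset$split == eval_split
  fit <- fit_ridge_logistic(X[tr, , drop = FALSE], y[tr], penalty)
  scores <- predict(fit, X[ev, , drop = FALSE])
  list(scores = scores, labels = y[ev],
       auroc = auroc(scores, y[ev]), aupr = aupr(scores, y[ev]), fit = fit)
}

#' InSight baseline on a dataset
#'
#' Hourly grids, window/correlation features with training-fitted
#' trichotomization, ridge logistic scorer.
#'
#' @inheritParams grid_logreg_baseline
#' @param window six-hour feature window.
#' @return list with `scores`, `labels`, `auroc`, `aupr`, `fit`,
#'   `n_features`.
#' @export
insight_baseline <- function(dataset, N = 25, window = 6, penalty = 1e-2,
                             eval_split = "test") {
  grids <- lapply(dataset$records, hourly_grid_impute,
                  roster = dataset$roster, N = N)
  y <- vapply(dataset$records, function(r) r$label, integer(1))
  tr <- dataset$split == "train"
  ev <- dataset$split == eval_split
  fm <- build_feature_matrix(grids, train = tr, window = window)
  fit <- fit_ridge_logistic(fm$X[tr, , drop = FALSE], y[tr], penalty)
  scores <- predict(fit, fm$X[ev, , drop = FALSE])
  list(scores = scores, labels = y[ev], auroc = auroc(scores, y[ev]),
       aupr = aupr(scores, y[ev]), fit = fit, n_features = fm$n_features)
}

#' MGP + logistic-regression ablation
#'
#' Replaces the AttTCN arm by a logistic regression: Monte Carlo samples are
#' drawn from the (fitted) posterior, flattened, averaged over samples, and
#' scored by the ridge logistic head.
#'
#' @param dataset dataset list.
#' @param mgp an [mgp_params()] (fitted or jointly trained).
#' @param S Monte Carlo samples per record.
#' @param seed integer seed.
#' @param N window length.
#' @param penalty ridge penalty.
#' @param eval_split split to score.
#' @return list with `scores`, `labels`, `auroc`, `aupr`, `fit`.
#' @export
mgp_logreg_baseline <- function(dataset, mgp, S = 4, seed = 1, N = 25,
                                penalty = 1e-2, eval_split = "test") {
  inputs <- prepare_inputs(dataset$records, dataset$roster)
  X <- with_seed(seed, t(vapply(inputs, function(inp) {
    t_grid <- as.numeric(-(N - 1):0)
    t_grid <- t_grid[t_grid >= -inp$end_time]
    cond <- mgp_condition(mgp, inp$ob$feat, inp$ob$t, inp$ob$y, t_grid)
    L <- chol_jitter(cond$Sigma, mgp$jitter, "posterior covariance")
    eta <- matrix(stats::rnorm(cond$G * S), cond$G, S)
    samp <- cond$mu + L %*% eta
    acc <- 0
    for (s in seq_len(S))
      acc <- acc + build_sample_matrix(samp[, s], length(t_grid), mgp$M, N,
                                       inp$statics) / S
    as.numeric(acc)
  }, numeric(N * (mgp$M + dataset$roster$Q)))))
  y <- vapply(dataset$records, function(r) r$label, integer(1))
  tr <- dataset$split == "train"
  ev <- dataset$split == eval_split
  fit <- fit_ridge_logistic(X[tr, , drop = FALSE], y[tr], penalty)
  scores <- predict(fit, X[ev, , drop = FALSE])
  list(scores = scores, labels = y[ev], auroc = auroc(scores, y[ev]),
       aupr = aupr(scores, y[ev]), fit = fit)
}
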