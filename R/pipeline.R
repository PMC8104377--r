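# Cohort construction: matching, truncation thresholds, horizon augmentation,
# splitting, normalization, and the baselines' hourly-grid imputation.
#
# "Data points" for the 40/250 thresholds counts individual observations
# across all features, matching the sparse-matrix framing of the records.

# truncate a record's observation window to [0, t_end]
truncate_record_to <- function(record, t_end) {
  keep <- record$observations$time_h <= t_end
  record$observations <- record$observations[keep, , drop = FALSE]
  rownames(record$observations) <- NULL
  record$end_time <- t_end
  record
}

#' Case-control matching with length truncation
#'
#' Sepsis onset tends to happen early in the ICU stay while controls stay
#' longer and end their records in good health, so both record length and
#' end-of-stay values would shortcut classification. Each case is therefore
#' matched (seeded, without replacement) to `floor(r)` or `ceil(r)` controls —
#' `r` being the control/case imbalance ratio, with the ceiling quotas
#' assigned to a seeded subset of cases so the totals are exact — and every
#' matched control is truncated to its case's admission-to-onset length.
#' Controls shorter than a candidate case are skipped for that case; controls
#' that fit no case are dropped with a message.
#'
#' @param cases records with an onset time (`end_time` = onset).
#' @param controls records (at least as many as cases).
#' @param seed integer seed.
#' @return list of records: cases unchanged, controls truncated, each control
#'   carrying the matched case id in attribute `"matched_case"`.
#' @export
match_case_control <- function(cases, controls, seed = 1) {
  stopifnot(length(cases) >= 1, length(controls) >= length(cases))
  for (cs in cases)
    if (is.na(cs$onset_time)) stop("every case needs an onset time")
  r <- length(controls) / length(cases)
  n_ceil <- length(controls) - length(cases) * floor(r)
  with_seed(seed, {
    quota <- rep(floor(r), length(cases))
    if (n_ceil > 0)
      quota[sample.int(length(cases), n_ceil)] <- ceiling(r)
    pool <- sample(seq_along(controls))   # shuffled candidate order
    used <- logical(length(controls))
    matched <- list()
    for (ci in seq_along(cases)) {
      len <- cases[[ci]]$onset_time
      taken <- 0
      for (pi in pool) {
        if (taken >= quota[ci]) break
        if (used[pi]) next
        ctrl <- controls[[pi]]
        if (ctrl$end_time < len) next   # too short for this case; re-draw
        used[pi] <- TRUE
        taken <- taken + 1
        tr <- truncate_record_to(ctrl, len)
        attr(tr, "matched_case") <- cases[[ci]]$patient_id
        matched[[length(matched) + 1]] <- tr
      }
    }
    if (any(!used))
      message(sum(!used), " control(s) not matched to any case (dropped)")
    c(cases, matched)
  })
}

#' Discard records with too few observations
#'
#' @param records list of records.
#' @param min_obs minimum total observation count (default 40); records with
#'   fewer are discarded, the boundary itself is kept.
#' @return filtered list.
#' @export
filter_min_observations <- function(records, min_obs = 40) {
  Filter(function(r) nrow(r$observations) >= min_obs, records)
}

#' Truncate a record to its last `max_points` observations
#'
#' For computational tractability long stays keep only the most recent
#' `max_points` observations: the earliest `N_p - max_points` observations in
#' global time order (ties broken by feature order) are removed.
#'
#' @param record a [patient_record()].
#' @param max_points maximum observation count (default 250).
#' @return the (possibly truncated) record.
#' @export
truncate_max_points <- function(record, max_points = 250) {
  obs <- record$observations
  n <- nrow(obs)
  if (n <= max_points) return(record)
  ord <- order(obs$time_h, obs$feature)
  keep <- sort(ord[(n - max_points + 1):n])
  record$observations <- obs[keep, , drop = FALSE]
  rownames(record$observations) <- NULL
  record
}

#' Horizon augmentation
#'
#' To train earlier prediction, each record is copied at horizons 1..6: the
#' horizon-`h` copy drops all observations in the final `h` hours and moves
#' the prediction time `h` hours earlier. Horizon 0 is the untruncated record.
#' Copies falling below `min_obs` observations are discarded, so per-horizon
#' copy counts are non-increasing in `h`.
#'
#' @param records list of records ending at onset (cases) or at the matched
#'   end (controls).
#' @param horizons integer horizons (default `0:6`).
#' @param min_obs minimum observation count per copy (default 40).
#' @return flat list of records with the `horizon` field set; each copy keeps
#'   its source patient id.
#' @export
horizon_augment <- function(records, horizons = 0:6, min_obs = 40) {
  out <- list()
  for (r in records) {
    for (h in horizons) {
      cp <- if (h == 0) r else truncate_record_to(r, r$end_time - h)
      cp$horizon <- as.integer(h)
      if (nrow(cp$observations) >= min_obs)
        out[[length(out) + 1]] <- cp
    }
  }
  out
}

#' Grouped train/validation/test split
#'
#' Splits by source patient id so all horizon copies of one patient share a
#' split and augmented copies can never leak across splits; `by_patient =
#' FALSE` splits each record (copy) independently instead, mimicking a
#' per-copy split.
#'
#' @param records list of records (possibly horizon-augmented).
#' @param fractions train/validation/test fractions summing to one.
#' @param seed integer seed.
#' @param by_patient group the split by source patient id (default).
#' @return character vector of `"train"`, `"val"`, `"test"` tags, one per
#'   record.
#' @export
split_cohort <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1,
                         by_patient = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  ids <- if (by_patient)
    vapply(records, function(r) r$patient_id, character(1))
  else as.character(seq_along(records))
  uids <- unique(ids)
  n <- length(uids)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_val <- min(n_val, n - n_train)
  with_seed(seed, {
    perm <- sample(uids)
    tag_by_id <- stats::setNames(
      rep(c("train", "val", "test"),
          c(n_train, n_val, n - n_train - n_val)), perm)
    unname(tag_by_id[ids])
  })
}

#' Normalize a split cohort
#'
#' Computes each dynamic feature's mean and population (divide-by-n) standard
#' deviation over the training-split observations only, and applies the
#' transformation to every split. The age static is z-scored with training
#' statistics as well; gender and the one-hot unit columns are left as coded.
#' A feature constant in training is centred only, with a warning.
#'
#' @param records list of records.
#' @param split split tags from [split_cohort()].
#' @param roster the [feature_roster()].
#' @param stats optional pre-computed statistics (to transform new data with
#'   frozen training statistics).
#' @return list with `records` (transformed) and `stats` (data.frame
#'   `feature, mean, sd`, plus age mean/sd as attributes).
#' @export
normalize_cohort <- function(records, split, roster, stats = NULL) {
  if (is.null(stats)) {
    train <- records[split == "train"]
    if (!length(train)) stop("no training records to compute statistics from")
    all_obs <- do.call(rbind, lapply(train, function(r) r$observations))
    stats <- do.call(rbind, lapply(roster$dynamic_features, function(f) {
      v <- all_obs$value[all_obs$feature == f]
      if (!length(v)) return(data.frame(feature = f, mean = 0, sd = 1))
      m <- mean(v)
      s <- sqrt(mean((v - m)^2))
      if (s == 0) {
        warning("feature ", f, " constant in training; centred only")
        s <- 1
      }
      data.frame(feature = f, mean = m, sd = s)
    }))
    ages <- vapply(train, function(r) r$statics[["age"]], numeric(1))
    attr(stats, "age_mean") <- mean(ages)
    attr(stats, "age_sd") <- max(sqrt(mean((ages - mean(ages))^2)), 1e-12)
  }
  lookup_m <- stats::setNames(stats$mean, stats$feature)
  lookup_s <- stats::setNames(stats$sd, stats$feature)
  out <- lapply(records, function(r) {
    f <- r$observations$feature
    r$observations$value <-
      (r$observations$value - lookup_m[f]) / lookup_s[f]
    r$statics[["age"]] <-
      (r$statics[["age"]] - attr(stats, "age_mean")) / attr(stats, "age_sd")
    r
  })
  attributes(out) <- attributes(records)
  list(records = out, stats = stats)
}

#' Hourly-grid forward imputation
#'
#' The baselines' discretization: per hour and feature, the mean of that
#' hour's observations; hours without observations carry the previous hour's
#' value forward; hours before the first observation are zero. The matrix is
#' end-aligned to the prediction time and left zero-padded (or left-truncated)
#' to `N` columns; a mask marks the padded prefix.
#'
#' @param record a (normalized) [patient_record()].
#' @param roster the [feature_roster()].
#' @param N window length (default 25).
#' @return object of class `dense_grid`: `values` (`N x M`, rows = hours,
#'   end-aligned), `statics`, `mask` (logical length `N`, `TRUE` = padded),
#'   `label`, `horizon`, `patient_id`.
#' @export
hourly_grid_impute <- function(record, roster, N = 25) {
  M <- roster$M
  n_hours <- max(1L, ceiling(record$end_time))
  H <- matrix(0, n_hours, M)
  obs <- record$observations
  if (nrow(obs)) {
    feat <- match(obs$feature, roster$dynamic_features)
    hr <- pmin(floor(obs$time_h), n_hours - 1) + 1
    for (k in seq_len(M)) {
      sel <- feat == k
      if (!any(sel)) next
      means <- tapply(obs$value[sel], hr[sel], mean)
      col <- rep(NA_real_, n_hours)
      col[as.integer(names(means))] <- as.numeric(means)
      # carry forward; hours before the first observation stay zero
      last <- 0
      seen <- FALSE
      for (h in seq_len(n_hours)) {
        if (!is.na(col[h])) { last <- col[h]; seen <- TRUE }
        else col[h] <- if (seen) last else 0
      }
      H[, k] <- col
    }
  }
  if (n_hours >= N) {
    values <- H[(n_hours - N + 1):n_hours, , drop = FALSE]
    mask <- rep(FALSE, N)
  } else {
    values <- rbind(matrix(0, N - n_hours, M), H)
    mask <- c(rep(TRUE, N - n_hours), rep(FALSE, n_hours))
  }
  structure(list(values = values, statics = record$statics, mask = mask,
                 label = record$label, horizon = record$horizon,
                 patient_id = record$patient_id),
            class = "dense_grid")
}

#' Build a model-ready horizon dataset
#'
#' Full pipeline from labelled records to a split, normalized, horizon-
#' augmented dataset: case-control matching, the minimum-observation filter,
#' the maximum-point truncation, horizon augmentation, the grouped split, and
#' training-statistics normalization. Deterministic given `(records, seed)`.
#'
#' @param cases,controls labelled records (cases end at onset).
#' @param roster the [feature_roster()].
#' @param horizons horizons to augment over (default `0:6`; use `0` to skip
#'   augmentation).
#' @param min_obs,max_points the 40 / 250 observation thresholds.
#' @param fractions split fractions.
#' @param seed integer seed driving matching and splitting.
#' @return list with `records`, `split`, `stats`, `roster`, `horizons`.
#' @export
build_horizon_dataset <- function(cases, controls, roster, horizons = 0:6,
                                  min_obs = 40, max_points = 250,
                                  fractions = c(0.8, 0.1, 0.1), seed = 1) {
  matched <- match_case_control(cases, controls, seed = derive_seed(seed, 11))
  matched <- filter_min_observations(matched, min_obs)
  matched <- lapply(matched, truncate_max_points, max_points = max_points)
  aug <- horizon_augment(matched, horizons = horizons, min_obs = min_obs)
  split <- split_cohort(aug, fractions, seed = derive_seed(seed, 12))
  norm <- normalize_cohort(aug, split, roster)
  list(records = norm$records, split = split, stats = norm$stats,
       roster = roster, horizons = horizons)
}
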