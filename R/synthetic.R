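#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the model assumes: a
#' zero-mean multitask Gaussian process over two smoothness clusters (noisy,
#' frequently sampled "vitals" with a short lengthscale; smooth, sparsely
#' sampled "labs" with a long one), cross-feature correlation through two
#' free-form feature covariances, per-feature observation noise, and a label
#' mechanism that is logistic in the mean of designated signal features over
#' the final hours of the record, so earlier prediction horizons are harder.
#'
#' @param n_vitals,n_labs number of features per cluster (default 5 + 5).
#' @param lengthscales true Ornstein-Uhlenbeck lengthscales in hours, short
#'   (vitals) then long (labs); default `c(2, 64)`.
#' @param noise_sd per-feature observation noise standard deviations; default
#'   0.5 for vitals, 0.1 for labs.
#' @param rates per-feature observation rates in events/hour; default 1 for
#'   vitals and 1/12 for labs.
#' @param record_length_range record length drawn uniformly from this range
#'   (hours); default 24--72 h.
#' @param signal_features names of the two features whose latent mean over the
#'   final `signal_window_h` hours drives the label.
#' @param label_weights coefficient vector `w` on the signal means.
#' @param intercept fixed logistic intercept `b`; if `NULL` (default) the
#'   intercept is calibrated so the mean event probability over the generated
#'   cohort equals `target_prevalence`.
#' @param target_prevalence desired case fraction used for calibration.
#' @param signal_window_h width of the label window in hours (default 6).
#' @param latent_grid_h resolution of the dense latent grid (default 0.25 h);
#'   observation times snap to this grid.
#' @param factor_seed seed fixing the ground-truth feature covariances.
#' @return an object of class `synthetic_config`. Ground-truth feature
#'   covariances are stored as lower-triangular factors `F` with
#'   `K = F %*% t(F)`, one per smoothness cluster.
#' @export
synthetic_config <- function(n_vitals = 5, n_labs = 5,
                             lengthscales = c(2, 64),
                             noise_sd = NULL, rates = NULL,
                             record_length_range = c(24, 72),
                             signal_features = c("vital_1", "lab_1"),
                             label_weights = c(3, 3),
                             intercept = NULL,
                             target_prevalence = 0.4,
                             signal_window_h = 6,
                             latent_grid_h = 0.25,
                             factor_seed = 20260101) {
  M <- n_vitals + n_labs
  roster <- synthetic_roster(n_vitals, n_labs)
  if (is.null(noise_sd))
    noise_sd <- c(rep(0.5, n_vitals), rep(0.1, n_labs))
  if (is.null(rates))
    rates <- c(rep(1, n_vitals), rep(1 / 12, n_labs))
  stopifnot(length(noise_sd) == M, length(rates) == M,
            all(rates >= 0), all(noise_sd >= 0),
            all(lengthscales > 0), length(lengthscales) == 2,
            target_prevalence > 0, target_prevalence < 1)
  # ground-truth covariance factors: cluster l puts most of its variance on
  # its own features, with mild random cross-feature loading
  factors <- with_seed(factor_seed, {
    lapply(1:2, function(l) {
      d <- if (l == 1) c(rep(1, n_vitals), rep(0.2, n_labs))
           else c(rep(0.2, n_vitals), rep(1, n_labs))
      Fm <- matrix(stats::rnorm(M * M, sd = 0.12), M, M)
      Fm[upper.tri(Fm)] <- 0
      diag(Fm) <- d
      Fm
    })
  })
  names(noise_sd) <- roster$dynamic_features
  names(rates) <- roster$dynamic_features
  structure(list(
    roster = roster, M = M, lengthscales = lengthscales,
    factors = factors, noise_sd = noise_sd, rates = rates,
    record_length_range = record_length_range,
    signal_features = signal_features, label_weights = label_weights,
    intercept = intercept, target_prevalence = target_prevalence,
    signal_window_h = signal_window_h, latent_grid_h = latent_grid_h
  ), class = "synthetic_config")
}

#' Draw dense latent trajectories
#'
#' Samples, for each patient, a dense multivariate path from the zero-mean
#' Gaussian process with covariance `sum_l K_l otimes OU(lambda_l)` on a
#' regular fine grid, using the Kronecker structure (one small Cholesky per
#' cluster in feature space and one in time) so the cost is far below a joint
#' factorization.
#'
#' @param config a [synthetic_config()].
#' @param n_patients number of patients.
#' @param seed integer seed; the same seed reproduces identical paths.
#' @param record_lengths optional numeric vector of record lengths (hours);
#'   drawn from `config$record_length_range` when `NULL`.
#' @return list with one element per patient: `times` (dense grid) and
#'   `values` (matrix `length(times) x M`).
#' @export
sample_latent_paths <- function(config, n_patients, seed,
                                record_lengths = NULL) {
  M <- config$M
  K <- lapply(config$factors, tcrossprod)
  for (Kk in K) {
    ev <- min(eigen(Kk, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) stop("configured feature covariance is not PSD")
  }
  Fk <- config$factors
  with_seed(seed, {
    if (is.null(record_lengths))
      record_lengths <- stats::runif(n_patients, config$record_length_range[1],
                                     config$record_length_range[2])
    lapply(seq_len(n_patients), function(p) {
      times <- seq(0, record_lengths[p], by = config$latent_grid_h)
      nt <- length(times)
      Y <- matrix(0, nt, M)
      for (l in 1:2) {
        Tt <- ou_kernel(times, lengthscale = config$lengthscales[l])
        Bt <- chol_jitter(Tt, 1e-9, "latent time kernel")
        Z <- matrix(stats::rnorm(M * nt), M, nt)
        # vec covariance (K_l ox T_l): Y_l = B_t Z^T F_l^T has the right law
        Y <- Y + Bt %*% t(Z) %*% t(Fk[[l]])
      }
      list(times = times, values = Y, length_h = record_lengths[p])
    })
  })
}

#' Thin latent paths to irregular observations
#'
#' Observation times per feature follow a homogeneous point process at the
#' feature's cluster rate, realized on the dense latent grid (distinct grid
#' slots, count Poisson-distributed); observed values are the latent values
#' plus independent Gaussian noise.
#'
#' @param paths output of [sample_latent_paths()].
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list of [patient_record()]s (unlabelled), roster attached.
#' @export
thin_to_observations <- function(paths, config, seed) {
  roster <- config$roster
  with_seed(seed, {
    records <- lapply(seq_along(paths), function(p) {
      path <- paths[[p]]
      nt <- length(path$times)
      obs <- list()
      for (k in seq_len(config$M)) {
        rate <- config$rates[k]
        if (rate <= 0) next
        n_obs <- stats::rpois(1, rate * path$length_h)
        n_obs <- min(n_obs, nt)
        if (n_obs == 0) next
        idx <- sort(sample.int(nt, n_obs))
        obs[[length(obs) + 1]] <- data.frame(
          feature = roster$dynamic_features[k],
          time_h = path$times[idx],
          value = path$values[idx, k] +
            stats::rnorm(n_obs, sd = config$noise_sd[k])
        )
      }
      obs <- if (length(obs)) do.call(rbind, obs)
             else data.frame(feature = character(0), time_h = numeric(0),
                             value = numeric(0))
      statics <- encode_statics(
        age = stats::runif(1, 18, 90),
        gender = stats::rbinom(1, 1, 0.5),
        unit = sample(roster$units, 1),
        roster
      )
      patient_record(sprintf("synth_%04d", p), obs, statics,
                     end_time = path$length_h)
    })
    attr(records, "roster") <- roster
    records
  })
}

#' Assign labels from the latent process
#'
#' The event probability is `plogis(w . phi + b)` where `phi` is the mean of
#' the latent signal features over the final `signal_window_h` hours. When the
#' config's intercept is `NULL`, `b` is calibrated by root finding so the mean
#' event probability equals the target prevalence. Cases receive an onset time
#' at the record end.
#'
#' @param records records from [thin_to_observations()].
#' @param paths the matching latent paths.
#' @param config a [synthetic_config()].
#' @param seed integer seed for the Bernoulli draws.
#' @return the records with `label` and (for cases) `onset_time` filled in;
#'   the linear scores and probabilities are attached as attributes
#'   `"score"` and `"prob"` for diagnostics.
#' @export
assign_labels <- function(records, paths, config, seed) {
  idx <- match(config$signal_features, config$roster$dynamic_features)
  if (anyNA(idx)) stop("signal features not in roster")
  phi <- t(vapply(paths, function(path) {
    keep <- path$times >= path$length_h - config$signal_window_h
    colMeans(path$values[keep, idx, drop = FALSE])
  }, numeric(length(idx))))
  score <- as.numeric(phi %*% config$label_weights)
  b <- config$intercept
  if (is.null(b)) {
    target <- config$target_prevalence
    b <- stats::uniroot(function(bb) mean(stats::plogis(score + bb)) - target,
                        interval = c(-50, 50))$root
  }
  prob <- stats::plogis(score + b)
  labels <- with_seed(seed, stats::rbinom(length(records), 1, prob))
  out <- lapply(seq_along(records), function(p) {
    r <- records[[p]]
    r$label <- as.integer(labels[p])
    r$onset_time <- if (labels[p] == 1) r$end_time else NA_real_
    r
  })
  attributes(out) <- attributes(records)
  attr(out, "score") <- score
  attr(out, "prob") <- prob
  attr(out, "intercept") <- b
  out
}

#' Generate a labelled synthetic cohort
#'
#' Convenience wrapper: latent paths, thinning to irregular observations, and
#' label assignment, each with a seed derived from `seed`.
#'
#' @param config a [synthetic_config()].
#' @param n_patients cohort size.
#' @param seed integer master seed.
#' @return list of labelled [patient_record()]s with the roster and the
#'   generating scores attached as attributes.
#' @export
generate_cohort <- function(config, n_patients, seed) {
  paths <- sample_latent_paths(config, n_patients, derive_seed(seed, 1))
  records <- thin_to_observations(paths, config, derive_seed(seed, 2))
  assign_labels(records, paths, config, derive_seed(seed, 3))
}

#' Scripted event-table fixtures with known ground truth
#'
#' Builds an event table from a fixed set of scripted scenarios (antibiotics
#' without culture, a qualifying suspicion pair with a SOFA rise inside the
#' window, a rise outside every window, an isolated liver-failure pattern with
#' all other organ systems unmeasured, under-age and ICD-flagged patients...),
#' together with a sidecar table stating the intended class and onset under
#' both missing-contributor policies. The sidecar is written by the scenario
#' script, not by the labeller, so it can serve as an independent reference.
#'
#' @param n_patients number of patients; scenarios are cycled.
#' @param seed reserved for interface stability; the scenarios are scripted
#'   and deterministic.
#' @return list with `events` (an [event_table()]) and `truth` (data.frame
#'   with `patient_id`, `scenario`, `class_healthy_zero`, `onset_healthy_zero`,
#'   `class_undefined`, `onset_undefined`).
#' @export
generate_event_fixtures <- function(n_patients = 8, seed = 1) {
  scenarios <- c("abx_only", "pair_rise_inside", "rise_outside_window",
                 "liver_only", "no_events", "under_age", "icd_control",
                 "culture_too_late")
  abx <- list(); cult <- list(); sofa <- list(); pats <- list()
  truth <- list()
  all_systems <- c("respiration", "coagulation", "liver", "cardiovascular",
                   "cns", "renal")
  for (p in seq_len(n_patients)) {
    sc <- scenarios[(p - 1) %% length(scenarios) + 1]
    id <- sprintf("fix_%03d", p)
    age <- 50; icd <- 0L
    add_sofa <- function(time_h, system, score)
      sofa[[length(sofa) + 1]] <<- data.frame(patient_id = id, time_h = time_h,
                                              system = system, score = score)
    if (sc == "abx_only") {
      abx[[length(abx) + 1]] <- data.frame(patient_id = id, time_h = 10)
      add_sofa(2, "respiration", 1); add_sofa(14, "respiration", 3)
      truth[[p]] <- c("control", NA, "control", NA)
    } else if (sc == "pair_rise_inside") {
      abx[[length(abx) + 1]] <- data.frame(patient_id = id, time_h = 10)
      cult[[length(cult) + 1]] <- data.frame(patient_id = id, time_h = 11)
      for (s in all_systems) add_sofa(0, s, 0)
      add_sofa(14, "respiration", 2)
      # suspicion at 10, window [0, 34]; total rises 0 -> 2 at hour 14
      truth[[p]] <- c("case", 14, "case", 14)
    } else if (sc == "rise_outside_window") {
      cult[[length(cult) + 1]] <- data.frame(patient_id = id, time_h = 60)
      abx[[length(abx) + 1]] <- data.frame(patient_id = id, time_h = 70)
      for (s in all_systems) add_sofa(0, s, 0)
      add_sofa(5, "respiration", 2)     # rise long before window [12, 84]
      # re-measurements keep every sub-score alive (carry-forward is 24 h),
      # so the total stays constant at 2 inside the window: control
      for (tt in c(20, 40, 60, 80))
        for (s in all_systems)
          add_sofa(tt, s, if (s == "respiration") 2L else 0L)
      truth[[p]] <- c("control", NA, "control", NA)
    } else if (sc == "liver_only") {
      abx[[length(abx) + 1]] <- data.frame(patient_id = id, time_h = 5)
      cult[[length(cult) + 1]] <- data.frame(patient_id = id, time_h = 6)
      add_sofa(1, "liver", 0); add_sofa(10, "liver", 2)
      # healthy-zero: total 0 -> 2 at hour 10 inside window [0, 29] => case;
      # undefined: five systems never measured => total undefined => control
      truth[[p]] <- c("case", 10, "control", NA)
    } else if (sc == "no_events") {
      truth[[p]] <- c("control", NA, "control", NA)
    } else if (sc == "under_age") {
      age <- 12
      abx[[length(abx) + 1]] <- data.frame(patient_id = id, time_h = 10)
      cult[[length(cult) + 1]] <- data.frame(patient_id = id, time_h = 11)
      for (s in all_systems) add_sofa(0, s, 0)
      add_sofa(14, "respiration", 2)
      truth[[p]] <- c("excluded", NA, "excluded", NA)
    } else if (sc == "icd_control") {
      icd <- 1L
      truth[[p]] <- c("excluded", NA, "excluded", NA)
    } else if (sc == "culture_too_late") {
      abx[[length(abx) + 1]] <- data.frame(patient_id = id, time_h = 10)
      cult[[length(cult) + 1]] <- data.frame(patient_id = id, time_h = 40)
      for (s in all_systems) add_sofa(0, s, 0)
      add_sofa(20, "respiration", 2)
      truth[[p]] <- c("control", NA, "control", NA)
    }
    pats[[p]] <- data.frame(patient_id = id, age = age, icd_sepsis = icd,
                            icu_in_h = 0, icu_out_h = 100)
    truth[[p]] <- data.frame(patient_id = id, scenario = sc,
                             class_healthy_zero = truth[[p]][1],
                             onset_healthy_zero = as.numeric(truth[[p]][2]),
                             class_undefined = truth[[p]][3],
                             onset_undefined = as.numeric(truth[[p]][4]))
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  ev <- event_table(
    antibiotics = bind(abx, data.frame(patient_id = character(0), time_h = numeric(0))),
    cultures = bind(cult, data.frame(patient_id = character(0), time_h = numeric(0))),
    sofa = bind(sofa, data.frame(patient_id = character(0), time_h = numeric(0),
                                 system = character(0), score = integer(0))),
    patients = do.call(rbind, pats)
  )
  list(events = ev, truth = do.call(rbind, truth))
}
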