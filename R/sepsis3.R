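#' Event tables for Sepsis-3 labelling
#'
#' Container for the per-patient event streams the labeller consumes:
#' antibiotic administrations, blood-culture draws, timestamped SOFA organ
#' sub-scores, and per-patient metadata (age, ICD sepsis discharge flag, ICU
#' stay interval).
#'
#' @param antibiotics data.frame `patient_id, time_h`.
#' @param cultures data.frame `patient_id, time_h`.
#' @param sofa data.frame `patient_id, time_h, system, score` with `system`
#'   one of respiration, coagulation, liver, cardiovascular, cns, renal and
#'   `score` in 0..4.
#' @param patients data.frame `patient_id, age, icd_sepsis, icu_in_h, icu_out_h`.
#' @return an object of class `event_table`.
#' @export
event_table <- function(antibiotics, cultures, sofa, patients) {
  systems <- sofa_systems()
  if (nrow(sofa)) {
    if (!all(sofa$system %in% systems))
      stop("unknown SOFA system: ",
           paste(setdiff(unique(sofa$system), systems), collapse = ", "))
    if (!all(sofa$score %in% 0:4))
      stop("SOFA sub-scores must be integers in 0..4")
  }
  for (tab in list(antibiotics, cultures, sofa))
    if (nrow(tab) && any(tab$time_h < 0)) stop("event times must be >= 0")
  structure(list(antibiotics = antibiotics, cultures = cultures,
                 sofa = sofa, patients = patients),
            class = "event_table")
}

#' The six SOFA organ systems
#' @return character vector of system names.
#' @export
sofa_systems <- function() {
  c("respiration", "coagulation", "liver", "cardiovascular", "cns", "renal")
}

#' Suspected-infection windows
#'
#' A suspicion of infection is the co-occurrence of a broad-spectrum
#' antibiotic administration and a blood-culture draw within a set interval:
#' antibiotics up to `abx_after_culture_h` hours after a culture, or a culture
#' up to `culture_after_abx_h` hours after antibiotics. The suspicion time is
#' the earlier event of the qualifying pair and expands to the window
#' `[t - lookback_h, t + lookforward_h]`; overlapping windows are merged.
#' The interval constants follow the conventional Sepsis-3 implementation and
#' are exposed as configuration.
#'
#' @param events an [event_table()].
#' @param abx_after_culture_h,culture_after_abx_h pairing interval limits (h).
#' @param lookback_h,lookforward_h window expansion around the suspicion time.
#' @return data.frame `patient_id, start_h, end_h`, one row per merged window.
#' @export
suspicion_windows <- function(events, abx_after_culture_h = 72,
                              culture_after_abx_h = 24,
                              lookback_h = 48, lookforward_h = 24) {
  if (any(c(abx_after_culture_h, culture_after_abx_h,
            lookback_h, lookforward_h) < 0))
    stop("interval parameters must be non-negative")
  ids <- unique(c(events$antibiotics$patient_id, events$cultures$patient_id))
  out <- lapply(ids, function(id) {
    ta <- sort(events$antibiotics$time_h[events$antibiotics$patient_id == id])
    tc <- sort(events$cultures$time_h[events$cultures$patient_id == id])
    if (!length(ta) || !length(tc)) return(NULL)
    susp <- c()
    for (a in ta) for (cc in tc) {
      qualifies <- (a >= cc && a - cc <= abx_after_culture_h) ||
                   (cc >= a && cc - a <= culture_after_abx_h)
      if (qualifies) susp <- c(susp, min(a, cc))
    }
    if (!length(susp)) return(NULL)
    susp <- sort(unique(susp))
    win <- data.frame(start_h = pmax(0, susp - lookback_h),
                      end_h = susp + lookforward_h)
    # merge overlaps
    merged <- win[1, ]
    if (nrow(win) > 1) {
      for (i in 2:nrow(win)) {
        last <- nrow(merged)
        if (win$start_h[i] <= merged$end_h[last]) {
          merged$end_h[last] <- max(merged$end_h[last], win$end_h[i])
        } else merged <- rbind(merged, win[i, ])
      }
    }
    cbind(patient_id = id, merged)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), start_h = numeric(0),
                      end_h = numeric(0))
  rownames(out) <- NULL
  out
}

#' Hourly SOFA timeline for one patient
#'
#' Builds the hourly total SOFA score from timestamped sub-scores. Measured
#' sub-scores are carried forward for `carry_forward_h` hours. Under the
#' `healthy_zero` policy an unmeasured organ system is assumed within the
#' healthy norm and contributes zero; under the `undefined` policy (the
#' behaviour of the comparison labels) any hour with at least one unmeasured
#' system yields an undefined (`NA`) total.
#'
#' @param sofa data.frame `time_h, system, score` for one patient.
#' @param t_max timeline end (hours); the grid is `0:floor(t_max)`.
#' @param missing_policy `"healthy_zero"` or `"undefined"`.
#' @param carry_forward_h validity horizon of a measurement (default 24 h).
#' @return object of class `sofa_timeline`: list with `hours`, `total`
#'   (integer, `NA` where undefined) and `sub` (matrix hours x systems).
#' @export
sofa_timeline <- function(sofa, t_max,
                          missing_policy = c("healthy_zero", "undefined"),
                          carry_forward_h = 24) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(sofa) && !all(sofa$score %in% 0:4))
    stop("SOFA sub-scores must be integers in 0..4")
  hours <- 0:floor(t_max)
  systems <- sofa_systems()
  sub <- matrix(NA_integer_, length(hours), length(systems),
                dimnames = list(NULL, systems))
  for (s in systems) {
    m <- sofa[sofa$system == s, , drop = FALSE]
    if (!nrow(m)) next
    m <- m[order(m$time_h), , drop = FALSE]
    for (h in seq_along(hours)) {
      valid <- m$time_h <= hours[h] & m$time_h > hours[h] - carry_forward_h
      if (any(valid)) sub[h, s] <- m$score[max(which(valid))]
    }
  }
  if (missing_policy == "healthy_zero") {
    filled <- sub
    filled[is.na(filled)] <- 0L
    total <- as.integer(rowSums(filled))
  } else {
    total <- ifelse(rowSums(is.na(sub)) > 0, NA_integer_,
                    as.integer(rowSums(sub)))
  }
  structure(list(hours = hours, total = total, sub = sub,
                 policy = missing_policy),
            class = "sofa_timeline")
}

#' Assign sepsis onset from a SOFA timeline and suspicion windows
#'
#' Sepsis onset is the earliest hour inside any suspected-infection window at
#' which the total SOFA score has risen by at least two points above the
#' running minimum of the total since the window start. Hours with an
#' undefined total (under the `undefined` policy) are skipped: they neither
#' update the baseline nor can host an onset.
#'
#' @param timeline a [sofa_timeline()].
#' @param windows data.frame with `start_h`, `end_h` (one patient's windows).
#' @param rise minimum SOFA increase (default 2).
#' @param baseline `"running_min"` (default) or `"window_start"`.
#' @return list `class` (`"case"` or `"control"`) and `onset_time` (`NA` for
#'   controls).
#' @export
assign_onset <- function(timeline, windows, rise = 2,
                         baseline = c("running_min", "window_start")) {
  baseline <- match.arg(baseline)
  if (!nrow(windows)) return(list(class = "control", onset_time = NA_real_))
  for (w in seq_len(nrow(windows))) {
    inwin <- which(timeline$hours >= windows$start_h[w] &
                   timeline$hours <= windows$end_h[w])
    base <- Inf
    for (h in inwin) {
      tot <- timeline$total[h]
      if (is.na(tot)) next
      if (is.infinite(base)) base <- tot      # first defined hour in window
      if (baseline == "running_min") base <- min(base, tot)
      if (tot >= base + rise)
        return(list(class = "case", onset_time = timeline$hours[h]))
    }
  }
  list(class = "control", onset_time = NA_real_)
}

#' Apply inclusion and exclusion rules
#'
#' Patients aged 14 or younger are excluded; patients with a missing age are
#' excluded as invalid records; controls carrying an ICD sepsis discharge code
#' are excluded; a case requires an onset inside the ICU stay interval (an
#' onset outside the stay reverts the patient to control status before the
#' ICD check).
#'
#' @param events an [event_table()] (for age, ICD flag and stay interval).
#' @param labels data.frame `patient_id, class, onset_time` from the labeller.
#' @param min_age_years inclusion threshold; patients must be strictly older.
#' @return data.frame `patient_id, class, onset_time, exclusion_reason`.
#' @export
classify_patients <- function(events, labels, min_age_years = 14) {
  pats <- events$patients
  out <- merge(labels, pats, by = "patient_id", all.x = TRUE, sort = TRUE)
  out$exclusion_reason <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (is.na(out$age[i])) {
      out$class[i] <- "excluded"; out$onset_time[i] <- NA_real_
      out$exclusion_reason[i] <- "invalid record"
      next
    }
    if (out$age[i] <= min_age_years) {
      out$class[i] <- "excluded"; out$onset_time[i] <- NA_real_
      out$exclusion_reason[i] <- "age"
      next
    }
    if (out$class[i] == "case" &&
        (out$onset_time[i] < out$icu_in_h[i] ||
         out$onset_time[i] > out$icu_out_h[i])) {
      out$class[i] <- "control"; out$onset_time[i] <- NA_real_
    }
    if (out$class[i] == "control" && !is.na(out$icd_sepsis[i]) &&
        out$icd_sepsis[i] == 1) {
      out$class[i] <- "excluded"
      out$exclusion_reason[i] <- "ICD sepsis code without in-stay onset"
    }
  }
  out[, c("patient_id", "class", "onset_time", "exclusion_reason")]
}

#' Label a whole cohort under the Sepsis-3 rules
#'
#' Runs [suspicion_windows()], [sofa_timeline()] and [assign_onset()] per
#' patient, then [classify_patients()].
#'
#' @param events an [event_table()].
#' @param missing_policy `"healthy_zero"` (assume unmeasured organ systems
#'   healthy) or `"undefined"`.
#' @param ... passed to [suspicion_windows()].
#' @param carry_forward_h,rise,baseline,min_age_years see the stage functions.
#' @return data.frame `patient_id, class, onset_time, exclusion_reason`.
#' @export
label_cohort <- function(events, missing_policy = "healthy_zero",
                         carry_forward_h = 24, rise = 2,
                         baseline = "running_min", min_age_years = 14, ...) {
  wins <- suspicion_windows(events, ...)
  labs <- lapply(seq_len(nrow(events$patients)), function(i) {
    id <- events$patients$patient_id[i]
    tl <- sofa_timeline(events$sofa[events$sofa$patient_id == id, , drop = FALSE],
                        t_max = events$patients$icu_out_h[i],
                        missing_policy = missing_policy,
                        carry_forward_h = carry_forward_h)
    res <- assign_onset(tl, wins[wins$patient_id == id, , drop = FALSE],
                        rise = rise, baseline = baseline)
    data.frame(patient_id = id, class = res$class, onset_time = res$onset_time)
  })
  classify_patients(events, do.call(rbind, labs), min_age_years = min_age_years)
}
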