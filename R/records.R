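#' Irregular patient records
#'
#' A `patient_record` is the compact representation of one ICU encounter:
#' a set of `(feature, time, value)` observations at irregular times (hours
#' from admission), an encoded static vector, an optional binary sepsis label,
#' an optional onset time, an optional horizon tag, and the end of the
#' observation window (`end_time`, the prediction time for model-facing
#' records).
#'
#' @param patient_id scalar identifier (coerced to character).
#' @param observations data.frame with columns `feature` (character),
#'   `time_h` (numeric, hours from admission) and `value` (numeric).
#' @param statics named numeric vector of encoded statics (length `Q`).
#' @param label 0, 1 or `NA`.
#' @param onset_time onset in hours from admission, or `NA`.
#' @param horizon integer horizon-to-onset tag in `0..6`, or `NA`.
#' @param end_time end of the observation window in hours from admission;
#'   defaults to the last observation time.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, observations, statics,
                           label = NA_integer_, onset_time = NA_real_,
                           horizon = NA_integer_, end_time = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("feature", "time_h", "value") %in% names(observations)))
  obs <- observations[order(observations$feature, observations$time_h), ,
                      drop = FALSE]
  rownames(obs) <- NULL
  obs$feature <- as.character(obs$feature)
  if (is.null(end_time)) {
    end_time <- if (nrow(obs)) max(obs$time_h) else 0
  }
  structure(list(
    patient_id = as.character(patient_id),
    observations = obs,
    statics = statics,
    label = if (is.na(label)) NA_integer_ else as.integer(label),
    onset_time = as.numeric(onset_time),
    horizon = if (is.na(horizon)) NA_integer_ else as.integer(horizon),
    end_time = as.numeric(end_time)
  ), class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> %d obs over %d features, end %.1f h, label %s\n",
              x$patient_id, nrow(x$observations),
              length(unique(x$observations$feature)), x$end_time,
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Validate a patient record against a roster
#'
#' Checks the record invariants and returns the violations as a character
#' vector (empty when the record is valid). Nothing is raised, so the function
#' can be used for both filtering and reporting.
#'
#' @param record a [patient_record()].
#' @param roster a [feature_roster()].
#' @param require_label check that a 0/1 label is present (model-ready records).
#' @return character vector of human-readable violations; `character(0)` if valid.
#' @export
validate_record <- function(record, roster, require_label = FALSE) {
  v <- character(0)
  obs <- record$observations
  if (nrow(obs) < 1) v <- c(v, "record has no observations")
  bad_t <- !is.finite(obs$time_h) | obs$time_h < 0
  if (any(bad_t))
    v <- c(v, sprintf("observation %d: time %s is not finite and >= 0",
                      which(bad_t)[1], format(obs$time_h[which(bad_t)[1]])))
  unknown <- setdiff(unique(obs$feature), roster$dynamic_features)
  if (length(unknown))
    v <- c(v, paste0("feature outside roster: ", paste(unknown, collapse = ", ")))
  if (length(record$statics) != roster$Q)
    v <- c(v, sprintf("statics length %d != Q = %d",
                      length(record$statics), roster$Q))
  if (!is.na(record$label) && !record$label %in% c(0L, 1L))
    v <- c(v, "label must be 0, 1 or NA")
  if (require_label && is.na(record$label))
    v <- c(v, "model-ready record lacks a label")
  if (!is.na(record$horizon) && !(record$horizon %in% 0:6))
    v <- c(v, "horizon must be in 0..6")
  if (any(!is.finite(obs$value)))
    v <- c(v, "non-finite observation value")
  v
}

#' Read a cohort from disk
#'
#' The on-disk layout is a directory holding a long-format `observations.csv`
#' (`patient_id, feature, time_h, value`), a wide `statics.csv`
#' (`patient_id, age, gender, unit`) and an optional `labels.csv`
#' (`patient_id, label, onset_time, horizon, end_time`).
#'
#' @param path directory containing the cohort tables.
#' @param roster a [feature_roster()]; observations with features outside the
#'   roster are rejected with an error naming the offending feature.
#' @return list of [patient_record()]s with the roster attached as an
#'   attribute, sorted by patient id.
#' @export
read_cohort <- function(path, roster) {
  obs_file <- file.path(path, "observations.csv")
  st_file <- file.path(path, "statics.csv")
  if (!file.exists(obs_file)) stop("missing observations table: ", obs_file)
  if (!file.exists(st_file)) stop("missing statics table: ", st_file)
  obs <- data.table::fread(obs_file, colClasses = list(character = "patient_id"),
                           data.table = FALSE)
  need <- c("patient_id", "feature", "time_h", "value")
  if (!all(need %in% names(obs)))
    stop("observations table lacks required columns: ",
         paste(setdiff(need, names(obs)), collapse = ", "))
  if (nrow(obs)) {
    for (col in c("time_h", "value")) {
      x <- obs[[col]]
      if (!is.numeric(x)) {
        parsed <- suppressWarnings(as.numeric(x))
        bad <- which(is.na(parsed) & !is.na(x))
        if (length(bad))
          stop(sprintf("non-numeric %s at observations row %d: '%s'",
                       col, bad[1], x[bad[1]]))
        obs[[col]] <- parsed
      }
    }
    unknown <- setdiff(unique(obs$feature), roster$dynamic_features)
    if (length(unknown))
      stop("feature outside roster: ", paste(unknown, collapse = ", "))
  }
  statics <- data.table::fread(st_file, colClasses = list(character = "patient_id"),
                               data.table = FALSE)
  if (!all(c("patient_id", "age", "gender", "unit") %in% names(statics)))
    stop("statics table lacks required columns")
  labels <- NULL
  lab_file <- file.path(path, "labels.csv")
  if (file.exists(lab_file))
    labels <- data.table::fread(lab_file, colClasses = list(character = "patient_id"),
                                data.table = FALSE)

  ids <- sort(unique(statics$patient_id))
  obs_split <- split(obs, factor(obs$patient_id, levels = ids))
  records <- lapply(ids, function(id) {
    o <- obs_split[[id]]
    if (is.null(o)) o <- data.frame(feature = character(0), time_h = numeric(0),
                                    value = numeric(0))
    srow <- statics[statics$patient_id == id, , drop = FALSE][1, ]
    s <- encode_statics(srow$age, srow$gender, srow$unit, roster)
    lab <- NA_integer_; onset <- NA_real_; hor <- NA_integer_; endt <- NULL
    if (!is.null(labels) && id %in% labels$patient_id) {
      lrow <- labels[labels$patient_id == id, , drop = FALSE][1, ]
      lab <- if (is.na(lrow$label)) NA_integer_ else as.integer(lrow$label)
      onset <- as.numeric(lrow$onset_time)
      hor <- if (is.na(lrow$horizon)) NA_integer_ else as.integer(lrow$horizon)
      if (!is.na(lrow$end_time)) endt <- as.numeric(lrow$end_time)
    }
    patient_record(id, o[, c("feature", "time_h", "value")], s,
                   label = lab, onset_time = onset, horizon = hor,
                   end_time = endt)
  })
  attr(records, "roster") <- roster
  records
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: writes `observations.csv`, `statics.csv` and
#' `labels.csv` into `path`. Numeric columns are serialized at full double
#' precision so that a write/read round trip is lossless.
#'
#' @param records list of [patient_record()]s.
#' @param path output directory (created if missing).
#' @param roster a [feature_roster()] used to decode the statics columns.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, roster = attr(records, "roster")) {
  if (is.null(roster)) stop("a roster is required to decode statics")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf("%.17g", x)
  obs <- data.table::rbindlist(lapply(records, function(r) {
    o <- r$observations
    data.table::data.table(patient_id = rep(r$patient_id, nrow(o)),
                           feature = o$feature, time_h = fmt(o$time_h),
                           value = fmt(o$value))
  }))
  if (!nrow(obs))
    obs <- data.table::data.table(patient_id = character(0), feature = character(0),
                                  time_h = character(0), value = character(0))
  data.table::fwrite(obs, file.path(path, "observations.csv"))
  statics <- data.table::rbindlist(lapply(records, function(r) {
    s <- r$statics
    unit_cols <- s[-(1:2)]
    data.table::data.table(patient_id = r$patient_id, age = fmt(s[["age"]]),
                           gender = s[["gender"]],
                           unit = roster$units[which(unit_cols == 1)[1]])
  }))
  if (!nrow(statics))
    statics <- data.table::data.table(patient_id = character(0), age = character(0),
                                      gender = numeric(0), unit = character(0))
  data.table::fwrite(statics, file.path(path, "statics.csv"))
  labels <- data.table::rbindlist(lapply(records, function(r) {
    data.table::data.table(patient_id = r$patient_id, label = r$label,
                           onset_time = ifelse(is.na(r$onset_time), NA_character_,
                                               fmt(r$onset_time)),
                           horizon = r$horizon,
                           end_time = fmt(r$end_time))
  }))
  if (!nrow(labels))
    labels <- data.table::data.table(patient_id = character(0), label = integer(0),
                                     onset_time = character(0), horizon = integer(0),
                                     end_time = character(0))
  data.table::fwrite(labels, file.path(path, "labels.csv"))
  invisible(path)
}
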