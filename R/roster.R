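#' Feature rosters
#'
#' A feature roster fixes the global ordering of dynamic features (vitals and
#' labs) and the encoding of static features (age, gender, one-hot first
#' admission unit). All downstream matrices index features by this ordering,
#' so the roster is constructed once per study and passed everywhere.
#'
#' @param dynamic_features character vector of M unique dynamic feature names.
#' @param cluster character vector of the same length with entries `"vital"`
#'   or `"lab"`, tagging the expected sampling/noise regime of each feature.
#' @param units character vector of first-admission-unit levels; the unit is
#'   one-hot encoded, so the number of static columns is `Q = 2 + length(units)`.
#' @return an object of class `feature_roster` with elements
#'   `dynamic_features`, `cluster`, `units`, `static_features` (encoded names),
#'   `M` and `Q`.
#' @examples
#' r <- feature_roster(c("heartrate", "lactate"), c("vital", "lab"))
#' r$M; r$Q
#' @export
feature_roster <- function(dynamic_features, cluster,
                           units = c("MICU", "SICU", "CCU")) {
  stopifnot(is.character(dynamic_features), length(dynamic_features) >= 1)
  if (anyDuplicated(dynamic_features))
    stop("dynamic feature names must be unique")
  if (length(cluster) != length(dynamic_features))
    stop("cluster tags must match dynamic features in length")
  if (!all(cluster %in% c("vital", "lab")))
    stop("cluster tags must be 'vital' or 'lab'")
  if (anyDuplicated(units)) stop("unit levels must be unique")
  static_features <- c("age", "gender", paste0("unit_", units))
  structure(list(
    dynamic_features = dynamic_features,
    cluster = cluster,
    units = units,
    static_features = static_features,
    M = length(dynamic_features),
    Q = length(static_features)
  ), class = "feature_roster")
}

#' @export
print.feature_roster <- function(x, ...) {
  cat("<feature_roster> M =", x$M, "dynamic (",
      sum(x$cluster == "vital"), "vitals /", sum(x$cluster == "lab"),
      "labs ), Q =", x$Q, "static columns\n")
  invisible(x)
}

#' Default 24-feature intensive-care roster
#'
#' Seven frequently measured vital signs and seventeen laboratory values,
#' the dynamic variables reported at least once for the large majority of an
#' adult ICU population.
#'
#' @param units first-admission-unit levels for the one-hot static encoding.
#' @return a [feature_roster()].
#' @export
default_roster <- function(units = c("MICU", "SICU", "CCU", "CSRU", "TSICU")) {
  vitals <- c("sysbp", "diabp", "meanbp", "resprate", "heartrate",
              "spo2_pulsoxy", "tempc")
  labs <- c("bicarbonate", "creatinine", "chloride", "glucose", "hematocrit",
            "hemoglobin", "lactate", "platelet", "potassium", "ptt", "inr",
            "pt", "sodium", "bun", "wbc", "magnesium", "ph_bloodgas")
  feature_roster(c(vitals, labs),
                 c(rep("vital", length(vitals)), rep("lab", length(labs))),
                 units = units)
}

#' Roster for synthetic cohorts
#'
#' @param n_vitals,n_labs number of synthetic vital / lab features.
#' @param units unit levels for the static one-hot encoding.
#' @return a [feature_roster()] with features `vital_1..` and `lab_1..`.
#' @export
synthetic_roster <- function(n_vitals = 5, n_labs = 5,
                             units = c("MICU", "SICU", "CCU")) {
  feature_roster(
    c(paste0("vital_", seq_len(n_vitals)), paste0("lab_", seq_len(n_labs))),
    c(rep("vital", n_vitals), rep("lab", n_labs)),
    units = units
  )
}

#' Read or write a roster as YAML
#'
#' @param path file path.
#' @return `read_roster` returns a [feature_roster()]; `write_roster` returns
#'   `path` invisibly.
#' @export
read_roster <- function(path) {
  y <- yaml::read_yaml(path)
  feature_roster(y$dynamic_features, y$cluster, units = y$units)
}

#' @rdname read_roster
#' @param roster a [feature_roster()].
#' @export
write_roster <- function(roster, path) {
  yaml::write_yaml(list(dynamic_features = roster$dynamic_features,
                        cluster = roster$cluster,
                        units = roster$units), path)
  invisible(path)
}

# encode a statics row (age, gender, unit level) into the named Q-vector
encode_statics <- function(age, gender, unit, roster) {
  onehot <- as.numeric(roster$units == unit)
  if (sum(onehot) != 1)
    stop("unknown admission unit: ", unit)
  stats::setNames(c(age, gender, onehot), roster$static_features)
}
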