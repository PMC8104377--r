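# Sepsis-3 labelling: suspicion windows, SOFA timelines under both
# missing-contributor policies, onset assignment, inclusion rules.

empty_events <- function(patients) {
  event_table(
    antibiotics = data.frame(patient_id = character(0), time_h = numeric(0)),
    cultures = data.frame(patient_id = character(0), time_h = numeric(0)),
    sofa = data.frame(patient_id = character(0), time_h = numeric(0),
                      system = character(0), score = integer(0)),
    patients = patients
  )
}

test_that("suspicion windows follow the pairing rule and merge overlaps", {
  pats <- data.frame(patient_id = "a", age = 50, icd_sepsis = 0L,
                     icu_in_h = 0, icu_out_h = 100)
  ev <- empty_events(pats)
  ev$antibiotics <- data.frame(patient_id = "a", time_h = 10)
  ev$cultures <- data.frame(patient_id = "a", time_h = 11)
  w <- suspicion_windows(ev)
  # suspicion at the earlier event (10 h): [10 - 48, 10 + 24] clamped at 0
  expect_equal(nrow(w), 1)
  expect_equal(w$start_h, 0)
  expect_equal(w$end_h, 34)

  # antibiotics alone never create suspicion
  ev$cultures <- ev$cultures[0, ]
  expect_equal(nrow(suspicion_windows(ev)), 0)

  # two suspicion times 1 h apart with wide windows merge into one
  ev$cultures <- data.frame(patient_id = "a", time_h = c(11, 12))
  ev$antibiotics <- data.frame(patient_id = "a", time_h = c(10, 11.5))
  w <- suspicion_windows(ev)
  expect_equal(nrow(w), 1)

  # culture too long after antibiotics does not qualify
  ev$antibiotics <- data.frame(patient_id = "a", time_h = 10)
  ev$cultures <- data.frame(patient_id = "a", time_h = 40)
  expect_equal(nrow(suspicion_windows(ev)), 0)

  expect_error(suspicion_windows(ev, lookback_h = -1), "non-negative")
})

test_that("SOFA timelines honour the missing-contributor policy", {
  none <- data.frame(time_h = numeric(0), system = character(0),
                     score = integer(0))
  tl <- sofa_timeline(none, t_max = 5, missing_policy = "healthy_zero")
  expect_true(all(tl$total == 0))
  tl_u <- sofa_timeline(none, t_max = 5, missing_policy = "undefined")
  expect_true(all(is.na(tl_u$total)))

  liver <- data.frame(time_h = 5, system = "liver", score = 2L)
  tl <- sofa_timeline(liver, t_max = 10, missing_policy = "healthy_zero")
  expect_equal(tl$total[tl$hours < 5], rep(0L, 5))
  expect_equal(tl$total[tl$hours >= 5], rep(2L, 6))
  tl_u <- sofa_timeline(liver, t_max = 10, missing_policy = "undefined")
  expect_true(all(is.na(tl_u$total)))

  worst <- do.call(rbind, lapply(sofa_systems(), function(s)
    data.frame(time_h = 0, system = s, score = 4L)))
  tl <- sofa_timeline(worst, t_max = 3, missing_policy = "healthy_zero")
  expect_equal(tl$total, rep(24L, 4))

  bad <- data.frame(time_h = 0, system = "liver", score = 7L)
  expect_error(sofa_timeline(bad, t_max = 2), "0..4")
})

test_that("measurements expire after the carry-forward horizon", {
  liver <- data.frame(time_h = 1, system = "liver", score = 3L)
  tl <- sofa_timeline(liver, t_max = 30, missing_policy = "healthy_zero",
                      carry_forward_h = 10)
  expect_equal(tl$total[tl$hours == 5], 3L)
  expect_equal(tl$total[tl$hours == 12], 0L)   # expired, back to healthy
})

test_that("onset is the first two-point rise above the running minimum", {
  win <- data.frame(start_h = 10, end_h = 40)
  mk <- function(totals) {
    structure(list(hours = seq_along(totals) - 1, total = totals),
              class = "sofa_timeline")
  }
  # constant SOFA: control
  expect_equal(assign_onset(mk(rep(3L, 50)), win)$class, "control")
  # 1 at window start, 3 at start+4: case with onset there
  tot <- rep(1L, 50); tot[15:50] <- 3L   # hours 14+
  res <- assign_onset(mk(tot), win)
  expect_equal(res$class, "case")
  expect_equal(res$onset_time, 14)
  # same rise outside every window: control
  expect_equal(assign_onset(mk(tot), data.frame(start_h = 20, end_h = 40))$class,
               "control")
  # drop then rise relative to the running minimum
  tot2 <- rep(4L, 50); tot2[20:25] <- 1L; tot2[26:50] <- 3L
  res2 <- assign_onset(mk(tot2), win)
  expect_equal(res2$class, "case")
  expect_equal(res2$onset_time, 25)
  # undefined hours are skipped, not treated as zero
  tot3 <- rep(NA_integer_, 50); tot3[12] <- 2L; tot3[30] <- 3L
  expect_equal(assign_onset(mk(tot3), win)$class, "control")
})

test_that("onset is monotone: adding a later rise never moves onset earlier", {
  win <- data.frame(start_h = 0, end_h = 30)
  mk <- function(totals) structure(list(hours = seq_along(totals) - 1,
                                        total = totals),
                                   class = "sofa_timeline")
  base <- c(rep(1L, 10), rep(3L, 21))
  res1 <- assign_onset(mk(base), win)
  later <- base; later[25:31] <- 5L
  res2 <- assign_onset(mk(later), win)
  expect_equal(res1$onset_time, 10)
  expect_true(res2$onset_time >= res1$onset_time - 1e-9)
})

test_that("inclusion rules exclude minors, invalid records and ICD controls", {
  pats <- data.frame(patient_id = c("a", "b", "c", "d"),
                     age = c(12, 50, 60, NA),
                     icd_sepsis = c(0L, 1L, 0L, 0L),
                     icu_in_h = 0, icu_out_h = 100)
  labels <- data.frame(patient_id = c("a", "b", "c", "d"),
                       class = c("case", "control", "case", "control"),
                       onset_time = c(5, NA, 50, NA))
  out <- classify_patients(empty_events(pats), labels)
  expect_equal(out$class[out$patient_id == "a"], "excluded")
  expect_equal(out$exclusion_reason[out$patient_id == "a"], "age")
  expect_equal(out$class[out$patient_id == "b"], "excluded")
  expect_equal(out$class[out$patient_id == "c"], "case")
  expect_equal(out$class[out$patient_id == "d"], "excluded")
  expect_equal(out$exclusion_reason[out$patient_id == "d"], "invalid record")

  # onset after discharge reverts to control
  labels2 <- data.frame(patient_id = "c", class = "case", onset_time = 150)
  out2 <- classify_patients(empty_events(pats[3, ]), labels2)
  expect_equal(out2$class, "control")
})

test_that("the scripted fixtures reproduce their hand-derived ground truth", {
  fx <- generate_event_fixtures(n_patients = 8)
  for (policy in c("healthy_zero", "undefined")) {
    got <- label_cohort(fx$events, missing_policy = policy)
    truth_class <- fx$truth[[paste0("class_", policy)]]
    truth_onset <- fx$truth[[paste0("onset_", policy)]]
    ord <- match(fx$truth$patient_id, got$patient_id)
    expect_equal(got$class[ord], truth_class,
                 info = paste("policy", policy))
    expect_equal(got$onset_time[ord], truth_onset,
                 info = paste("policy", policy))
  }
})

test_that("healthy-zero labelling never finds fewer cases than undefined", {
  fx <- generate_event_fixtures(n_patients = 8)
  hz <- label_cohort(fx$events, missing_policy = "healthy_zero")
  ud <- label_cohort(fx$events, missing_policy = "undefined")
  cases_hz <- hz$patient_id[hz$class == "case"]
  cases_ud <- ud$patient_id[ud$class == "case"]
  expect_true(all(cases_ud %in% cases_hz))
})
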