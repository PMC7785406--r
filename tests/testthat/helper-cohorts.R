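# Fixture builders shared across the suite. All cohorts are constructed in
# code; no data files.

# Minimal visit row with sensible vitals; symptom scores supplied per call.
make_visits <- function(patient_id, days, scores) {
  # `scores`: named list symptom -> vector (recycled), defaults to 1
  n <- length(days)
  sc <- lapply(c("dyspnea", "orthopnea", "bendopnea", "pnd"), function(s) {
    v <- scores[[s]]
    if (is.null(v)) rep(1L, n) else rep(as.integer(v), length.out = n)
  })
  names(sc) <- c("dyspnea", "orthopnea", "bendopnea", "pnd")
  data.frame(
    patient_id = patient_id, day = as.integer(days),
    sbp_mmhg = 120, dbp_mmhg = 70, hr_bpm = 70, weight_kg = 80,
    bnp_pg_ml = 500,
    dyspnea = sc$dyspnea, orthopnea = sc$orthopnea,
    bendopnea = sc$bendopnea, pnd = sc$pnd
  )
}

make_patient <- function(patient_id, hospitalized = 0L,
                         admission_day = NA_integer_,
                         excluded_intervals = "") {
  data.frame(patient_id = patient_id,
             hospitalized = as.integer(hospitalized),
             admission_day = as.integer(admission_day),
             excluded_intervals = excluded_intervals)
}

# Cohort where hospitalized patients always score `hi` on every symptom and
# the others always `lo`; one eligible day-set per patient.
make_degenerate_cohort <- function(n_events = 3L, n_nonevents = 4L,
                                   hi = 5L, lo = 1L,
                                   days = c(0L, 14L, 17L)) {
  ids_e <- sprintf("E%02d", seq_len(n_events))
  ids_n <- sprintf("N%02d", seq_len(n_nonevents))
  visits <- rbind(
    do.call(rbind, lapply(ids_e, function(id)
      make_visits(id, days, list(dyspnea = hi, orthopnea = hi,
                                 bendopnea = hi, pnd = hi)))),
    do.call(rbind, lapply(ids_n, function(id)
      make_visits(id, days, list(dyspnea = lo, orthopnea = lo,
                                 bendopnea = lo, pnd = lo))))
  )
  patients <- rbind(
    do.call(rbind, lapply(ids_e, function(id)
      make_patient(id, 1L, admission_day = 20L))),
    do.call(rbind, lapply(ids_n, function(id) make_patient(id)))
  )
  hf_cohort(visits, patients)
}

# Small cohort with hand-set scores and exactly one eligible day per
# patient, so random-day sampling is deterministic.
make_hand_cohort <- function() {
  visits <- rbind(
    make_visits("E01", c(0L, 17L), list(dyspnea = c(1L, 4L),
                                        orthopnea = c(1L, 3L),
                                        bendopnea = c(1L, 5L))),
    make_visits("E02", c(0L, 17L), list(dyspnea = c(1L, 2L),
                                        orthopnea = c(1L, 2L),
                                        bendopnea = c(1L, 4L))),
    make_visits("N01", c(10L), list(dyspnea = 3L, orthopnea = 1L,
                                    bendopnea = 1L)),
    make_visits("N02", c(10L), list(dyspnea = 1L, orthopnea = 1L,
                                    bendopnea = 1L))
  )
  patients <- rbind(
    make_patient("E01", 1L, 20L),
    make_patient("E02", 1L, 20L),
    make_patient("N01"),
    make_patient("N02")
  )
  hf_cohort(visits, patients)
}

# Random small cohort for property tests: every patient shares the visit
# schedule; scores drawn uniformly from 1..5.
make_random_cohort <- function(n_events = 3L, n_nonevents = 4L,
                               days = c(0L, 3L, 7L, 14L, 17L)) {
  ids <- c(sprintf("E%02d", seq_len(n_events)),
           sprintf("N%02d", seq_len(n_nonevents)))
  hosp <- rep(c(1L, 0L), c(n_events, n_nonevents))
  visits <- do.call(rbind, lapply(ids, function(id) {
    make_visits(id, days,
                list(dyspnea = sample(1:5, length(days), replace = TRUE),
                     orthopnea = sample(1:5, length(days), replace = TRUE),
                     bendopnea = sample(1:5, length(days), replace = TRUE),
                     pnd = sample(1:5, length(days), replace = TRUE)))
  }))
  patients <- do.call(rbind, lapply(seq_along(ids), function(i) {
    make_patient(ids[i], hosp[i],
                 admission_day = if (hosp[i] == 1L) 20L else NA_integer_)
  }))
  hf_cohort(visits, patients)
}

# window object without going through a patients table
make_window <- function(patient_id, days, basis = "full_period") {
  structure(list(patient_id = patient_id, days = as.integer(days),
                 basis = basis, empty = length(days) == 0L),
            class = "eligibility_window")
}
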