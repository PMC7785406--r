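#' Construct a telemonitoring cohort object
#'
#' Bundles the two tables of a longitudinal cohort — one row per
#' patient-visit and one row per patient — and checks their joint
#' invariants: every visit belongs to a known patient, per-patient visit
#' days are unique, symptom scores are integers in 1-5, vitals are strictly
#' positive, and hospitalized patients carry an admission day.
#'
#' @param visits Data frame with columns `patient_id, day, sbp_mmhg,
#'   dbp_mmhg, hr_bpm, weight_kg, bnp_pg_ml, dyspnea, orthopnea, bendopnea,
#'   pnd`.
#' @param patients Data frame with columns `patient_id, hospitalized,
#'   admission_day, excluded_intervals` (semicolon-separated `start-end`
#'   day pairs, possibly empty).
#'
#' @return An object of class `hf_cohort`: a list with sorted `visits` and
#'   `patients` data frames.
#' @export
hf_cohort <- function(visits, patients) {
  missing_v <- setdiff(HF_VISIT_COLUMNS, names(visits))
  if (length(missing_v)) {
    stop("visits table is missing column(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  missing_p <- setdiff(HF_PATIENT_COLUMNS, names(patients))
  if (length(missing_p)) {
    stop("patients table is missing column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  visits <- as.data.frame(visits)[HF_VISIT_COLUMNS]
  patients <- as.data.frame(patients)[HF_PATIENT_COLUMNS]
  patients$patient_id <- as.character(patients$patient_id)
  visits$patient_id <- as.character(visits$patient_id)
  patients$excluded_intervals <- as.character(patients$excluded_intervals)
  patients$excluded_intervals[is.na(patients$excluded_intervals)] <- ""

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id in patients table", call. = FALSE)
  }
  orphan <- !(visits$patient_id %in% patients$patient_id)
  if (any(orphan)) {
    stop(sprintf("visit row %d: unknown patient_id '%s'",
                 which(orphan)[1L], visits$patient_id[which(orphan)[1L]]),
         call. = FALSE)
  }
  for (sym in HF_SYMPTOMS) {
    s <- visits[[sym]]
    bad <- is.na(s) | s != as.integer(s) | s < 1 | s > 5
    if (any(bad)) {
      stop(sprintf("visit row %d: field '%s' must be an integer score in 1-5 (got %s)",
                   which(bad)[1L], sym, s[which(bad)[1L]]), call. = FALSE)
    }
    visits[[sym]] <- as.integer(s)
  }
  for (col in unname(HF_VITALS)) {
    v <- visits[[col]]
    bad <- is.na(v) | v <= 0
    if (any(bad)) {
      stop(sprintf("visit row %d: field '%s' must be strictly positive",
                   which(bad)[1L], col), call. = FALSE)
    }
  }
  if (!all(patients$hospitalized %in% c(0L, 1L))) {
    stop("patients field 'hospitalized' must be 0 or 1", call. = FALSE)
  }
  patients$hospitalized <- as.integer(patients$hospitalized)
  bad_adm <- patients$hospitalized == 1L & is.na(patients$admission_day)
  if (any(bad_adm)) {
    stop(sprintf("patient row %d: field 'admission_day' must be set when hospitalized = 1",
                 which(bad_adm)[1L]), call. = FALSE)
  }
  ord <- order(visits$patient_id, visits$day)
  visits <- visits[ord, , drop = FALSE]
  dup <- duplicated(visits[c("patient_id", "day")])
  if (any(dup)) {
    stop(sprintf("visit row %d: duplicated day %d for patient '%s'",
                 which(dup)[1L], visits$day[which(dup)[1L]],
                 visits$patient_id[which(dup)[1L]]), call. = FALSE)
  }
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  rownames(visits) <- NULL
  rownames(patients) <- NULL
  structure(list(visits = visits, patients = patients), class = "hf_cohort")
}

#' @export
print.hf_cohort <- function(x, ...) {
  n_ev <- sum(x$patients$hospitalized)
  cat(sprintf("<hf_cohort> %d patients (%d hospitalized), %d visits\n",
              nrow(x$patients), n_ev, nrow(x$visits)))
  invisible(x)
}

# Parse "s-e;s-e" into a 2-column matrix of day intervals.
parse_intervals <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    if (length(p) != 2L || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("malformed excluded_intervals entry: '", txt, "'", call. = FALSE)
    }
    as.numeric(p)
  }, numeric(2L)))
  colnames(out) <- c("start", "end")
  if (any(out[, "end"] < out[, "start"])) {
    stop("excluded interval with end before start: '", txt, "'",
         call. = FALSE)
  }
  out
}

format_intervals <- function(m) {
  if (nrow(m) == 0L) return("")
  paste(sprintf("%g-%g", m[, 1L], m[, 2L]), collapse = ";")
}

#' Generate a synthetic telemonitoring cohort
#'
#' Simulates a short longitudinal cohort under the latent-severity model of
#' [sim_config()]. `round(n_patients * event_fraction)` patients are
#' hospitalized; each receives an admission day drawn uniformly from the
#' second half of the study among days with at least two visits in the
#' preceding 7 days. Hospitalized patients' visits stop before admission;
#' their visits within 7 days of admission draw latent symptom severity,
#' heart rate and BNP (with its pre-admission linear trend) from the event
#' regime, earlier visits from the non-event regime. Each symptom score is
#' 1 plus the number of `ordinal_thresholds` strictly below its latent
#' draw. Vitals are rounded to measurement precision (integer mmHg and bpm,
#' 0.1 kg, 0.1 pg/mL), so written CSVs round-trip exactly.
#'
#' @param config A [sim_config()].
#' @return An [hf_cohort()].
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(seed = 42))
#' coh
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_patients
  n_events <- as.integer(round(n * config$event_fraction))
  ids <- sprintf("P%03d", seq_len(n))
  hospitalized <- seq_len(n) <= n_events
  vd <- config$visit_days
  sds <- config$vital_noise_sds

  admission <- rep(NA_integer_, n)
  if (n_events > 0L) {
    lo <- as.integer(ceiling(config$study_days / 2)) - 1L
    hi <- config$study_days - 2L
    candidates <- seq.int(max(lo, 1L), max(hi, 1L))
    ok <- vapply(candidates, function(a) {
      sum(vd >= a - 7L & vd < a) >= 2L
    }, logical(1L))
    if (!any(ok)) {
      stop("visit schedule too sparse: no admission day in the second half ",
           "of the study has >= 2 visits within the preceding 7 days",
           call. = FALSE)
    }
    candidates <- candidates[ok]
    admission[hospitalized] <- vapply(
      seq_len(n_events), function(i) draw_one(candidates), integer(1L))
  }

  excluded <- rep("", n)
  if (config$nontarget_admission && any(!hospitalized)) {
    # one non-target admission (e.g. infection without congestion) of ~3
    # days mid-study for the last non-hospitalized patient
    s <- as.integer(round(config$study_days * 0.4))
    excluded[max(which(!hospitalized))] <- sprintf("%d-%d", s, s + 2L)
  }

  visit_rows <- vector("list", n)
  for (i in seq_len(n)) {
    days <- if (hospitalized[i]) vd[vd < admission[i]] else vd
    m <- length(days)
    pre <- if (hospitalized[i]) (admission[i] - days) <= 7 else rep(FALSE, m)

    # between-patient intercepts (same scale as within-visit noise)
    int_hr <- rnorm(1L, 0, sds[["hr"]])
    int_sbp <- rnorm(1L, 0, sds[["sbp"]])
    int_dbp <- rnorm(1L, 0, sds[["dbp"]])
    int_wt <- rnorm(1L, 0, sds[["weight"]])
    fac_bnp <- exp(rnorm(1L, 0, sds[["bnp_log"]]) - sds[["bnp_log"]]^2 / 2)

    hr_mu <- ifelse(pre, config$hr_mean_event, config$hr_mean_nonevent)
    hr <- hr_mu + int_hr + rnorm(m, 0, sds[["hr"]])
    sbp <- config$sbp_mean + int_sbp + rnorm(m, 0, sds[["sbp"]])
    dbp <- config$dbp_mean + int_dbp + rnorm(m, 0, sds[["dbp"]])
    wt <- config$weight_mean + int_wt + rnorm(m, 0, sds[["weight"]])

    # BNP: log-normal noise around a regime mean; in the pre-admission
    # window the mean ramps linearly, centred so the window average stays
    # at bnp_mean_event
    bnp_mu <- ifelse(
      pre,
      config$bnp_mean_event +
        config$bnp_preadmission_slope * (days - (admission[i] - 3.5)),
      config$bnp_mean_nonevent
    )
    bnp_mu <- pmax(bnp_mu, 1)
    bnp <- bnp_mu * fac_bnp *
      exp(rnorm(m, 0, sds[["bnp_log"]]) - sds[["bnp_log"]]^2 / 2)

    lat_mu <- ifelse(pre, config$latent_mean_event, config$latent_mean_nonevent)
    scores <- sapply(HF_SYMPTOMS, function(sym) {
      latent <- rnorm(m, lat_mu, config$latent_sd)
      1L + as.integer(rowSums(outer(latent, config$ordinal_thresholds, ">")))
    })
    scores <- matrix(scores, nrow = m,
                     dimnames = list(NULL, HF_SYMPTOMS))

    visit_rows[[i]] <- data.frame(
      patient_id = ids[i],
      day = days,
      sbp_mmhg = pmax(round(sbp), 1),
      dbp_mmhg = pmax(round(dbp), 1),
      hr_bpm = pmax(round(hr), 1),
      weight_kg = pmax(round(wt, 1), 0.1),
      bnp_pg_ml = pmax(round(bnp, 1), 0.1),
      dyspnea = scores[, "dyspnea"],
      orthopnea = scores[, "orthopnea"],
      bendopnea = scores[, "bendopnea"],
      pnd = scores[, "pnd"]
    )
  }

  visits <- do.call(rbind, visit_rows)
  patients <- data.frame(
    patient_id = ids,
    hospitalized = as.integer(hospitalized),
    admission_day = admission,
    excluded_intervals = excluded
  )
  hf_cohort(visits, patients)
}

#' Write a cohort to its two-CSV representation
#'
#' Writes the visit-level and patient-level tables as plain CSVs with the
#' canonical column layout. `admission_day` is blank for patients without a
#' heart-failure admission. [read_cohort()] on the written files reproduces
#' the cohort exactly.
#'
#' @param cohort An [hf_cohort()].
#' @param visit_path,patient_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, visit_path, patient_path) {
  stopifnot(inherits(cohort, "hf_cohort"))
  write.csv(cohort$visits, visit_path, row.names = FALSE, quote = FALSE,
            na = "")
  write.csv(cohort$patients, patient_path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(c(visits = visit_path, patients = patient_path))
}

#' Read a cohort from its two-CSV representation
#'
#' Validates the schema on read: missing columns, non-ordinal symptom
#' scores, orphan visits and hospitalized patients without an admission day
#' all raise an error naming the offending row and field.
#'
#' @param visit_path,patient_path Paths written by [write_cohort()] (or any
#'   files with the same schema).
#' @return An [hf_cohort()].
#' @export
read_cohort <- function(visit_path, patient_path) {
  for (p in c(visit_path, patient_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  visits <- read.csv(visit_path, stringsAsFactors = FALSE,
                     colClasses = c(patient_id = "character"))
  patients <- read.csv(patient_path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      excluded_intervals = "character"))
  if ("admission_day" %in% names(patients) &&
      is.character(patients$admission_day)) {
    patients$admission_day <-
      suppressWarnings(as.integer(patients$admission_day))
  }
  hf_cohort(visits, patients)
}
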