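#' Simulation configuration for synthetic telemonitoring cohorts
#'
#' Builds and validates the parameter set of the synthetic cohort
#' generator. The defaults describe a 29-patient pilot-scale cohort
#' followed for 30 days with twice-weekly visits and a 10/29 (~34%)
#' heart-failure hospitalization rate. Hospitalized patients switch, for
#' visits in the 7 days before admission, from the non-event to the event
#' regime: higher latent symptom severity (median Likert scores about 4 vs
#' 2), higher heart rate (about 80 vs 67 bpm) and higher, upward-trending
#' BNP (about 1113 vs 546 pg/mL, rising roughly 20 pg/mL per day before
#' admission).
#'
#' Symptom scores arise from a latent Gaussian severity per symptom per
#' visit, cut at `ordinal_thresholds`: the score is 1 plus the number of
#' thresholds strictly below the sampled latent value. This latent model is
#' invertible — the Youden-optimal cutoff implied by the two latent
#' distributions is known in closed form — which is what makes cutoff
#' recovery testable.
#'
#' @param n_patients Number of patients.
#' @param event_fraction Fraction hospitalized for heart failure; the
#'   number of events is `round(n_patients * event_fraction)`.
#' @param study_days Length of the observation period in days.
#' @param visit_days Strictly increasing visit schedule (days since
#'   enrollment), all within `[0, study_days]`.
#' @param latent_mean_event,latent_mean_nonevent Latent severity means for
#'   pre-admission visits of hospitalized patients and for all other
#'   visits.
#' @param latent_sd Latent severity standard deviation (both regimes).
#' @param ordinal_thresholds Four strictly ascending cut points mapping
#'   latent severity to Likert scores 1-5.
#' @param hr_mean_event,hr_mean_nonevent Heart-rate means (bpm) for the two
#'   regimes.
#' @param bnp_mean_event,bnp_mean_nonevent BNP levels (pg/mL); BNP is
#'   simulated log-normally so values stay positive.
#' @param bnp_preadmission_slope Linear BNP trend (pg/mL per day) across
#'   the 7-day pre-admission window, centred so the window mean stays at
#'   `bnp_mean_event`.
#' @param weight_mean,sbp_mean,dbp_mean Weight (kg) and blood-pressure
#'   (mmHg) means, identical in both regimes (neither separates the groups
#'   in this design).
#' @param vital_noise_sds Named vector of noise scales: `sbp`, `dbp`, `hr`
#'   (mmHg/bpm), `weight` (kg) — additive Gaussian within-visit noise, also
#'   used as the between-patient intercept SD — and `bnp_log`, the SD of
#'   the log-normal multiplicative noise for BNP.
#' @param nontarget_admission If `TRUE`, one non-hospitalized patient
#'   carries a short non-target admission interval (e.g. an infection
#'   without congestion), exercising the 7-day clearance logic downstream.
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_patients
sim_config <- function(n_patients = 29L,
                       event_fraction = 10 / 29,
                       study_days = 30L,
                       visit_days = c(0L, 3L, 7L, 10L, 14L, 17L, 21L, 24L, 28L),
                       latent_mean_event = 4.0,
                       latent_mean_nonevent = 2.0,
                       latent_sd = 0.7,
                       ordinal_thresholds = c(1.5, 2.5, 3.5, 4.5),
                       hr_mean_event = 80.4,
                       hr_mean_nonevent = 67.4,
                       bnp_mean_event = 1112.5,
                       bnp_mean_nonevent = 545.6,
                       bnp_preadmission_slope = 19.65,
                       weight_mean = 85,
                       sbp_mean = 122,
                       dbp_mean = 72,
                       vital_noise_sds = c(sbp = 13, dbp = 8, hr = 7,
                                           weight = 1, bnp_log = 0.2),
                       nontarget_admission = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    event_fraction = event_fraction,
    study_days = as.integer(study_days),
    visit_days = as.integer(visit_days),
    latent_mean_event = latent_mean_event,
    latent_mean_nonevent = latent_mean_nonevent,
    latent_sd = latent_sd,
    ordinal_thresholds = as.numeric(ordinal_thresholds),
    hr_mean_event = hr_mean_event,
    hr_mean_nonevent = hr_mean_nonevent,
    bnp_mean_event = bnp_mean_event,
    bnp_mean_nonevent = bnp_mean_nonevent,
    bnp_preadmission_slope = bnp_preadmission_slope,
    weight_mean = weight_mean,
    sbp_mean = sbp_mean,
    dbp_mean = dbp_mean,
    vital_noise_sds = vital_noise_sds,
    nontarget_admission = isTRUE(nontarget_admission),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 1L) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cfg$event_fraction) || cfg$event_fraction < 0 ||
      cfg$event_fraction > 1) {
    stop("`event_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$study_days < 1L) {
    stop("`study_days` must be a positive integer", call. = FALSE)
  }
  vd <- cfg$visit_days
  if (length(vd) < 1L || any(diff(vd) <= 0)) {
    stop("`visit_days` must be strictly increasing", call. = FALSE)
  }
  if (any(vd < 0L) || any(vd > cfg$study_days)) {
    stop("`visit_days` must lie within [0, study_days]", call. = FALSE)
  }
  th <- cfg$ordinal_thresholds
  if (length(th) != 4L || any(diff(th) <= 0)) {
    stop("`ordinal_thresholds` must be 4 strictly ascending values",
         call. = FALSE)
  }
  check_scalar_number(cfg$latent_sd, "latent_sd", positive = TRUE)
  for (nm in c("latent_mean_event", "latent_mean_nonevent", "hr_mean_event",
               "hr_mean_nonevent", "bnp_mean_event", "bnp_mean_nonevent",
               "bnp_preadmission_slope", "weight_mean", "sbp_mean",
               "dbp_mean")) {
    check_scalar_number(cfg[[nm]], nm)
  }
  need <- c("sbp", "dbp", "hr", "weight", "bnp_log")
  if (!all(need %in% names(cfg$vital_noise_sds)) ||
      any(cfg$vital_noise_sds[need] <= 0)) {
    stop("`vital_noise_sds` must provide positive values named ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("`seed` is required", call. = FALSE)
  cfg
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file holds a flat mapping of [sim_config()] field names to values;
#' absent fields fall back to the defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$vital_noise_sds)) {
    raw$vital_noise_sds <- unlist(raw$vital_noise_sds)
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients, event fraction %.3f (%d events), %d study days\n",
              x$n_patients, x$event_fraction,
              round(x$n_patients * x$event_fraction), x$study_days))
  cat("  visit days:", paste(x$visit_days, collapse = " "), "\n")
  cat(sprintf("  latent severity: event %.2f / non-event %.2f (sd %.2f), cuts %s\n",
              x$latent_mean_event, x$latent_mean_nonevent, x$latent_sd,
              paste(x$ordinal_thresholds, collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
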