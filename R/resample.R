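#' Draw one random eligible day per patient
#'
#' For each patient with a non-empty eligibility window, chooses one visit
#' day uniformly at random from the window: a day within the 7 days before
#' admission for hospitalized patients, any (clearance-respecting) day for
#' the others. Patients with empty windows are omitted and recorded.
#'
#' Uses the current RNG state; call `set.seed()` (or let the iteration
#' drivers do it) for reproducibility. Patients are processed in sorted id
#' order, so the draw does not depend on row order.
#'
#' @param cohort An [hf_cohort()].
#' @param windows Precomputed [eligible_windows()] (computed if omitted).
#' @return A `day_sample`: list with `assignments` (named integer vector,
#'   patient id -> day) and `omitted` (character ids with empty windows).
#' @export
sample_random_days <- function(cohort, windows = eligible_windows(cohort, quiet = TRUE)) {
  nonempty <- Filter(function(w) !w$empty, windows)
  if (length(nonempty) == 0L) {
    stop("all eligibility windows are empty; nothing to sample",
         call. = FALSE)
  }
  days <- vapply(nonempty, function(w) draw_one(w$days), integer(1L))
  structure(
    list(assignments = days,
         omitted = setdiff(names(windows), names(nonempty))),
    class = "day_sample"
  )
}

#' Draw one random pair of consecutive visits per patient
#'
#' For each patient, the candidate pairs are adjacent visits in the
#' patient's schedule with *both* days inside the eligibility window (for
#' hospitalized patients this keeps the pair within the 7-day
#' pre-admission horizon); one pair is chosen uniformly. Patients with no
#' candidate pair are omitted and recorded.
#'
#' @inheritParams sample_random_days
#' @return List with `pairs` (named list of `c(day1, day2)` integer
#'   vectors) and `omitted` (character ids).
#' @export
sample_consecutive_pairs <- function(cohort, windows = eligible_windows(cohort, quiet = TRUE)) {
  pairs <- list()
  omitted <- character(0)
  for (w in windows) {
    vd <- sort(unique(cohort$visits$day[cohort$visits$patient_id == w$patient_id]))
    cand <- which(vd[-length(vd)] %in% w$days & vd[-1L] %in% w$days)
    if (length(vd) < 2L || length(cand) == 0L) {
      omitted <- c(omitted, w$patient_id)
      next
    }
    k <- draw_one(cand)
    pairs[[w$patient_id]] <- c(vd[k], vd[k + 1L])
  }
  if (length(pairs) == 0L) {
    stop("no patient has an eligible pair of consecutive visits",
         call. = FALSE)
  }
  list(pairs = pairs, omitted = omitted)
}

# symptom scores at assigned days, aligned with hospitalization labels
scores_at_days <- function(cohort, symptom, assignments) {
  key <- paste(cohort$visits$patient_id, cohort$visits$day)
  idx <- match(paste(names(assignments), assignments), key)
  if (anyNA(idx)) {
    stop("sampled day without a visit for patient(s): ",
         paste(names(assignments)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  scores <- cohort$visits[[symptom]][idx]
  labels <- cohort$patients$hospitalized[
    match(names(assignments), cohort$patients$patient_id)]
  list(scores = scores, labels = labels)
}

#' Select a symptom's severity cutoff by random-day resampling
#'
#' Implements the resampling procedure for choosing the Likert cutoff of a
#' single symptom: in each of `n_iterations` iterations one random
#' eligible day is drawn per patient, the Youden index of the rule "score
#' at least c" is computed for every cutoff c in `{2, 3, 4, 5}`, and the
#' best cutoff of the iteration (ties broken toward the lower cutoff,
#' which favours sensitivity in a screening setting) receives a win. The
#' chosen cutoff is the modal winner across iterations, again with ties
#' broken low. The full-ordinal AUC of the sampled scores and the best
#' Youden index are recorded per iteration.
#'
#' Each iteration runs on its own RNG substream derived from `seed`, so
#' results are reproducible and independent of execution order.
#'
#' @param cohort An [hf_cohort()] containing both hospitalized and
#'   non-hospitalized patients with non-empty eligibility windows.
#' @param symptom One of `"dyspnea"`, `"orthopnea"`, `"bendopnea"`,
#'   `"pnd"`.
#' @param n_iterations Number of resampling iterations (1000 by
#'   convention).
#' @param seed Integer root seed.
#' @return A `cutoff_selection`: list with `symptom`, `chosen_cutoff`,
#'   `per_cutoff_win_counts`, `auc_distribution`, `yi_distribution`,
#'   `n_iterations`, `omitted` (patient ids never sampled), `seed`.
#' @export
select_cutoff <- function(cohort, symptom, n_iterations = 1000L, seed = 1L) {
  stopifnot(inherits(cohort, "hf_cohort"))
  symptom <- match.arg(symptom, HF_SYMPTOMS)
  check_scalar_number(n_iterations, "n_iterations", positive = TRUE)
  windows <- eligible_windows(cohort, quiet = TRUE)
  usable <- names(Filter(function(w) !w$empty, windows))
  labels <- cohort$patients$hospitalized[
    match(usable, cohort$patients$patient_id)]
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    empties <- setdiff(names(windows), usable)
    stop("cutoff selection needs both groups with non-empty windows",
         if (length(empties)) paste0(" (empty windows: ",
                                     paste(empties, collapse = ", "), ")"),
         call. = FALSE)
  }

  cutoffs <- 2:5
  win_counts <- setNames(integer(length(cutoffs)), cutoffs)
  auc_dist <- numeric(n_iterations)
  yi_dist <- numeric(n_iterations)
  iter_seeds <- derive_seeds(seed, n_iterations)

  for (i in seq_len(n_iterations)) {
    set.seed(iter_seeds[i])
    ds <- sample_random_days(cohort, windows)
    sl <- scores_at_days(cohort, symptom, ds$assignments)
    yis <- vapply(cutoffs, function(cv) {
      confusion_at_cutoff(sl$scores, sl$labels, cv)$youden
    }, numeric(1L))
    best <- which.max(yis) # which.max returns the first (lowest) maximum
    win_counts[best] <- win_counts[best] + 1L
    yi_dist[i] <- yis[best]
    auc_dist[i] <- roc_auc(sl$scores, sl$labels)
  }

  structure(
    list(symptom = symptom,
         chosen_cutoff = cutoffs[which.max(win_counts)],
         per_cutoff_win_counts = win_counts,
         auc_distribution = auc_dist,
         yi_distribution = yi_dist,
         n_iterations = as.integer(n_iterations),
         omitted = setdiff(names(windows), usable),
         seed = as.integer(seed)),
    class = "cutoff_selection"
  )
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat(sprintf("<cutoff_selection> %s: chosen cutoff >= %d over %d iterations\n",
              x$symptom, x$chosen_cutoff, x$n_iterations))
  cat("  win counts:",
      paste(sprintf(">=%s: %d", names(x$per_cutoff_win_counts),
                    x$per_cutoff_win_counts), collapse = ", "), "\n")
  cat(sprintf("  AUC mean %.3f [%.3f, %.3f]; best-YI mean %.3f\n",
              mean(x$auc_distribution),
              quantile(x$auc_distribution, 0.025, names = FALSE),
              quantile(x$auc_distribution, 0.975, names = FALSE),
              mean(x$yi_distribution)))
  invisible(x)
}

# Distribution summary used in JSON reports.
dist_summary <- function(x) {
  list(mean = mean(x), median = median(x),
       p2.5 = quantile(x, 0.025, names = FALSE),
       p97.5 = quantile(x, 0.975, names = FALSE))
}
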