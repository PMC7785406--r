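#' Specify a multi-symptom decision rule
#'
#' A rule is a non-empty subset of the four respiratory symptoms together
#' with per-symptom severity cutoffs and a temporal mode. A patient is
#' predicted positive when the rule's per-symptom predicate holds for
#' *every* symptom in the subset:
#'
#' * `single_day` — score on the sampled day >= cutoff;
#' * `either_of_two` — score >= cutoff on at least one of two consecutive
#'   visits;
#' * `both_of_two` — score >= cutoff on both;
#' * `increase` — score strictly greater on the later visit (no cutoff).
#'
#' @param symptoms Character subset of
#'   `c("dyspnea", "orthopnea", "bendopnea", "pnd")`.
#' @param cutoffs Named integer vector (values in 2-5) covering at least
#'   `symptoms`; ignored for `increase`. Defaults to
#'   [reference_cutoffs()].
#' @param temporal_mode One of `"single_day"`, `"either_of_two"`,
#'   `"both_of_two"`, `"increase"`.
#' @return A `rule_spec` list with fields `symptoms`, `cutoffs`,
#'   `temporal_mode` and a canonical `name`.
#' @export
#' @examples
#' rule_spec(c("dyspnea", "orthopnea", "bendopnea"))
rule_spec <- function(symptoms,
                      cutoffs = reference_cutoffs(),
                      temporal_mode = c("single_day", "either_of_two",
                                        "both_of_two", "increase")) {
  temporal_mode <- match.arg(temporal_mode)
  symptoms <- sort(unique(as.character(symptoms)))
  bad <- setdiff(symptoms, HF_SYMPTOMS)
  if (length(symptoms) == 0L || length(bad)) {
    stop("`symptoms` must be a non-empty subset of {",
         paste(HF_SYMPTOMS, collapse = ", "), "}", call. = FALSE)
  }
  if (temporal_mode != "increase") {
    miss <- setdiff(symptoms, names(cutoffs))
    if (length(miss)) {
      stop("missing cutoff(s) for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    cutoffs <- cutoffs[symptoms]
    if (any(cutoffs < 2L) || any(cutoffs > 5L)) {
      stop("cutoffs must lie in {2, ..., 5}", call. = FALSE)
    }
  } else {
    cutoffs <- setNames(rep(NA_integer_, length(symptoms)), symptoms)
  }
  structure(
    list(symptoms = symptoms,
         cutoffs = cutoffs,
         temporal_mode = temporal_mode,
         name = paste(symptoms, collapse = "+")),
    class = "rule_spec"
  )
}

#' @export
print.rule_spec <- function(x, ...) {
  cat(sprintf("<rule_spec> %s [%s]\n", x$name, x$temporal_mode))
  if (x$temporal_mode != "increase") {
    cat("  cutoffs:", paste(sprintf("%s>=%d", names(x$cutoffs), x$cutoffs),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate symptom-combination rules
#'
#' All subsets of the given symptoms with sizes between `min_size` and
#' `max_size`, in deterministic order (by size, then lexicographically).
#' The default sizes 2-3 over four symptoms yield the canonical 10
#' combinations (6 pairs + 4 triples).
#'
#' @param symptoms Symptom pool (default: all four).
#' @param min_size,max_size Inclusive bounds on subset size.
#' @inheritParams rule_spec
#' @return List of [rule_spec()] objects.
#' @export
#' @examples
#' length(enumerate_rules()) # 10
enumerate_rules <- function(symptoms = HF_SYMPTOMS,
                            min_size = 2L, max_size = 3L,
                            cutoffs = reference_cutoffs(),
                            temporal_mode = "single_day") {
  symptoms <- sort(unique(symptoms))
  if (min_size < 1L || min_size > max_size || max_size > length(symptoms)) {
    stop(sprintf("need 1 <= min_size <= max_size <= %d", length(symptoms)),
         call. = FALSE)
  }
  out <- list()
  for (k in seq.int(min_size, max_size)) {
    subsets <- combn(symptoms, k, simplify = FALSE) # lexicographic on sorted input
    for (s in subsets) {
      out[[length(out) + 1L]] <- rule_spec(s, cutoffs, temporal_mode)
    }
  }
  out
}

#' Apply a rule to a single sampled day per patient
#'
#' @param rule A [rule_spec()] with `temporal_mode = "single_day"`.
#' @param sample A `day_sample` from [sample_random_days()].
#' @param cohort The [hf_cohort()].
#' @return Named logical vector of predictions (patient id -> positive).
#' @export
apply_rule_single_day <- function(rule, sample, cohort) {
  stopifnot(inherits(rule, "rule_spec"))
  if (rule$temporal_mode != "single_day") {
    stop("rule temporal_mode must be 'single_day'", call. = FALSE)
  }
  pred <- rep(TRUE, length(sample$assignments))
  names(pred) <- names(sample$assignments)
  for (sym in rule$symptoms) {
    sl <- scores_at_days(cohort, sym, sample$assignments)
    pred <- pred & (sl$scores >= rule$cutoffs[[sym]])
  }
  pred
}

#' Apply a rule to sampled pairs of consecutive visits
#'
#' Evaluates the temporal predicate of `rule$temporal_mode` per symptom on
#' each patient's `(day1, day2)` pair, then conjoins across the rule's
#' symptoms.
#'
#' @param rule A [rule_spec()] with a two-day `temporal_mode`.
#' @param pairs The `pairs`/`omitted` list from
#'   [sample_consecutive_pairs()].
#' @param cohort The [hf_cohort()].
#' @return Named logical vector of predictions.
#' @export
apply_rule_two_day <- function(rule, pairs, cohort) {
  stopifnot(inherits(rule, "rule_spec"))
  mode <- rule$temporal_mode
  if (!mode %in% c("either_of_two", "both_of_two", "increase")) {
    stop("rule temporal_mode must be a two-day mode", call. = FALSE)
  }
  ids <- names(pairs$pairs)
  d1 <- setNames(vapply(pairs$pairs, `[[`, numeric(1L), 1L), ids)
  d2 <- setNames(vapply(pairs$pairs, `[[`, numeric(1L), 2L), ids)
  pred <- rep(TRUE, length(ids))
  names(pred) <- ids
  for (sym in rule$symptoms) {
    s1 <- scores_at_days(cohort, sym, d1)$scores
    s2 <- scores_at_days(cohort, sym, d2)$scores
    pred <- pred & switch(
      mode,
      either_of_two = s1 >= rule$cutoffs[[sym]] | s2 >= rule$cutoffs[[sym]],
      both_of_two   = s1 >= rule$cutoffs[[sym]] & s2 >= rule$cutoffs[[sym]],
      increase      = s2 > s1
    )
  }
  pred
}

#' Evaluate a decision rule over random-day resampling
#'
#' In each iteration, draws the temporal sample required by the rule's
#' mode (one random eligible day per patient, or one random pair of
#' consecutive in-window visits), applies the rule, and computes
#' sensitivity and specificity against the true hospitalization labels;
#' the Youden index is `sens + spec - 1` and the (binary-rule) AUC is
#' `(sens + spec) / 2`. Iterations in which the omissions leave a group
#' empty are skipped and counted; more than 50% skipped is an error.
#'
#' @param rule A [rule_spec()].
#' @param cohort An [hf_cohort()].
#' @param n_iterations Number of resampling iterations.
#' @param seed Integer root seed (per-iteration substreams).
#' @return A `rule_evaluation`: rule, iteration counts, metric means,
#'   2.5/97.5 percentiles, per-iteration `distributions` data frame and
#'   `n_patients_used` per iteration.
#' @export
evaluate_rule <- function(rule, cohort, n_iterations = 1000L, seed = 1L) {
  stopifnot(inherits(rule, "rule_spec"), inherits(cohort, "hf_cohort"))
  check_scalar_number(n_iterations, "n_iterations", positive = TRUE)
  windows <- eligible_windows(cohort, quiet = TRUE)
  iter_seeds <- derive_seeds(seed, n_iterations)
  labels_all <- setNames(cohort$patients$hospitalized,
                         cohort$patients$patient_id)

  sens <- spec <- numeric(n_iterations)
  n_used <- integer(n_iterations)
  keep <- logical(n_iterations)

  for (i in seq_len(n_iterations)) {
    set.seed(iter_seeds[i])
    if (rule$temporal_mode == "single_day") {
      ds <- sample_random_days(cohort, windows)
      pred <- apply_rule_single_day(rule, ds, cohort)
    } else {
      pp <- sample_consecutive_pairs(cohort, windows)
      pred <- apply_rule_two_day(rule, pp, cohort)
    }
    lab <- labels_all[names(pred)]
    if (sum(lab == 1L) == 0L || sum(lab == 0L) == 0L) next
    keep[i] <- TRUE
    n_used[i] <- length(pred)
    sens[i] <- sum(pred & lab == 1L) / sum(lab == 1L)
    spec[i] <- sum(!pred & lab == 0L) / sum(lab == 0L)
  }

  n_skipped <- sum(!keep)
  if (n_skipped > n_iterations / 2) {
    stop(sprintf("%d of %d iterations lost a group to omissions",
                 n_skipped, as.integer(n_iterations)), call. = FALSE)
  }
  sens <- sens[keep]; spec <- spec[keep]
  yi <- sens + spec - 1
  auc <- (sens + spec) / 2

  structure(
    list(rule = rule,
         n_iterations = as.integer(n_iterations),
         n_skipped = n_skipped,
         sensitivity_mean = mean(sens),
         specificity_mean = mean(spec),
         youden_mean = mean(yi),
         auc_mean = mean(auc),
         sensitivity_summary = dist_summary(sens),
         specificity_summary = dist_summary(spec),
         youden_summary = dist_summary(yi),
         auc_summary = dist_summary(auc),
         distributions = data.frame(sensitivity = sens, specificity = spec,
                                    youden = yi, auc = auc),
         n_patients_used = n_used[keep],
         seed = as.integer(seed)),
    class = "rule_evaluation"
  )
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat(sprintf("<rule_evaluation> %s [%s], %d iterations (%d skipped)\n",
              x$rule$name, x$rule$temporal_mode, x$n_iterations, x$n_skipped))
  cat(sprintf("  sens %.2f  spec %.2f  AUC %.2f  Youden %.2f\n",
              x$sensitivity_mean, x$specificity_mean, x$auc_mean,
              x$youden_mean))
  invisible(x)
}

#' Rank rule evaluations by discrimination
#'
#' Orders evaluations by descending mean Youden index, breaking ties by
#' descending mean AUC and then by rule name; the order is deterministic
#' and independent of input order.
#'
#' @param evaluations List of [evaluate_rule()] results.
#' @return Data frame, one row per rule x mode: name, mode, n_symptoms,
#'   metric means and 2.5/97.5 percentiles of sensitivity and specificity.
#' @export
rank_rules <- function(evaluations) {
  if (length(evaluations) == 0L) stop("no evaluations given", call. = FALSE)
  rows <- lapply(evaluations, function(e) {
    data.frame(
      rule = e$rule$name,
      mode = e$rule$temporal_mode,
      n_symptoms = length(e$rule$symptoms),
      sensitivity_mean = e$sensitivity_mean,
      specificity_mean = e$specificity_mean,
      auc_mean = e$auc_mean,
      youden_mean = e$youden_mean,
      sensitivity_p2.5 = e$sensitivity_summary$p2.5,
      sensitivity_p97.5 = e$sensitivity_summary$p97.5,
      specificity_p2.5 = e$specificity_summary$p2.5,
      specificity_p97.5 = e$specificity_summary$p97.5,
      n_skipped = e$n_skipped
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$youden_mean, -out$auc_mean, out$rule, out$mode), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
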