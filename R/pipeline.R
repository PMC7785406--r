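#' Configuration of an end-to-end pipeline run
#'
#' Describes one seeded run: the cohort source (either a [sim_config()] or
#' a pair of cohort CSV paths), the resampling effort, optional cutoff
#' overrides, the rule sizes and temporal modes to evaluate, and an
#' optional output directory. A seed is mandatory — there is no silent
#' nondeterminism.
#'
#' @param sim A [sim_config()] to simulate the cohort, or `NULL` when
#'   reading from files.
#' @param visit_path,patient_path Cohort CSVs (used when `sim` is `NULL`).
#' @param iterations Resampling iterations for cutoff selection and rule
#'   evaluation.
#' @param seed Integer root seed for all resampling stages.
#' @param cutoffs Optional named cutoff overrides; when `NULL` the
#'   cutoffs chosen by [select_cutoff()] on this cohort are used.
#' @param min_size,max_size Rule subset sizes (defaults 2-3: the 10
#'   canonical combinations).
#' @param modes Temporal modes to evaluate.
#' @param out_dir Optional directory for the output artifacts
#'   (`visits.csv`, `patients.csv`, `table3.csv`, `cutoffs.json`,
#'   `rules.csv`, `report.json`).
#' @return A validated `run_config`.
#' @export
run_config <- function(sim = NULL, visit_path = NULL, patient_path = NULL,
                       iterations = 1000L, seed = NULL, cutoffs = NULL,
                       min_size = 2L, max_size = 3L,
                       modes = c("single_day", "either_of_two",
                                 "both_of_two", "increase"),
                       out_dir = NULL) {
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("`seed` is required: every run must be reproducible", call. = FALSE)
  }
  check_scalar_number(iterations, "iterations", positive = TRUE)
  if (is.null(sim) && (is.null(visit_path) || is.null(patient_path))) {
    stop("provide either `sim` or both `visit_path` and `patient_path`",
         call. = FALSE)
  }
  if (!is.null(sim)) validate_sim_config(sim)
  modes <- match.arg(modes, several.ok = TRUE)
  if (!is.null(cutoffs)) {
    miss <- setdiff(HF_SYMPTOMS, names(cutoffs))
    if (length(miss)) {
      stop("cutoff overrides must cover all symptoms; missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    cutoffs <- vapply(HF_SYMPTOMS, function(s) as.integer(cutoffs[[s]]),
                      integer(1L))
  }
  structure(
    list(sim = sim, visit_path = visit_path, patient_path = patient_path,
         iterations = as.integer(iterations), seed = as.integer(seed),
         cutoffs = cutoffs, min_size = as.integer(min_size),
         max_size = as.integer(max_size), modes = modes, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation or ingestion; eligibility-window
#' feature summaries with group comparisons; per-symptom cutoff selection
#' by random-day resampling (unless overridden); and evaluation plus
#' ranking of all requested symptom-combination rules under each temporal
#' mode. Identical configuration and seed give a byte-identical report.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `cohort_digest`, `table3` (data
#'   frame), `cutoffs` (per-symptom selections), `rules` (ranked data
#'   frame), `rule_evaluations`, and a `provenance` block (seed, config
#'   hash, package version). When `config$out_dir` is set the artifacts
#'   are written there as a side effect.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(sim = sim_config(seed = 3), iterations = 50, seed = 3)
#' rep <- run_pipeline(cfg)
#' head(rep$rules)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage_seeds <- derive_seeds(config$seed, 2L + 4L)

  cohort <- tryCatch({
    if (!is.null(config$sim)) {
      generate_cohort(config$sim)
    } else {
      read_cohort(config$visit_path, config$patient_path)
    }
  }, error = function(e) {
    stop("cohort stage: ", conditionMessage(e), call. = FALSE)
  })

  summaries <- tryCatch(
    summarize_cohort(cohort),
    error = function(e) stop("window stage: ", conditionMessage(e),
                             call. = FALSE)
  )

  selections <- NULL
  if (is.null(config$cutoffs)) {
    selections <- lapply(seq_along(HF_SYMPTOMS), function(k) {
      tryCatch(
        select_cutoff(cohort, HF_SYMPTOMS[k], config$iterations,
                      seed = stage_seeds[2L + k]),
        error = function(e) stop("cutoff stage (", HF_SYMPTOMS[k], "): ",
                                 conditionMessage(e), call. = FALSE)
      )
    })
    names(selections) <- HF_SYMPTOMS
    cutoffs <- vapply(selections, `[[`, integer(1L), "chosen_cutoff")
  } else {
    cutoffs <- config$cutoffs
  }

  evaluations <- list()
  rule_seed_base <- stage_seeds[2L]
  for (mode in config$modes) {
    rules <- enumerate_rules(HF_SYMPTOMS, config$min_size, config$max_size,
                             cutoffs, mode)
    # keep derived seeds inside 32-bit integer range
    mode_seed <- (rule_seed_base %% 2147483000L) + match(mode, config$modes)
    mode_seeds <- derive_seeds(mode_seed, length(rules))
    for (j in seq_along(rules)) {
      ev <- tryCatch(
        evaluate_rule(rules[[j]], cohort, config$iterations,
                      seed = mode_seeds[j]),
        error = function(e) stop("rule stage (", rules[[j]]$name, ", ",
                                 mode, "): ", conditionMessage(e),
                                 call. = FALSE)
      )
      evaluations[[paste(rules[[j]]$name, mode, sep = " | ")]] <- ev
    }
  }
  ranked <- rank_rules(evaluations)

  cfg_for_hash <- config[c("sim", "iterations", "seed", "cutoffs",
                           "min_size", "max_size", "modes")]
  report <- structure(
    list(
      cohort_digest = list(
        n_patients = nrow(cohort$patients),
        n_events = sum(cohort$patients$hospitalized),
        n_visits = nrow(cohort$visits)
      ),
      table3 = summaries$table,
      cutoffs = list(
        chosen = as.list(cutoffs),
        source = if (is.null(config$cutoffs)) "selected" else "override",
        selections = if (!is.null(selections)) {
          lapply(selections, function(s) {
            list(chosen_cutoff = s$chosen_cutoff,
                 win_counts = as.list(s$per_cutoff_win_counts),
                 auc = dist_summary(s$auc_distribution),
                 youden = dist_summary(s$yi_distribution))
          })
        }
      ),
      rules = ranked,
      rule_evaluations = evaluations,
      provenance = list(
        seed = config$seed,
        iterations = config$iterations,
        config_hash = config_hash(cfg_for_hash),
        package_version = as.character(packageVersion("hfsymptoms"))
      ),
      cohort = cohort
    ),
    class = "run_report"
  )

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d patients (%d hospitalized), seed %d\n",
              x$cohort_digest$n_patients, x$cohort_digest$n_events,
              x$provenance$seed))
  cat("  chosen cutoffs:",
      paste(sprintf("%s>=%d", names(x$cutoffs$chosen),
                    unlist(x$cutoffs$chosen)), collapse = ", "), "\n")
  cat("  top rules:\n")
  top <- utils::head(x$rules[c("rule", "mode", "sensitivity_mean",
                               "specificity_mean", "auc_mean",
                               "youden_mean")], 3L)
  print(top, digits = 3)
  invisible(x)
}

#' Render the group-comparison table as CSV text
#'
#' Formats the windowed-summary comparison table (one row per group x
#' measure x statistic) with display rounding — medians and quartiles to 1
#' decimal, p-values to 3 — matching the usual presentation of such
#' tables. No arithmetic is performed beyond formatting; full precision
#' lives in the report object. With a single group the p-value column is
#' blank.
#'
#' @param report A `run_report` from [run_pipeline()] (or a data frame
#'   shaped like its `table3` element).
#' @return A single string of CSV text with columns
#'   `group, measure, statistic, median, q1, q3, p_value`.
#' @export
render_table3 <- function(report) {
  tab <- if (inherits(report, "run_report")) report$table3 else report
  stopifnot(is.data.frame(tab),
            all(c("group", "measure", "statistic", "median", "q1", "q3",
                  "p_value") %in% names(tab)))
  fmt1 <- function(v) ifelse(is.na(v), "", sprintf("%.1f", v))
  fmtp <- function(v) ifelse(is.na(v), "", sprintf("%.3f", v))
  lines <- c(
    "group,measure,statistic,median,q1,q3,p_value",
    sprintf("%s,%s,%s,%s,%s,%s,%s",
            tab$group, tab$measure, tab$statistic,
            fmt1(tab$median), fmt1(tab$q1), fmt1(tab$q3),
            fmtp(tab$p_value))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a run report's artifacts to a directory
#'
#' Writes the cohort CSVs, `table3.csv`, `cutoffs.json`, `rules.csv` and
#' the full-precision `report.json` (which excludes the raw per-iteration
#' distributions but carries their summaries and the provenance block).
#'
#' @param report A `run_report`.
#' @param out_dir Directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    visits = file.path(out_dir, "visits.csv"),
    patients = file.path(out_dir, "patients.csv"),
    table3 = file.path(out_dir, "table3.csv"),
    cutoffs = file.path(out_dir, "cutoffs.json"),
    rules = file.path(out_dir, "rules.csv"),
    report = file.path(out_dir, "report.json")
  )
  write_cohort(report$cohort, paths[["visits"]], paths[["patients"]])
  cat(render_table3(report), file = paths[["table3"]])
  jsonlite::write_json(report$cutoffs, paths[["cutoffs"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(report$rules, paths[["rules"]], row.names = FALSE)
  json_report <- list(
    cohort_digest = report$cohort_digest,
    table3 = report$table3,
    cutoffs = report$cutoffs,
    rules = report$rules,
    provenance = report$provenance
  )
  jsonlite::write_json(json_report, paths[["report"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(paths)
}
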