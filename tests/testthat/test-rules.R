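test_that("rule enumeration counts and ordering are deterministic", {
  expect_length(enumerate_rules(), 10L) # 6 pairs + 4 triples
  expect_length(enumerate_rules(min_size = 2L, max_size = 4L), 11L)
  expect_length(enumerate_rules(min_size = 1L, max_size = 1L), 4L)
  r <- enumerate_rules()
  names_r <- vapply(r, `[[`, character(1L), "name")
  # sorted by size then lexicographically
  expect_equal(names_r[1:3], c("bendopnea+dyspnea", "bendopnea+orthopnea",
                               "bendopnea+pnd"))
  expect_equal(names_r[7], "bendopnea+dyspnea+orthopnea")
  expect_error(enumerate_rules(min_size = 3L, max_size = 2L), "min_size")
  expect_error(enumerate_rules(min_size = 0L), "min_size")
})

test_that("single-day rules are conjunctions over the symptom subset", {
  visits <- make_visits("A", 17L, list(dyspnea = 4L, orthopnea = 3L,
                                       bendopnea = 5L))
  visits <- rbind(visits, make_visits("B", 17L,
                                      list(dyspnea = 4L, orthopnea = 1L,
                                           bendopnea = 5L)))
  patients <- rbind(make_patient("A", 1L, 20L), make_patient("B"))
  coh <- hf_cohort(visits, patients)
  ds <- list(assignments = c(A = 17L, B = 17L), omitted = character(0))
  rule <- rule_spec(c("dyspnea", "orthopnea", "bendopnea"),
                    c(dyspnea = 3L, orthopnea = 2L, bendopnea = 4L))
  pred <- apply_rule_single_day(rule, ds, coh)
  expect_true(pred[["A"]])   # all three meet their cutoffs
  expect_false(pred[["B"]])  # orthopnea below cutoff sinks the conjunction

  # singleton rule reproduces score >= cutoff
  r1 <- rule_spec("dyspnea", c(dyspnea = 3L))
  p1 <- apply_rule_single_day(r1, ds, coh)
  expect_equal(unname(p1), c(TRUE, TRUE))
})

test_that("two-day predicates implement either/both/increase semantics", {
  visits <- make_visits("A", c(14L, 17L), list(dyspnea = c(2L, 4L)))
  visits <- rbind(visits, make_visits("B", c(14L, 17L),
                                      list(dyspnea = c(3L, 3L))))
  patients <- rbind(make_patient("A", 1L, 20L), make_patient("B"))
  coh <- hf_cohort(visits, patients)
  pp <- list(pairs = list(A = c(14L, 17L), B = c(14L, 17L)),
             omitted = character(0))

  pred_at <- function(mode, cutoff) {
    rule <- rule_spec("dyspnea", c(dyspnea = cutoff), temporal_mode = mode)
    apply_rule_two_day(rule, pp, coh)
  }
  # scores (2, 4) with cutoff 4: severe only on the later day
  expect_true(pred_at("either_of_two", 4L)[["A"]])
  expect_false(pred_at("both_of_two", 4L)[["A"]])
  expect_true(pred_at("increase", 4L)[["A"]])
  # constant (3, 3) with cutoff 3: severe both days, no increase
  expect_true(pred_at("either_of_two", 3L)[["B"]])
  expect_true(pred_at("both_of_two", 3L)[["B"]])
  expect_false(pred_at("increase", 3L)[["B"]])
})

test_that("consecutive-pair sampling stays inside eligibility windows", {
  coh <- make_degenerate_cohort(days = c(0L, 3L, 14L, 17L))
  ws <- eligible_windows(coh, quiet = TRUE)
  # hospitalized window {14, 17}: single adjacent pair, deterministic
  set.seed(601)
  pp <- sample_consecutive_pairs(coh, ws)
  expect_equal(pp$pairs[["E01"]], c(14L, 17L))

  # non-hospitalized, 4 visits: 3 candidate pairs, roughly uniform
  set.seed(602)
  firsts <- replicate(6000, {
    sample_consecutive_pairs(coh, ws)$pairs[["N01"]][1L]
  })
  freq <- table(factor(firsts, levels = c(0L, 3L, 14L)))
  expect_true(all(abs(freq / 6000 - 1 / 3) < 0.03))

  # seeded determinism
  set.seed(603); a <- sample_consecutive_pairs(coh, ws)
  set.seed(603); b <- sample_consecutive_pairs(coh, ws)
  expect_identical(a, b)

  # a patient with a single visit has no pair and is omitted
  visits <- rbind(make_visits("E01", c(14L, 17L), list()),
                  make_visits("N01", 10L, list()))
  patients <- rbind(make_patient("E01", 1L, 20L), make_patient("N01"))
  coh2 <- hf_cohort(visits, patients)
  pp2 <- sample_consecutive_pairs(coh2, eligible_windows(coh2, quiet = TRUE))
  expect_equal(pp2$omitted, "N01")
})

test_that("perfect separation gives perfect rule metrics in every iteration", {
  coh <- make_degenerate_cohort()
  for (mode in c("single_day", "either_of_two", "both_of_two")) {
    rule <- rule_spec(c("dyspnea", "bendopnea"),
                      reference_cutoffs(), temporal_mode = mode)
    ev <- evaluate_rule(rule, coh, n_iterations = 10L, seed = 5L)
    expect_equal(ev$sensitivity_mean, 1)
    expect_equal(ev$specificity_mean, 1)
    expect_equal(ev$auc_mean, 1)
    expect_equal(ev$youden_mean, 1)
    expect_equal(ev$n_skipped, 0L)
  }
})

test_that("a single-iteration evaluation matches hand-enumerated counts", {
  coh <- make_hand_cohort() # one eligible day per patient -> deterministic
  rule <- rule_spec(c("dyspnea", "bendopnea"),
                    c(dyspnea = 3L, bendopnea = 4L))
  ev <- evaluate_rule(rule, coh, n_iterations = 1L, seed = 11L)
  # on day 17: E01 scores (4, 5) -> positive; E02 (2, 4) -> negative
  # on day 10: N01 (3, 1) -> negative; N02 (1, 1) -> negative
  expect_equal(ev$sensitivity_mean, 0.5)
  expect_equal(ev$specificity_mean, 1)
  expect_equal(ev$youden_mean, 0.5)
  expect_equal(ev$auc_mean, 0.75)
  expect_equal(ev$n_patients_used, 4L)
})

test_that("per-iteration binary identities hold against roc_auc", {
  set.seed(604)
  coh <- make_random_cohort(n_events = 4L, n_nonevents = 5L)
  ws <- eligible_windows(coh, quiet = TRUE)
  rule <- rule_spec(c("dyspnea", "orthopnea"), reference_cutoffs())
  labels <- setNames(coh$patients$hospitalized, coh$patients$patient_id)
  for (rep in 1:30) {
    ds <- sample_random_days(coh, ws)
    pred <- apply_rule_single_day(rule, ds, coh)
    lab <- labels[names(pred)]
    cm <- confusion_at_cutoff(as.integer(pred), lab, 1L)
    expect_equal(cm$youden, cm$sensitivity + cm$specificity - 1)
    expect_equal(roc_auc(as.integer(pred), lab),
                 (cm$sensitivity + cm$specificity) / 2)
  }
})

test_that("cutoff and conjunction monotonicity hold per fixed sample", {
  set.seed(605)
  labels_of <- function(coh, pred) {
    setNames(coh$patients$hospitalized,
             coh$patients$patient_id)[names(pred)]
  }
  for (rep in 1:40) {
    coh <- make_random_cohort(n_events = 3L, n_nonevents = 4L)
    ws <- eligible_windows(coh, quiet = TRUE)
    ds <- sample_random_days(coh, ws)
    for (cut in 2:4) {
      lo <- apply_rule_single_day(
        rule_spec("bendopnea", c(bendopnea = cut)), ds, coh)
      hi <- apply_rule_single_day(
        rule_spec("bendopnea", c(bendopnea = cut + 1L)), ds, coh)
      # raising the cutoff can only switch predictions off
      expect_true(all(lo | !hi))
    }
    small <- apply_rule_single_day(
      rule_spec(c("dyspnea", "pnd"), reference_cutoffs()), ds, coh)
    big <- apply_rule_single_day(
      rule_spec(c("dyspnea", "pnd", "orthopnea"), reference_cutoffs()),
      ds, coh)
    # adding a symptom can only switch predictions off
    expect_true(all(small | !big))

    pp <- sample_consecutive_pairs(coh, ws)
    rule_e <- rule_spec(c("dyspnea", "bendopnea"), reference_cutoffs(),
                        temporal_mode = "either_of_two")
    rule_b <- rule_spec(c("dyspnea", "bendopnea"), reference_cutoffs(),
                        temporal_mode = "both_of_two")
    pe <- apply_rule_two_day(rule_e, pp, coh)
    pb <- apply_rule_two_day(rule_b, pp, coh)
    expect_true(all(pe | !pb)) # both-days implies either-day
  }
})

test_that("rule ranking is deterministic and order-invariant", {
  set.seed(606)
  coh <- make_random_cohort(n_events = 4L, n_nonevents = 5L)
  evs <- lapply(enumerate_rules(min_size = 1L, max_size = 2L),
                function(r) evaluate_rule(r, coh, 30L, seed = 2L))
  rk1 <- rank_rules(evs)
  rk2 <- rank_rules(rev(evs))
  expect_equal(rk1, rk2)
  expect_true(all(diff(rk1$youden_mean) <= 1e-12))
  expect_length(unique(rk1$rule), 10L) # 4 singletons + 6 pairs
  expect_error(rank_rules(list()), "no evaluations")
})
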