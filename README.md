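# hfsymptoms

Symptom-based prediction of imminent heart-failure hospitalization.

Heart-failure (HF) decompensation — acute fluid congestion — is the main
driver of HF hospitalizations. In a telemonitoring design, high-risk
patients are visited roughly twice weekly for a month; each visit records
objective vitals (blood pressure, heart rate, weight, B-type natriuretic
peptide) and four respiratory symptoms — dyspnea, orthopnea, bendopnea and
paroxysmal nocturnal dyspnea (PND) — each self-scored on a 5-point Likert
scale (1 = none, 5 = severe). `hfsymptoms` is for biostatisticians and
telemonitoring researchers who want to ask, reproducibly: *do simple
symptom-severity rules flag an admission days in advance, and how do they
compare with the vitals?*

## What it computes

* **Eligibility windows.** For a patient admitted on day *a*, only visit
  days *d* with 0 < *a* − *d* ≤ 7 are used (the week before admission,
  never the admission day); for other patients, the whole period with
  7-day clearance around any non-target admission. Vitals are summarised
  per window by mean, sample SD and OLS slope (units/day); ordinal
  symptoms by median and range. Groups are compared by Wilcoxon rank-sum
  and Fisher exact tests.
* **Cutoff selection.** Because each patient has many visits but one
  label, one random eligible day per patient is drawn; the Youden index
  *J*(*c*) = sens(*c*) + spec(*c*) − 1 is computed for each cutoff
  *c* ∈ {2,…,5}; over 1000 resampled day combinations the cutoff that
  wins most often is chosen (ties toward the lower, sensitivity-favouring
  cutoff). The ordinal AUC — the Mann-Whitney probability
  P(S₊ > S₋) + ½P(tie) — is recorded per iteration.
* **Decision rules.** Conjunctive rules over symptom subsets (sizes 2–3
  give the canonical 10 combinations) under four temporal modes:
  `single_day`, `either_of_two`, `both_of_two` and `increase` (strictly
  rising across two consecutive in-window visits). Per iteration the rule
  is a binary classifier, so *J* = sens + spec − 1 and
  AUC = (sens + spec)/2 hold by identity; rules are ranked by mean
  Youden index over the resampling.
* **Synthetic cohorts.** A seeded generator (29 patients, 10/29 event
  rate, 30 days, twice-weekly visits by default) with latent-Gaussian
  ordinal symptoms cut at fixed thresholds, regime-switching heart rate,
  and log-normal BNP with a pre-admission ramp — so the entire pipeline
  is testable, including recovery of the generative cutoff.

See `vignettes/symptom-rules.Rmd` for the model, parameter meanings and
design choices.

## Worked example

```r
library(hfsymptoms)

cfg <- run_config(sim = sim_config(seed = 1), iterations = 1000, seed = 1)
report <- run_pipeline(cfg)
report
#> <run_report> 29 patients (10 hospitalized), seed 1
#>   chosen cutoffs: dyspnea>=4, orthopnea>=3, bendopnea>=4, pnd>=4

subset(report$rules, mode == "single_day")[1:3, c(1, 4:7)]
#>                  rule sensitivity_mean specificity_mean auc_mean youden_mean
#>     dyspnea+orthopnea            0.850            0.994    0.922       0.843
#>   bendopnea+orthopnea            0.795            1.000    0.897       0.795
#>         orthopnea+pnd            0.794            0.995    0.894       0.788
```

The chosen cutoffs are the modal Youden-optimal severity levels over 1000
random-day resamples of this synthetic cohort (its latent design places
the optimum between 3 and 4, so either is a faithful recovery). The rule
table reads: requiring dyspnea ≥ 4 *and* orthopnea ≥ 3 on the same random
day detects 85% of imminent admissions at 99% specificity, for a mean
Youden index of 0.84. The group-comparison table shows the same story at
the feature level — e.g. windowed heart-rate averages of 77.8 vs 66.3 bpm
(p = 0.001) and median dyspnea 4 vs 2 (p < 0.001) in this simulation:

```r
cat(render_table3(report))
#> group,measure,statistic,median,q1,q3,p_value
#> not_hospitalized,hr,average,66.3,63.8,73.1,0.001
#> hospitalized,hr,average,77.8,76.2,85.1,0.001
#> ...
```

A thin command-line wrapper over the same functions lives at
`inst/cli/hfsymptoms-cli.R` (subcommands `simulate`, `summarize`,
`select-cutoffs`, `evaluate-rules`, `run-all`).

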