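# adhereRx

Medication adherence after kidney transplantation is a stubborn clinical
problem: even small lapses raise the risk of graft rejection, and roughly a
third of recipients are non-adherent. mHealth systems attack this with an
electronic medication tray (a MEMS-style device that time-stamps every
compartment opening), escalating reminders, home blood-pressure
self-monitoring, and weekly summary reports that let providers adjust
therapy without waiting for the next clinic visit.

`adhereRx` implements the computational machinery of such a trial as a
reusable R pipeline:

* **Dose-window adherence scoring.** Each tray opening is matched to a
  scheduled dose (greedy, chronological, first-come). A dose opened within
  ±90 min of its prescribed time scores 1.0, within ±180 min scores 0.5,
  and a missed dose scores 0. Per-dose credits average to a daily score
  *s<sub>d</sub>* ∈ [0, 1]; daily scores average (one day, one vote) over a
  30-day block to the period score. Patients scoring < 0.85 over the
  screening month are classified non-adherent and trial-eligible.
* **Reminder escalation.** Per unopened dose, the intervention arm runs the
  ladder *light (0 min) → chime (30) → patient message (60) → coordinator
  alert (90)*; opening the compartment resolves it. BP measurement is
  prompted every 3 days; sessions outside physician-set safe ranges raise
  alerts, escalating after consecutive violations.
* **Resting BP reduction and staging.** A session is one acclimation
  reading plus two readings after 5 minutes' rest; the session value is the
  mean of the last two (nurse-measured same-day substitutions are flagged).
  Values are staged by JNC 7 (normal / prehypertension / stage 1 / stage 2)
  and summarised in weekly provider reports.
* **Trial statistics.** CONSORT flow rates, the pooled two-sample *t* test,
  and the 2 (arm) × 4 (timepoint) mixed repeated-measures ANOVA:
  *F*<sub>group</sub> = MS<sub>group</sub>/MS<sub>subject(group)</sub>,
  within-subject effects over MS<sub>residual</sub>, effect sizes
  ηₚ² = F·df₁/(F·df₁ + df₂), and per-cell Bonferroni-adjusted confidence
  intervals (mean ± *t*<sub>1−α/(2k)</sub>·SE, k = 4).
* **Synthetic data.** A seeded generator emulates per-dose taking behaviour
  as an i.i.d. mixture (in-window / late-window / missed, so
  E[score] = p_full + 0.5·p_half), an arm-by-time adherence trajectory, and
  a linear adherence→BP coupling — every stage is testable without the
  never-deposited device logs.

## Worked example

Simulate a 20-patient trial (10 per arm, four 30-day blocks, twice-daily
dosing), score the screening month, and analyse the trial:

```r
library(adhereRx)

sim <- simulate_trial(n_per_arm = 10, seed = 2013)
score_patients(sim$events, sim$regimen, sim$blocks[1], window_days = 30)
#> # A tibble: 20 × 4
#>   patient_id n_days period_score eligibility
#>   <chr>       <int>        <dbl> <fct>
#> 1 P001           30        0.542 NON_ADHERENT_ELIGIBLE
#> 2 P002           30        0.575 NON_ADHERENT_ELIGIBLE
#> 3 P003           30        0.575 NON_ADHERENT_ELIGIBLE
#> 4 P004           30        0.583 NON_ADHERENT_ELIGIBLE
#> # ...
```

Every simulated patient scored below the 0.85 screening cutoff
(`period_score` is the mean daily score over the 30-day screening block),
so all would be eligible for randomization. The mixed ANOVA then tests
whether the arms diverge over time:

```r
rm_anova(sim$trial, "adherence")
#> # A tibble: 3 × 8
#>   effect          ss   df1   df2    ms     F        p partial_eta_sq
#> 1 GROUP        1.32      1    18 1.32  408.  8.20e-14          0.958
#> 2 TIME         0.652     3    54 0.217  60.4 2.91e-17          0.770
#> 3 GROUP_X_TIME 0.350     3    54 0.117  32.4 4.09e-12          0.643
```

The `GROUP_X_TIME` row is the test of interest: the intervention arm's
adherence climbs after baseline while standard care stays flat, giving a
large interaction (ηₚ² = .64 here). The cell summary mirrors the
familiar adherence-by-time table layout:

```r
table2_summary(sim$trial, "adherence")
#> # A tibble: 4 × 9
#>   timepoint MHEALTH_mean MHEALTH_se MHEALTH_ci_lo MHEALTH_ci_hi SC_mean ...
#> 1 BASELINE         0.558    0.0199          0.495         0.620   0.527
#> 2 M1               0.876    0.0150          0.829         0.923   0.558
#> 3 M2               0.919    0.00861         0.892         0.946   0.607
#> 4 M3               0.942    0.00790         0.918         0.967   0.576
```

Intervals are Bonferroni-adjusted for k = 4 timepoint-wise comparisons;
two cells differ when their intervals are disjoint — here the arms
separate at every post-baseline month but not at baseline.

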