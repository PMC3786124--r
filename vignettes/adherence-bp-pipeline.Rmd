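---
title: "Methods: dose-window adherence scoring, BP summaries and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-window adherence scoring, BP summaries and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhereRx)
```

`adhereRx` models the computational side of an mHealth medication-adherence
and blood-pressure trial: an electronic pill tray time-stamps compartment
openings, a home monitor uploads BP sessions, and the analysis asks whether
enabling the tray's reminder ladder changes adherence and blood pressure
over four monthly evaluations. This vignette is the package's account of
the models it implements, the parameters that matter, and the choices made
where the design was genuinely open.

## The adherence score

Each scheduled dose earns a credit from the signed delay
$d = t_\text{opened} - t_\text{scheduled}$ (minutes):

$$
c(d) = \begin{cases}
1.0 & |d| \le 90 \\
0.5 & 90 < |d| \le 180 \\
0 & \text{otherwise, including a missed dose.}
\end{cases}
$$

Both windows are configurable (`study_config(full_window_min,
half_window_min)`); the defaults encode the 3-hour full-credit window
centred on the prescribed time inside a 6-hour half-credit window. The
daily score is the mean credit over that day's scheduled doses, and the
period score is the unweighted mean of daily scores — one day, one vote,
regardless of dose count. Patients below 0.85 over the screening month are
non-adherent and trial-eligible; the cutoff is strict, so exactly 0.85 is
adherent.

Three points were open and are fixed here as package policy:

* **Boundary credit.** $|d| = 90$ scores 1.0 and $|d| = 180$ scores 0.5 —
  inclusive toward the better score, because patients are instructed that
  "within 90 minutes on either side" counts as adherent, and the
  instruction should agree with the score.
* **Multi-dose days** aggregate by the arithmetic mean of per-dose credits.
* **The study "month"** is a consecutive 30-day block anchored at the
  patient's device activation date, not a calendar month; days with no
  scheduled doses are absent from the daily series rather than scored 0 or
  1 (`daily_score()` returns `NA` as the explicit no-score signal).

### Matching openings to doses

A generic event log does not say which dose an opening served, so
`match_openings()` assigns greedily and chronologically: each opening
attaches to the earliest still-unmatched dose within the half-credit
window, each opening is used at most once, and later openings of an
already-served dose are surplus. This mirrors the physical tray — one
compartment per dose, and the *first* opening is when the pills left the
tray — and it is deterministic and order-independent (inputs are sorted).
Greedy matching is not globally score-optimal in every configuration: when
dose windows overlap, or when a late half-credit opening precedes an
in-window one for the same dose, an exhaustive assignment could score
higher. We regard those assignments as behaviourally wrong (they credit a
re-opening rather than the actual taking event), and the test suite
verifies that greedy equals the exhaustive optimum exactly on every
enumerable day in which each dose window holds at most one candidate
opening, and never exceeds it elsewhere.

## Reminder escalation and safety alerts

The intervention-arm ladder is `LIGHT_ON` at the dose time and `CHIME_ON`,
`PATIENT_MESSAGE`, `COORDINATOR_ALERT` at +30/+60/+90 minutes
(`escalation_offsets_min`). An event fires only if the compartment is still
closed *strictly* before its offset, so an opening at exactly +30
suppresses the chime; the opening appends `RESOLVED`. The standard-care arm
uses the tray with reminders disabled and emits nothing. The chime's
30-minute duration is protocol metadata; no `CHIME_OFF` event is modelled.
The +60 patient message is a fixed offset, not conditioned on chime
completion.

BP reminders run every `bp_cadence_days = 3` days. Sessions outside the
safe ranges raise `OUT_OF_RANGE`; "persistently unsafe" is quantified as
`persistence_n = 2` consecutive out-of-range sessions (the protocol gives
no number; one session is routine, two in a row is a pattern worth a
physician's attention), raising one `PERSISTENT_OUT_OF_RANGE` per run of
violations. The default ranges — SBP [90, 180], DBP [50, 110] mmHg — are
deliberately wide placeholders: thresholds are physician-set per patient
and should be overridden.

## Blood pressure sessions, staging, weekly reports

A protocol session is three readings: one immediate (acclimation), then two
after five minutes' rest, two minutes apart. The session value is the mean
of the last two readings; the first never contributes, which the tests
assert as an invariance. When no protocol measurement exists, a same-day
nurse-measured clinic BP substitutes and carries a `substituted` flag.
Sessions that fit neither shape are quarantined with a reason, never
silently dropped, so report denominators remain auditable.

Session values are staged by the JNC 7 convention (the protocol names the
stages but no numbers, so the cutpoints are configuration, not data):
normal < 120/80; prehypertension 120–139 or 80–89; stage 1 140–159 or
90–99; stage 2 ≥ 160 or ≥ 100 — the category is the worse of the SBP- and
DBP-implied categories, applied to the *averaged* session value rather than
individual readings. `weekly_report()` assembles the provider summary:
dose counts and the windowed score (plus the raw percent-of-doses-taken,
since either reading of "adherence to medication dosing" may be wanted),
BP-monitoring adherence against the expected 3-day schedule (it may exceed
1 when patients measure extra; cap only for display), mean SBP/DBP, and
stage percentages that total 100 whenever any session exists. Report weeks
are Monday-anchored by convention and configurable.

## Trial statistics

**Flow rates.** Participation = consented/approached and retention =
continued/entering-screening-completers, displayed as whole percents, with
both numerator and denominator explicit in `flow_counts()` so the
accounting is auditable.

**Baseline comparison.** `two_sample_t()` is the pooled (equal-variance)
independent *t*; it accepts `(mean, sd, n)` summaries so published tables
can be re-tested. The parenthetical dispersions in such tables are treated
as SDs: only under that reading does the pooled formula reproduce the
published statistic, and the package reports its own two-sided *p* rather
than echoing a printed one.

**Mixed RM-ANOVA.** `rm_anova()` implements the classical univariate
split-plot decomposition for a between factor (arm, possibly unequal
$n_i$) crossed with a within factor (timepoint, complete within patient):

$$
F_\text{group} = \frac{MS_\text{group}}{MS_\text{subject(group)}}, \qquad
F_\text{time}, F_\text{group x time} = \frac{MS_\text{effect}}{MS_\text{residual}},
$$

with $\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$ held as an exact
identity of the output. Because each patient contributes every timepoint,
group and time are orthogonal even with unequal arms, and the decomposition
is exact (the tests compare it to `stats::aov`'s `Error()`-stratum output
at $10^{-9}$ on all small shapes). Analyses are complete-case — patients
missing the outcome at any timepoint are excluded with a warning and the
per-arm complete-case counts are attached — because the design's error
degrees of freedom, $(n - 2)(t - 1)$, presuppose it. No sphericity
correction is applied by default (matching integer published dfs); a
Greenhouse–Geisser adjustment is available via
`study_config(sphericity_correction = TRUE)`.

**Bonferroni cells.** `bonferroni_cis()` computes, per arm × timepoint
cell, mean ± $t_{1-\alpha/(2k),\,n-1} \cdot SE$ with $k$ defaulting to the
4 timepoint-wise group comparisons (per-comparison α = 0.0125 at α = .05);
two cells differ when their intervals are disjoint. `table2_summary()`
lays the cells out in the conventional mean/SE/CI grid. Degenerate cells
(n < 2) get no interval; a constant outcome yields SE 0 and a point
interval.

## The synthetic-data generator

The raw device logs behind such trials are not public, so the generator is
a first-class module that emulates the statistical structure the analysis
assumes:

* **Taking behaviour** is an i.i.d. three-point mixture per dose slot —
  taken in-window (probability `p_full`), taken late (`p_half`), missed —
  so the expected period score is exactly $p_\text{full} + 0.5\,
  p_\text{half}$ and scoring the generated log through the pipeline is a
  calibration check. In-window delays get truncated-normal jitter (SD 30
  min, truncated at ±90); late delays are uniform on (90, 180] with random
  sign; timestamps round to minute resolution with delays re-clamped into
  their windows so rounding never flips a credit.
* **Trajectories.** A target mean adherence $m$ per arm × timepoint maps to
  a mixture via $p_\text{half} = \min(0.1,\, 2(1-m),\, 2m)$,
  $p_\text{full} = m - p_\text{half}/2$: late doses are kept a minor mode
  (about one dose in ten at most), which is what tray logs look like when
  most errors are outright misses. The default targets
  (`table2_targets()`) follow the motivating pattern — the intervention arm
  rising from ≈ .58 to ≈ .95 while standard care stays near .5–.59.
* **BP coupling.** Session means follow $bp_{0,i} + \beta\,(a - a_\text{
  baseline}) + \varepsilon$, using each patient's *realized* block
  adherence $a$. Defaults: baselines $N(150, 12)$ / $N(90, 8)$ mmHg
  between patients (an uncontrolled hypertensive transplant population),
  $\beta_\text{SBP} = -50$ mmHg per unit adherence — chosen so the ≈ +0.4
  adherence gain typical of the intervention moves SBP by ≈ −20 mmHg, the
  magnitude such trials report — $\beta_\text{DBP} = -20$, within-session
  SD 4 mmHg, between-session SD 6 mmHg.
* **Trial assembly.** `simulate_trial()` draws ages per arm from
  $N(42.44, 12.04)$ and $N(57.6, 8.28)$ (the study's arms), gives every
  patient a twice-daily 09:00/21:00 regimen over four 30-day blocks, takes
  a clinic evaluation on each block's last day, and builds the long trial
  table by scoring the event log through `score_patients()` — the table is
  never copied from the targets. Everything is reproducible per seed
  (`withr::with_seed`, global RNG untouched).

What the generator deliberately does **not** emulate: habit or
autocorrelation in taking behaviour (doses are i.i.d., so between-patient
score variance is smaller than in real cohorts and simulated cell SEs are
optimistic), any mechanistic response to reminders (the arm effect enters
only through the mixture trajectory), drug holidays, white-coat effects, or
missing-by-malfunction patterns. Passing tests therefore demonstrate that
the pipeline computes its statistics correctly under the assumed structure
— not that real tray logs satisfy that structure.

## Numerical and engineering choices

* Timestamps are naive local civil time held as UTC `POSIXct` at minute
  resolution; no timezone or DST arithmetic (device clocks are local, and
  the two DST edge days a year are accepted as-is).
* Duplicate openings at the identical minute collapse to one (hardware
  double-reports), with a warning.
* Readers fail loudly with file, row and column on malformed input;
  malformed BP sessions and out-of-range openings are flagged or
  quarantined rather than dropped.
* Ties and boundaries: window edges credit toward the better score; the
  escalation ladder fires strictly before an opening; eligibility at the
  cutoff is adherent.

## Problem sizes used in the test suite

The suite's stochastic checks use: the split-plot oracle on all design
shapes up to 3 subjects/arm × 3 timepoints; a 2000-replicate null
simulation (10 patients/arm) whose interaction rejection rate must sit
within binomial 95% bounds of α = .05; generator calibration at 50
patients/arm against the default targets within 3 Monte-Carlo SEs; an
exhaustive greedy-vs-optimal enumeration over all ≤4-dose/≤4-opening days
on two dose grids (disjoint and overlapping windows) crossed with an
8-time opening grid; and 2000-replicate joint coverage of an arm's four
Bonferroni intervals. The end-to-end example trial is 20 patients over
four 30-day blocks.

## Known limitations

* Greedy matching can differ from a score-optimal assignment on ambiguous
  days (overlapping dose windows, or multiple openings inside one window);
  this is by design, but logs from trays whose compartments do not map 1:1
  to doses should be interpreted with that in mind.
* The staging cutpoints are JNC 7; other guidelines (e.g. 2017 ACC/AHA)
  re-draw them, so stage percentages are convention-dependent —
  override `stage_thresholds` to match your protocol.
* `rm_anova()` is complete-case by construction; with informative dropout
  a mixed-effects model (e.g. `lme4`) is the appropriate escalation, and
  this package does not provide one.
* The pooled *t* assumes equal variances; it is kept because it is the
  design's published analysis, not because it is robust.
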