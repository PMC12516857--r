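---
title: "Two-phase prevalence estimation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase prevalence estimation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twophaseprev)
```

## The estimation problem

Population studies of psychiatric diagnoses need structured clinical
interviews, but interviewing a whole cohort is infeasible. The two-phase
design screens everyone with cheap, high-sensitivity instruments (phase 1)
and invites only screen-positives to a structured diagnostic interview
(phase 2). Two complications then stand between the raw interview counts
and a population prevalence:

1. **Selective interviewing.** Screen-negatives are never interviewed; the
   design assumes they are free of the disorder (a generous screen cut-off
   makes false negatives rare).
2. **Interview non-response.** Only part of the screen-positives complete
   the interview. Dropping the rest would bias prevalence badly, so their
   diagnosis rate is imputed from the interviewed screen-positives.

For a group of total size $T$ with $D$ interviewed members meeting a
diagnosis, $ND$ interviewed members not meeting it, and $NI$
screen-positive members not interviewed, the adjusted lifetime prevalence
is

$$P = \frac{D + \frac{D}{D + ND}\, NI}{T}.$$

The imputation step is a missing-at-random (MAR) assumption *given screen
status*: non-interviewed screen-positives are assumed to carry the same
diagnosis rate as interviewed ones. `estimate_prevalence()` implements the
formula; a cell with screen-positives but no completed interviews
($NI > 0$, $D + ND = 0$) is *inestimable* and raises an error rather than
being silently zeroed, which would bias low.

### The sub-cohort correction for gambling and gaming

In the emulated design the gambling/gaming screens were missing from the
phase-1 questionnaire of one of the two school sub-cohorts; members of that
sub-cohort were screened only if they were anyway contacted for a
M.I.N.I./ADDIS interview. Members never screened ($NS_1$ of them) get the
adjusted prevalence $PD_2$ of a reference subset — sub-cohort-2 members
*not* interviewed with M.I.N.I./ADDIS, i.e. the fully screened population
most comparable to the never-screened — imputed:

$$P = \frac{D + \frac{D}{D + ND}\, NI + PD_2 \, NS_1}{T}.$$

Two choices here were genuinely open and are worth recording:

* **$PD_2$ is attrition-adjusted.** The reference subset was itself
  screened and selectively interviewed, so its prevalence is computed with
  the same formula, not as a raw interviewed proportion.
* **$PD_2$ is group-specific.** `aggregate_counts()` restricts the
  reference subset to the analysis group being estimated. Prevalences
  differ strongly between groups (e.g. gambling in boys vs girls), so a
  pooled reference would drag every group's estimate toward the population
  mean; simulation confirms a substantial bias for high-prevalence groups
  under a pooled reference and none under the group-wise one.
  `compute_pd2()` retains a whole-cohort default with an optional group
  restriction.

### Composites and the mean diagnosis count

Composite outcomes ("any anxiety disorder", "at least one of all 20") are
person-level unions: $D$ counts members with at least one member
diagnosis, once each; $ND$ counts members with at least one member screen
indication, all indicated instruments interviewed, and no member
diagnosis; $NI$ counts members with no recorded member diagnosis and at
least one indicated-but-missing interview. Members with no member
indication contribute only to $T$ (the "assumed no diagnosis" mass). This
is the unique reading under which a singleton composite reduces exactly to
the per-entity estimator, which the tests assert. The $PD_2 NS_1$ term is
not applied inside composites: the union counts are person-level and the
never-screened carry no person-level gambling/gaming information.

The mean number of diagnoses per group member is the sum of the 20
adjusted prevalences (linearity of expectation), so the attrition
adjustment is inherited consistently; under complete response this equals
per-person counting, which is tested.

## Group construction

Sexual orientation is classified from two 3-level attraction items
(opposite sex, same sex), not from self-identification: *asexual* (not at
all attracted to either), *homosexual* (attracted to same, not at all to
opposite), *heterosexual* (the mirror image), *bisexual* (attracted to
both). Any attraction ("somewhat" or "strongly") counts; category
membership is invariant to the somewhat/strongly distinction, which is
asserted as a property test. A record missing either item is
*unclassified*: excluded from orientation analyses but retained in the
gender-discontent analysis, so the two analyses have different
denominators by design.

Gender discontent (GD) pools "doubts about my legal gender" with "not at
all comfortable", and GD is reported as one group across legal genders
(the group is small, and its members question the attributed gender);
orientation analyses are gender-separated. Comparisons follow the same
rules: orientation minorities vs same-gender heterosexuals, GD vs all
non-GD.

## Association statistics

Relative risk is the ratio of adjusted prevalences, defined only when both
are positive (rendered "–" otherwise). Significance uses a plain Pearson
chi-square on the 2×2 table of adjusted case counts ($P \cdot T$ rounded
to integers) without continuity correction — the conventional reading of
"tested against the chi-square distribution" — with stars at
p < 0.05/0.01/0.001. The choice is isolated in `chi_square_test()` so
Yates or Fisher variants could be swapped in; tables with any expected
cell below 5 are flagged, and no multiple-testing correction is applied
(none is part of the emulated design). `rr_from_rounded_percent()`
re-derives RRs from already-rounded percentage displays, the convention
under which a published table's RR column can be reproduced from its
printed prevalence columns.

## The synthetic cohort generator

Real individual-level data of this kind cannot be shared, so every
pipeline stage is validated against `generate_cohort()`, a generative
mirror of the sampling design. Defaults are fixed once to the study
conditions the package emulates and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n` | 949 | analytical sample size |
| `female_fraction` | 528/949 | observed legal-gender split |
| `orientation_probs` | ∝ (11, 18, 101, 385) girls; (14, 10, 23, 361) boys | observed group sizes among 923 classifiable |
| `orientation_missing_prob` | 26/949 | observed item non-response |
| `gd_prob`, `gd_missing_prob` | 16/941, 8/949 | observed GD rate and non-response |
| `gd_severe_prob` | 1/16 | 15:1 doubts : not-at-all-comfortable split |
| `true_prevalence` | `default_true_prevalence()` | reported group prevalences; zero for asexuals and homosexual boys |
| `sensitivity`, `specificity` | 0.95, 0.70 per instrument | "generous cut-off" screens: high sensitivity, moderate specificity |
| `interview_response_prob` | 0.511 | observed phase-2 participation among selected |
| `subcohort1_fraction` | 0.5 | two school cohorts of similar size (exact split not reported) |

Screens operate at **instrument level**: one draw per instrument
(M.I.N.I., ADDIS, NODS, IGDS), positive with probability `sensitivity`
when any of the instrument's entities is truly present and `1 −
specificity` otherwise, copied to all entities the instrument owns. This
matches how broad screening scales select for interviews and — with the
defaults — reproduces an aggregate selection rate near 80% of the cohort.
Independent per-entity screen draws would select essentially everyone and
were rejected. Interview response is a single person-level draw (one phone
session covers all indicated instruments). In sub-cohort 1 the
gambling/gaming screens run only within a completed M.I.N.I./ADDIS
session, and a positive screen there leads to the NODS/IGDS module in the
same session; in sub-cohort 2 everyone is screened in phase 1.

Diagnoses are revealed (equal to latent truth) exactly for screen-positive
entities whose owning instrument was interviewed — interviews have perfect
diagnostic validity in the simulation. Draws are ordered
demographics-first, then per entity in catalog order, then the response
draw, so appending entities does not perturb earlier draws under the same
seed; identical config and seed give byte-identical cohorts.

What the generator deliberately does **not** emulate: item-level
questionnaire responses; longitudinal waves; comorbidity between entities
(diagnoses are drawn independently within a person by default — an
optional person-level shared frailty on the logit scale, `comorbidity_sd`,
exists for sensitivity analyses but defaults to off); interviewer effects;
and imperfect interview validity. Passing tests therefore certify the
estimation pipeline under the design's stated assumptions, not the
behaviour of the instruments on real adolescents.

`inject_informative_attrition()` breaks the MAR assumption on purpose:
it multiplies the response odds of participants carrying at least one
latent diagnosis (person-level, since response is a per-person event).
With an odds multiplier below 1 the estimator must under-estimate, and the
recovery study is required to detect that.

## Numerical conventions

* Percentages display at 1 decimal, RRs and means at 2, with **half-up**
  rounding (`round_half_up()`; R's `round()` is banker's rounding and
  would disagree on exact halves).
* Inestimable cells error by default; `on_inestimable = "na"` in
  `estimate_all()`/`run_pipeline()` reports them as `NA` with a flag —
  never as a silent zero. In replicated simulations, tiny groups (e.g.
  asexuals, n ≈ 10) occasionally hit this state.
* A degenerate 2×2 table (a zero case margin) returns chi-square 0, p = 1.
* The no-noise oracle configuration is sensitivity = specificity =
  response = 1 **and** `subcohort1_fraction = 0`: with a nonzero
  sub-cohort-1 fraction the $PD_2 NS_1$ term is an estimate, not an
  identity, so exact equality with latent-case proportions is only defined
  when everyone is screened.
* All-zero group columns are removed from rendered tables (and logged)
  when `drop_zero_columns` is on, mirroring the reporting convention for
  groups in which no participant met any diagnosis.

## Validation strategy and problem sizes

The test suite (chosen as the package's own validation budget) runs:

* exact worked examples of both formulas against a direct-evaluation
  oracle (tolerance 1e-12), plus reduction, monotonicity and bound
  properties over randomized counts;
* 200 no-noise cohorts of N = 1000: every group × entity adjusted
  prevalence equals the latent-case proportion exactly;
* a 500-replicate recovery study at N = 2000 with response 0.5 and
  sensitivity 1 (MAR): per-cell mean bias within 3 Monte-Carlo SE of zero
  for cells whose expected interviewed-case count is at least 5, measured
  against each replicate's realized latent proportions;
* 500 replicates with case response odds halved: a sign test on the
  per-replicate mean bias must detect negative bias at p < 0.01;
* the chi-square engine against a brute-force $\sum (O-E)^2/E$ oracle on
  1000 random tables (tolerance 1e-10);
* re-derivation of published-style RR displays from rounded prevalence
  pairs, and the participant-flow percentages 16/941 → 1.7% and
  387/758 → 51.1%.

`scripts/acceptance.R` re-runs a reporting-sized subset (50 no-noise
cohorts, 200 + 200 recovery replicates) and writes the resulting
quantities as JSON.

## Known limitations

* **Pooled-group gambling/gaming estimates carry a small aggregation
  bias.** The $PD_2$ reference subset conditions on *not being
  M.I.N.I./ADDIS-interviewed*; within that subset, a screen-positive
  responder is NODS-interviewed only if not M.I.N.I./ADDIS-selected.
  Selection correlates with psychiatric morbidity, hence with legal gender,
  hence — for groups that pool genders — with gambling/gaming prevalence.
  The MAR assumption therefore fails *structurally inside the reference
  subset* for heterogeneous groups. In the recovery study this shows up as
  a bias of about +0.1 percentage points (≈ 3.5 MC SE at 500 replicates)
  for the pooled non-GD group's gambling estimate, while every
  gender-separated cell is unbiased; decomposition confirms the screened
  part of the estimator is clean and the $PD_2 NS_1$ term carries the
  excess, and the bias vanishes when both genders share one prevalence
  profile or when no sub-cohort is unscreened. This is a property of the
  estimator as defined, not of its implementation; gender-separated
  reporting (the design's own rule for orientation groups) avoids it.
* RRs displayed by pooled-reference columns are computed from unrounded
  prevalences; re-deriving them from rounded 1-dp displays can disagree in
  the second decimal, so printed-display checks are only meaningful where
  the rounded pair reproduces the display exactly.
* No confidence intervals, survey weights or multiple-imputation
  alternatives: the pipeline reports the design's point estimates and
  star-coded tests only.
* ASPD/ADHD-type externalizing prevalences in a real cohort may be
  underestimated if attrition correlates with delinquency; the generator
  exposes exactly this mechanism via `inject_informative_attrition()`
  rather than modelling it by default.
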