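---
title: "Ascertaining major bleeding from routine data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertaining major bleeding from routine data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routinebleeds)
```

## The problem

Randomised trials traditionally ascertain safety outcomes such as major
bleeding through direct participant follow-up with blinded clinical
adjudication. Linkage to routinely collected hospital admission and
death-registry data is far cheaper, but routine records were not designed
for trials: ICD-10 coding does not grade bleeding severity, events can be
coded in secondary diagnostic positions or not at all, and a small fraction
of participants cannot be linked. `routinebleeds` implements the pipeline
needed to study whether an algorithmic severity classification applied to
routine records can stand in for adjudicated follow-up: classify, reduce to
per-participant outcomes, measure agreement, and re-run the randomised
comparison under each ascertainment source.

## Severity classification

Bleeding episodes are identified by prefix-matching normalised ICD-10
codes (uppercased, dots stripped; longest prefix wins) against a code map.
The shipped `default_bleed_code_map()` covers intracranial (I60–I62,
S06.4–S06.6), eye (H35.6, H43.1, H45.0), gastrointestinal (variceal and
ulcer bleeding/perforation fourth characters, K29.0, K62.5, K92.0–K92.2)
and other bleeding (epistaxis, haemoptysis, haematuria, vaginal,
unspecified). It is an editable configuration default, not a validated
clinical code list; real analyses should supply the code list actually
agreed by their clinicians.

A `severity_algorithm()` then labels each candidate event major or minor
from the two severity indicators routine data reliably contain:

* **diagnostic position** — was the bleeding code the primary diagnosis?
* **overnight stay** — `discharge_date > admission_date` by at least one
  calendar day. We define "stayed at least one night" by the date
  difference because episode tables carry dates, not duration fields.

The `primary` preset accepts intracranial and eye codes in *any* position
(these events are intrinsically severe), and requires primary position
*plus* an overnight stay for gastrointestinal and other bleeding. Fatal
events — a bleeding code in *underlying-cause* position on the death
record — are always major; a bleeding code in contributory position yields
a non-fatal event that classifies as minor, which keeps the
underlying-cause rule strict without silently discarding the record.

### The 15-algorithm grid

Sensitivity analyses sweep a grid of rule bundles. The historical variant
definitions are not public, so the grid is built on first principles as
the full factorial of {any position, primary only} × {overnight not
required, required} applied separately to the intracranial/eye pair and to
the gastrointestinal/other pair — 16 combinations — minus the single
incongruent one that restricts the severe intracranial/eye pair fully while
leaving gastrointestinal/other unrestricted. That leaves 15 named presets,
anchored by `all_bleeds_major` (strictness 0) and `primary`, ordered by a
strictness score that counts active restrictions. Relaxing any component
can only grow the major-event set, a monotonicity property the test suite
checks over the whole grid.

## Outcome reduction

`derive_outcomes()` produces exactly one record per participant per
(source, outcome): first qualifying event date and time at risk in days.
Decisions where convention was genuinely open:

* **Censoring-date events are inclusive**: an event dated on the end of
  follow-up counts. Some convention is required and exclusion would
  silently drop deaths coded on the censoring date.
* **Same-day ties**: the composite outcome takes the shared date; for
  reporting, categories are listed in the fixed order intracranial > eye >
  gastrointestinal > other. Nothing downstream depends on the tie-break
  because only the date enters the analysis.
* **Events dated outside follow-up** are excluded with a warning naming
  the count — they indicate a data inconsistency and should never vanish
  silently.
* **Unlinked participants** contribute `time_at_risk = 0` and no event to
  the routine source (day-zero censoring), while their direct follow-up is
  unaffected.
* **Pre-adjudication eye bleeds all count as major** in the `direct_pre`
  source: before adjudication a questionnaire cannot distinguish
  sight-threatening from other eye bleeds.

## Agreement statistics

Participants are cross-classified by outcome presence in each source
*irrespective of event timing*; timing is measured separately as the
proportion of both-source participants whose first-event dates fall within
a window (default 90 days).

**Kappa CI.** We use Cohen's original large-sample standard error
$\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ rather than the Fleiss–Cohen–Everitt
variance. For the extreme margins typical of rare outcomes in large
cohorts the two differ in the second decimal of the interval bounds, and
the Cohen form is the one that matches published agreement tables for this
design at their printed rounding. The point estimate is identical either
way; Wilson and exact intervals are provided as options for
sensitivity/specificity, whose default is the Wald interval for the same
reason.

**Discordance breakdown.** Each discordant participant is assigned to
exactly one explanation by the first matching rule, evaluated within the
window around the discordant source's first event date: for
adjudicated-only participants, *bleeding code present but not major* beats
*hospitalised without a bleeding code* beats *no hospital record*; for
routine-only participants, *refuted report nearby* beats *minor bleed
reported* beats *nothing reported*, with an explicit `other` remainder.
First-match assignment guarantees the splits always sum to the discordant
cells — a conservation property the tests assert on every input.

## Randomised comparisons

The treatment comparison uses the one-step log-rank estimator
$RR = \exp((O-E)/V)$ rather than a Cox partial likelihood: it is the
standard estimator in large streamlined-trial reporting, closed-form,
dependency-free, and asymptotically equivalent at these effect sizes. Ties
are handled in aggregate per distinct event time with the hypergeometric
variance (the $\,(n-d)/(n-1)$ correction); a zero total variance is
reported as an undefined rate ratio with a warning rather than a crash.
The test suite pins the implementation to a brute-force risk-set
enumeration oracle at $10^{-10}$ and to `survival::survdiff` on random
instances.

Absolute effects are crude rate differences scaled to events per 5000
person-years with the independent-Poisson standard error — the exact SE
construction used in historical reports is unstated, and the Poisson
approximation is the natural default for arm-wise event counts.

The between-source rate-ratio difference uses a participant-level
bootstrap: each resampled participant carries their records in *both*
sources, preserving the within-participant correlation that makes the
difference far more precise than the two rate ratios individually.
Percentile intervals, default 2000 replicates, mandatory seed. Replicates
with no events in some arm are skipped and counted; more than 10% skipped
triggers a warning. Resampling participants (rather than re-running the
event process) is the choice consistent with conditioning on the observed
cohort.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe a large UK aspirin-versus-placebo primary
prevention cohort: 15,480 participants randomised 1:1 over a 6-year
recruitment window from 2005, administrative censoring at a common
calendar date chosen so mean administrative follow-up is 7.4 years
(≈114,000 person-years before background mortality), latent exponential
time-to-first-event processes per outcome class (hazard ratio 1.3 on major
bleeding, 0.88 on the serious-vascular-event outcome), and a background
non-bleed death hazard of 0.008/person-year acting as competing censoring.

Capture is per-event Bernoulli, independent across sources. The defaults
were back-solved once from the published cross-classification margins:
with sensitivity ≈0.57 and 318 both-source events among 559 adjudicated,
the latent first-event count must be ≈1050, giving a control-arm latent
hazard of 0.008/person-year and `p_routine_capture = 0.57`,
`p_direct_capture = 0.53`. Majors that fail routine capture leave a
non-qualifying bleeding code, a no-bleeding-code hospitalisation, or no
record in the proportions 0.307/0.386/0.307 observed for linked UK trial
data; spurious questionnaire reports (4.6% of participants, eye-heavy)
are refuted on adjudication; minor bleeds and background hospitalisations
(0.10/person-year) supply realistic noise; 0.3% of participants are
unlinked. Questionnaire dates carry rounded N(0, 30 days) recall error.

Deliberately **not** modelled: recurrent events beyond the first per
class (the analyses are time-to-first-event), geographic heterogeneity of
linkage beyond a single unlinked probability, coding-practice drift over
calendar time, correlated capture failures (e.g. one hospital failing to
code bleeds for all its admissions), and heavy-tailed recall error. A
passing test suite therefore shows the *pipeline* is correct under a
plausible generating process, not that any particular real dataset
satisfies these independence assumptions.

```{r}
coh <- simulate_cohort(sim_config(n_participants = 2000, seed = 1))
coh
```

## Reference tables

The published agreement and adjudication tables ship as reference data so
the headline statistics can be recomputed exactly from printed counts.
Two reconstruction points deserve note:

* The adjudication cross-tabulation counts first events per participant
  *per pre-category* (1279), while overall refutation rates are quoted on
  first events per participant (1215, of which 710 refuted).
  `reference_adjudication_reports()` is a deterministic synthetic
  report-level table satisfying both simultaneously: 64 eye reports are
  second events of participants whose first is a confirmed
  gastrointestinal bleed, and 71 pre-minor reports upgraded to major on
  adjudication supply the published major column totals while staying out
  of row confirmation rates. Only the printed marginals constrain it; the
  duplicate assignment is one consistent choice and is documented as
  synthetic.
* Gastrointestinal subsite confirmation (upper 135/162, lower 71/149) is
  quoted on a basis that cannot be reconciled with the cross-tabulation
  row (the two subsites alone exceed the row's confirmed count), so
  subsite rates are computed from their own numerators and denominators
  (`reference_gi_subsites()`), never derived from the matrix.

## Numerical conventions

* Display rounding is half-away-from-zero (`round_half_up()`), matching
  how published tables are printed; all internal computation is double
  precision and unrounded.
* Dates are ISO-8601 `Date`s; day 0 is the randomisation date; times at
  risk are integer days, converted to person-years with 365.25.
* Degenerate inputs are reported, never guessed: kappa with degenerate
  margins, sensitivity with an empty reference class, a log-rank variance
  of zero and an empty timing-concordance cell all return `NA` with a
  warning or explicit count.

## Scale of the validation experiments

The test suite runs the property-based checks at sizes chosen to make the
Monte-Carlo error small relative to the tolerance being asserted:
parameter recovery on 20 cohorts of 50,000 participants (accepting rate
ratios in [1.2, 1.4] under a true 1.3), null calibration on 500 cohorts of
5,000 (95% CI coverage within 92–98%), attenuation of the diluted
`all_bleeds_major` comparison on 20 cohorts of 20,000, and oracle
agreement on 200 random small survival instances. The full suite completes
in about a minute on one core.

## Known limitations

* The shipped code map and algorithm grid are plausible defaults, not the
  historical clinical configurations, which are not public. Both are
  injectable.
* The kappa interval method behind published tables is inferred from
  agreement with their printed bounds, not from a stated formula.
* Cross-source agreement statistics inherit the usual caveat that the
  adjudicated reference itself misses events; sensitivity and specificity
  are relative to that imperfect reference.
* The one-step log-rank estimator shrinks very slightly toward the null
  for large effects; at rate ratios near 1.3 the bias is well under the
  Monte-Carlo tolerances used here.
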