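---
title: "Constructing lines of therapy and attrition tables from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing lines of therapy and attrition tables from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmlot)
```

## The problem

Newly diagnosed multiple myeloma (NDMM) is treated in successive *lines of
therapy* (LOT): a frontline regimen, then — on relapse or intolerance — a
second line, a third, and so on. In administrative claims data no field
says "this is line 2"; lines must be reconstructed from the dispensing and
administration records of anti-myeloma agents. Once lines exist, the
quantity of scientific interest is *attrition*: the fraction of patients at
each line with no record of the next one, because they died or because no
subsequent treatment appears in their observable follow-up. mmlot
implements that reconstruction, the surrounding cohort machinery
(eligibility filters, follow-up windows, transplant stratification,
comorbidity scoring), the attrition and predictor analyses, and a seeded
synthetic claims generator so that the entire pipeline is testable without
access to any proprietary claims database.

## The line-of-therapy rule

A line is identified from an initial administration of one or more
anti-myeloma agents and continues until **either** (a) a regimen agent is
discontinued for at least `discontinuation_gap_days` (default 60 days),
**or** (b) an agent outside the regimen is administered. In detail:

* **Exposure.** Each claim covers `[date, date + days_supply - 1]`. Oral
  dispensings carry their recorded supply; parenteral administrations
  (e.g. bortezomib infusions), which carry no supply in claims, cover a
  configurable administration cycle (`administration_default_supply_days`,
  default 7 days). Covered spans of one agent separated by at most
  `merge_gap_days` (default 0 — only overlap/abutment) merge into exposure
  intervals.
* **Regimen formation.** The line starts at the earliest remaining claim;
  agents with a claim within `regimen_formation_window_days` (default 60)
  of that start form the regimen. A formation window is standard in claims
  LOT algorithms because combination regimens start staggered across
  pharmacy fills; the window can be set to 0 to run the literal rule, under
  which any staggered start fragments the combination.
* **Line end.** The line ends at the *earliest* of: the day before the
  first claim of a non-regimen agent after the formation window
  (`new_agent`); the last covered day of the first regimen agent whose
  exposure lapses `>= 60` days while follow-up continues (`gap`); or
  follow-up end / death (clipped). When a gap end and a new-agent end
  coincide, `new_agent` wins — the new agent's start defines the next line
  unambiguously. Note the earliest-*end* convention: a 60-day lapse whose
  last covered day precedes a new agent's arrival ends the line at the
  lapse even though the lapse is only confirmed later in calendar time.
* **Next line.** The next line starts at the next claim
  (administration) after the line end. Keying this to claims rather than to
  merged exposure intervals matters: an agent whose coverage straddles a
  line boundary re-enters the following line through its next fill, so a
  de-escalation (say VRd to Rd) leaves the continuing lenalidomide and
  dexamethasone inside the new line rather than ownerless.
* **Steroids.** Dexamethasone/prednisone are ubiquitous co-medication:
  with `steroids_trigger_new_line = FALSE` (default) a steroid starting
  after the window neither ends nor starts a line, but a steroid inside the
  window still counts in the regimen set (Vd is distinct from V).
* **Modes.** `line_end_mode = "any_agent_discontinued"` (default) follows
  the literal ">= 1 agent discontinued" reading; consequently a partial
  de-escalation ends the line and the surviving agents open the next one.
  The `"all_agents_discontinued"` alternative treats a line as alive while
  any regimen agent continues, which many analysts prefer for real-world
  data where dropping dexamethasone should arguably not end a line.
* **Restarts.** A restart of the identical regimen after a >= 60-day gap
  counts as a new line (the literal rule says yes).

Durations are day spans divided by 30.4375 (the mean Gregorian month),
with a one-day floor so a single-day line has a defined, positive length;
"4 months" and "1 month" in the consolidation rule are rendered as 122 and
30 days to keep calendar arithmetic deterministic.

## Transplant phases

For patients with an autologous stem cell transplant (ASCT), the line
active at (or most recently before) the first ASCT is labelled
*induction*. Post-ASCT treatment is folded into that line as
*consolidation* — not a new line — iff it begins within
`consolidation_window_days` (122) of ASCT, persists at least
`consolidation_min_duration_days` (30) beyond ASCT, and its agent set
equals or contains the induction regimen. An induction line whose own
exposures simply continue past ASCT satisfies the same definition. Anything
else (for example a subset regimen such as lenalidomide alone after VRd
induction) starts the next line, and a patient whose last
treatment-related event is the ASCT itself remains single-line. ASCT
events preceding any observed exposure cannot be phase-labelled and are
counted in a warning.

## Cohort rules and follow-up

Inclusion requires, in order: an index MM diagnosis (first MM code) on or
after 2007-01-01; known sex; medical *and* pharmacy coverage active at
index; 365 days of continuous coverage before index (a configurable
`coverage_gap_days` bridge between intervals, default 0, since claims
conventions often bridge 30-45 days); no prior-malignancy code in the
look-back year; and at least one constructed line. Every step is logged
with before/excluded/after counts. Follow-up ends with continuous
eligibility for claims-type sources (the earlier end of the two coverage
kinds' merged intervals containing index) and at the last observed
activity for EMR-type sources; death truncates either. Age at diagnosis is
index year minus birth year, as full birth dates are rarely carried in
claims.

## Comorbidity scoring

Named comorbidity flags (cardiac arrhythmia, congestive heart failure,
complicated and simple hypertension, hepatic disease, pulmonary
circulation disorders, renal impairment, valvular disease) are set by a
single qualifying diagnosis in the 180 days before the anchor — either the
index diagnosis or the first-LOT start; both anchors are first-class
because different baseline tables use different ones. Complicated
hypertension suppresses simple hypertension. The four cardiovascular
conditions collapse into one composite covariate for modelling. The
Charlson Comorbidity Index uses the classic 17-category weights shipped as
a data file (`inst/extdata/code_map.csv`); each category counts once,
severe forms suppress mild forms, and the index MM code itself is excluded
from the score by default (configurable) so cohort membership does not
mechanically add the malignancy weight. The code map uses synthetic
`DX_*` codes matching the generator; real deployments supply their own
ICD dialect as a CSV.

## Attrition and disposition

At each line k, patients split exhaustively into *subsequent treatment*
(a line k+1 exists), *death* (no further line and death within follow-up)
and *no subsequent treatment in follow-up*. A patient who starts line k+1
and later dies is a transition at k, not a terminal state, which is what
makes the three columns partition each line's cohort. The attrition
percent at line k is `100 * (1 - n_k / n_(k-1))`. Duration summaries use
the arithmetic mean, the n-1 sample SD (undefined and blank at n = 1),
and the midpoint median. All rounding (one decimal) happens only in the
presentation layer.

## Inference

Group comparisons use uncorrected Pearson chi-squared tests for
categorical characteristics — the stratified Cochran-Mantel-Haenszel
statistic when a stratification variable is supplied; with a single
stratum the general-association statistic reduces to the ordinary
chi-squared, which is the declared default since no stratification
variable is specified for the published comparisons — and two-sample
t-tests for continuous ones (Welch by default; pooled-variance available).
Receipt of a subsequent line is modelled by maximum-likelihood logistic
regression on age category (reference 65-74), sex, the cardiovascular
composite, liver disease, pulmonary circulation disorders and renal
impairment, overall and within 6+/12+/24+ month follow-up subsets
(follow-up measured from first-LOT start) to account for censoring. Wald
95% intervals and p-values are reported per non-reference term; IRLS runs
to tolerance 1e-8 (max 50 iterations), and separation is flagged (absurd
coefficient or standard error) rather than silently reported. No
multiple-testing correction is applied, matching the analysis the package
reproduces.

## Small-cell suppression

Counts of 1-10 are never published (zero is exempt). Secondary suppression
iteratively masks the smallest remaining nonzero cell of a margin group
until no masked cell can be pinned down by a reader who knows the margin
and that masked counts are >= 1; this covers both the classic
single-suppression back-subtraction and the degenerate all-ones case
(masked cells summing to their own count force every cell to 1). When no
complementary cell is eligible the row margin itself is flagged for
suppression. The property tests verify with an exhaustive back-solver that
every masked cell admits at least two feasible values.

## What the generator emulates — and what it does not

`simulate_population()` draws each patient's journey line by line with
per-line continuation and death probabilities per transplant stratum; the
defaults are calibrated so the downstream pipeline reproduces the shape of
the published attrition table (continuation 0.431/0.545/0.573/0.574/0.580
non-transplant, 0.790/0.692/0.631/0.648/0.629 transplant; death fractions
0.129/0.122/... and 0.013/0.027/...). Line durations are log-normal with
meanlog/sdlog solved from the published per-line mean and median months;
between-line gaps are 61 days plus an exponential tail (mean 30 days) so
planted lines stay recoverable; treatment starts 0-60 days after index;
deaths fall within 90 days of the last line; comorbidity events are
planted uniformly in the 180 days before index at published prevalences;
ages are normal (non-transplant mean 72, transplant 64, truncated to
20-100); 60.9% of transplant patients carry an observable frontline
induction before ASCT and 11.1% of those a consolidation segment. A
configurable violation fraction injects >= 60-day intra-line holes and
late add-on agents to exercise the engine, and a per-year eligibility-loss
hazard can additionally truncate coverage (off by default, because the
journey probabilities already absorb loss to follow-up).

The generator does **not** emulate: ICD coding noise or code dialects,
dose/schedule structure within a cycle, payer switching and re-enrolment,
regimen changes correlated with comorbidity, costs, or death-date
misclassification across sources (death availability is a per-source
question the generator sidesteps by carrying one death date). Passing
tests therefore demonstrate algorithmic correctness under clean,
rule-conforming data and statistical recovery of known truth — not
robustness to real-world coding pathologies.

## Numerical and design choices

* Month constant 30.4375 days everywhere; follow-up months have no floor
  (a same-day window is 0), line durations have a 1-day floor.
* Ties between gap and new-agent events resolve to `new_agent`.
* Continuation + death must sum to <= 1 per line; categorical mixes must
  sum to 1 within 1e-9; every probability is validated with the offending
  field named in the error.
* Patients with exposures but no follow-up window (ineligible at index)
  are dropped from segmentation with a counted warning; unknown agents are
  skipped and counted, never silently reclassified.
* Empty inputs return typed empty tibbles; an empty stratum produces
  zero-count rows with blank percentages.
* The demo problem sizes used by the test-suite — 1,000 random claim
  streams for engine/oracle equivalence, a 20,000-patient population for
  continuation-probability recovery (within 3 binomial standard errors),
  n = 10,000 for logistic null/effect recovery, 200 fuzzed tables for
  suppression safety — were chosen as the smallest sizes at which the
  statistical tolerances are meaningful.

## Known limitations

* The published business-rule supplement for line construction is not
  public; the formation window, steroid handling and restart rules above
  are declared defaults, each exposed as configuration rather than code.
* Under `any_agent_discontinued`, staggered agent stops can split what a
  clinician would call one line; the all-agents mode is provided but the
  default follows the literal rule.
* Cross-database patient deduplication, Medicare Advantage exclusion
  mechanics and race harmonisation across sources are out of scope; the
  cohort machinery assumes one coherent patient table.
* Attrition conflates death, true treatment cessation and loss to
  follow-up wherever eligibility ends silently — the same limitation the
  underlying study design carries; no survival analysis is attempted.
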