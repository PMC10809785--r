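---
title: "Methods: rule-based survivorship care planning and the calibrated synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based survivorship care planning and the calibrated synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survplan)
```

`survplan` is an offline engine for organizing long-term follow-up (LTFU)
after childhood and young-adult cancer. Survivors carry organ-specific risks
determined by their treatment exposures — cumulative anthracycline dose,
radiation dose to individual organs, alkylating agents, platinum compounds,
transplantation, surgical organ loss — and international harmonized
guidelines (IGHG, complemented by PENTEC dose–effect reports where
radiotherapy precision is needed) map those exposures to surveillance
recommendations. This vignette explains the models and design decisions
behind each component, and what the tests do and do not demonstrate.

## The data model

A patient record is a structured oncological history: one or more diagnoses
(nine disease categories), each with numbered treatment lines carrying
surgery records (carcinological impact: completeness of resection;
functional impact: none / partial / complete removal of the organ),
chemotherapy courses with per-agent cumulative doses (mg/m² unless an
agent's catalogue entry declares mg/kg; no silent unit conversion),
radiotherapy courses (anatomical fields and prescribed dose always; mean
organ doses from dose–volume histograms when dosimetry is available),
transplantation, and supportive care. Follow-up events (late effects with
optional CTCAE v5 grades, organ losses), predisposition syndromes,
lifestyle and social data complete the record.

Design choices worth stating:

* **Closed vocabularies.** Organ and field codes are closed, versioned code
  lists shipped as CSV; unknown codes are rejected, never coerced. The
  field→organ exposure map (supra-diaphragmatic → breast, heart, lung,
  thyroid, esophagus; cervical → thyroid, salivary glands, carotid, ...;
  TBI → every organ) is an editable data file, because exposure sets are a
  clinical modelling decision, not code.
* **Dates and ages.** Dates are ISO-8601 calendar dates; ages are exact
  elapsed days divided by 365.25 — deterministic and timezone-free.
  Eligibility (age under 25 years) is checked **at the date of first
  diagnosis**; whether the bound applies at diagnosis or treatment start is
  ambiguous in practice, and diagnosis is the stricter, simpler reading.
* **Explicit cancer rank.** Second cancers may be registered
  retrospectively and out of order, so `cancer_rank` is stored, not
  inferred from dates.

## Three-valued plan generation

The rule base is declarative data: 53 endpoints (complementary
examinations, specialized consultations, educational tools), each with 1 to
34 conditions pairing a predicate over derived facts with a frequency, an
evidence level and a bibliography. Predicates are AND/OR/NOT trees whose
leaves compare facts (`cumulative_dose(doxorubicin) >= 250`,
`organ_mean_dose(breast) >= 10`, `sex == female`, ...) — editable YAML, so
clinical updates never require code changes. The packaged rule base is
assembled from public surveillance topics and is **illustrative, not for
clinical use**; its structure (53 endpoints, one of which carries 34
conditions) exercises every bound the engine enforces. Evidence levels use
a five-value ordinal scale (`high` … `very_low`, plus `expert_consensus`),
declared in the rule base header so an alternative grading system can be
swapped in.

The central modelling problem is **missing data**. Organ dosimetry is often
absent for older records: the field and prescribed dose are known, but not
what the organ actually received. We represent every fact as a typed value
or UNKNOWN, and evaluate predicates under strong Kleene three-valued
logic: a comparison against UNKNOWN is UNKNOWN; `TRUE OR UNKNOWN = TRUE`;
`FALSE AND UNKNOWN = FALSE`; `NOT UNKNOWN = UNKNOWN`. The fact derivation
rule for organ doses is:

* recorded dosimetry → the recorded mean dose (summed over courses), and
  organs absent from a complete dosimetry are treated as spared (dose 0);
* organ inside an irradiated field of a course without dosimetry → UNKNOWN
  (never 0);
* organ in no irradiated field → 0.

UNKNOWN means **propose with a caveat, not omit**: an endpoint whose best
condition is UNKNOWN enters the plan with `data_quality = "degraded"` and
the missing fact keys listed, because under-surveillance is the costly
error. Conversely, dosimetry showing a spared organ evaluates FALSE and
suppresses the proposal — the reward for precise data is a leaner plan.
When several conditions of one endpoint match, the item takes the
**shortest interval and the highest evidence level** among them (the most
protective combination; any other aggregation would let a weak condition
dilute a strong one). Endpoints targeting an organ whose status is
`removed` (complete surgical removal, or an organ-loss follow-up event as
of the generation date) are excluded with a logged suppression reason:
second-tumor surveillance of an organ that no longer exists is not only
useless but harmful noise. Organ-unspecific endpoints (e.g. thyroid
*function* testing after thyroidectomy) carry no target organ and survive.

Physician modifications (deselect, accept, modify frequency, annotate, add
endpoint) each append exactly one audit entry with before/after snapshots;
the audit log is append-only and replaying it onto the originally generated
plan reproduces the modified plan (event sourcing). Plans are pure
functions of (patient, rule base, exposure map, date) — `generated_at` is
the supplied date, not the wall clock, so regeneration is reproducible. A
physician's deselection is *not* silently re-applied after regeneration
with new data: the audit log preserves the history and the two plans can be
diffed, which we prefer to guessing precedence between an old deselection
and new clinical facts.

## The calendar

Accepted items become due-date series `anchor + start_offset + k·interval`
(anchors: end of treatment, diagnosis, or a fixed age), bounded by a
horizon (default 5 years ahead, regenerated on demand to keep schedules
finite) or by the item's end bound (an age, or lifelong). Pauses
(pregnancy, intercurrent health events, long trips) use **shift-then-
respace** semantics: a due date inside a closed pause moves to the first
day after the pause and the series re-spaces from there — a missed
examination is delayed, never dropped, because the surveillance intent is
"every N years from the last one", not "on fixed calendar slots". An
open-ended pause suspends all later entries until it is closed. A permanent
stop (e.g. replanning from initial follow-up to LTFU) cancels all pending
entries and is irreversible on that schedule object. Notifications are
window-based queries addressed to both the patient and the attending
physician (callers choose the lead time by choosing the window; 30 days is
a sensible default), marking is idempotent, and the overdue flag
(`due + grace < today`, grace defaulting to 3 months, configurable)
identifies survivors becoming less responsive to follow-up. The whole
calendar is a pure function of (plan, anchors, pauses, stop), verified by
regeneration tests.

## Summaries, exports, deprivation

The harmonized treatment summary renders the full oncological history —
including an explicit *"precise dosimetric data missing"* caveat for
radiotherapy courses without dosimetry, and per-agent cumulative doses
summed across all lines — as Markdown and JSON for deposit in the medical
record. Cumulative doses entered from a protocol/arm catalogue keep
`source = "table_default"` and must equal the catalogue value; per-patient
adaptations are flagged `adapted`.

Research exports replace patient ids with generated 12-character
identifiers computed from a keyed hash: the same key reproduces the same
identifiers (stable longitudinal exports), a different key yields an
unrelated set, and without the key the identifier carries no information
about the patient id (it is keyed generation, not a bare hash of
identity). Birth dates are reduced to birth year with ages pre-computed —
data minimization without implementing legal machinery. Non-consenting
patients are excluded and counted in the export manifest.

Area deprivation uses the European Deprivation Index: per-unit scores are
cut into quintiles **within each department** at the 20/40/60/80
percentiles, quintile 1 the most affluent. The tie rule is min-rank with a
ceiling cut (`⌈5·rank/n⌉`), so tied scores share the lower quintile —
deterministic, and degenerate inputs (all scores equal) land everyone in
quintile 1 rather than splitting ties arbitrarily. Units with missing
scores are reported as unknown, never imputed. Geocoding addresses to
units is out of scope; inputs are pre-resolved unit codes.

## The synthetic cohort generator

No survivor-level dataset ships with the package, so every engine path is
exercised by a generator calibrated to a published registered-cohort
profile (n = 2558). The `table1` preset encodes, at full count-derived
precision where counts exist: the nine-category disease mix (leukemia
28.3 %, cerebral tumors 19.8 %, ...), sex ratio (54.4 % boys), mean age at
diagnosis 8.34 years on [0, 23.2], first-line marginals — surgery 41.5 %
(16.1 % of whom had surgery alone), medical treatment 87.1 % (the
count 2228/2558; the source table's percentage column misprints this
value, and the printed figure is arithmetically incompatible with the
monitoring and surgery-only shares), radiotherapy 20.5 %, radiotherapy AND
medical treatment 18.6 %, autotransplant 3.6 %, allograft 3.8 %, simple
monitoring 3.8 % — tumor-bank availability 66.54 %, recurrences 12.8 %
with the recurrent subgroup composed 33.3 % cerebral / 23.8 % leukemia /
15.9 % sarcoma (the remainder spread over the other categories
proportionally to prevalence), and second cancers 1.6 % with the reported
type mix (11 sarcomas, 10 cerebral tumors, 6 leukemias, 5 lymphomas, 5
adult-type, 3 rare per 40). "Had both" is read as radiotherapy AND medical
treatment — the adjacent-sentence reading — and is a preset parameter so
the alternative interpretation is one configuration edit away.

Mechanics and declared choices:

* **Age at diagnosis** is gamma-distributed (shape 1.6, a right-skewed
  family that is the standard choice for a nonnegative age-at-onset
  variable when only mean and range are known), truncated to [0, 23.2],
  with the scale solved numerically so the truncated mean equals 8.34.
  Sampling is by inverse CDF on the truncated distribution.
* **Treatment profiles** are drawn from an explicit five-cell categorical —
  simple monitoring, surgery-only, radiotherapy-only, radiotherapy and
  medical treatment, medical treatment only — with additional
  (non-exclusive) surgery layered over the treated cells. The published
  marginals do not quite close: about 0.6 % of the cohort can belong to
  none of these cells as printed, so that slack is absorbed by the
  surgery-only cell. As a result the monitoring, surgery, medical,
  radiotherapy and joint radiotherapy-and-medical marginals hold exactly,
  and only the surgery-only share among surgery patients drifts (17.5 %
  generated vs 16.1 % printed).
* **Plausible sub-records.** Each treated modality is instantiated
  concretely: chemotherapy courses pull agents and theoretical cumulative
  doses from the packaged protocol catalogue (illustrative protocols per
  disease), radiotherapy courses draw a disease-appropriate field with a
  prescribed dose, and half of them include organ dosimetry — the other
  half exercise degraded mode. Allografted patients receive TBI-based
  conditioning. Recurrent patients get a numbered second line (with the
  reported allograft share among second lines); second cancers become
  additional ranked diagnoses.
* **Coverage quota.** After generation the cohort is patched, if needed,
  to contain at least one radiotherapy course without dosimetry, one
  complete organ removal and one confirmed predisposition carrier, so that
  downstream engine tests always meet every code path even at small n.
* **Determinism.** One seed drives everything; the same (preset, n, seed)
  reproduces the identical cohort byte for byte.

The generator emulates *marginal* structure, not joint clinical realism:
it does not model survival or mortality, era effects across the 1967–2022
recruitment span, correlations between dose intensity and stage, or
realistic protocol names. Passing round-trip tests therefore shows that
the generator and profiler agree and that the engine behaves correctly on
structurally realistic records — not that any clinical conclusion
transfers to real data.

**Test scales.** The generator/profiler round trip is tested at the
cohort's actual size (n = 2558, within 3 binomial standard errors per
marginal; 3 standard errors of the mean for age) and the law-of-large-
numbers convergence test runs at n = 100 000. Property suites use fixed
seeds throughout.

## Numerical and degenerate-input choices

* Period arithmetic is calendar-aware with day-of-month clamping
  (Jan 31 + 1 month = Feb 28/29); interval ordering for "most frequent"
  uses mean Gregorian month/year lengths.
* Truncated-gamma calibration solves the scale by `uniroot` to 1e-10 —
  deterministic to machine precision across platforms.
* An empty plan, an empty cohort and an empty schedule are legal values,
  reported with null percentages rather than NaN.
* Contradictory conjunctions in a rule base (e.g. `age ≥ 30 AND age ≤ 20`)
  load fine but are reported as warnings by the structural validator, via
  an interval-emptiness check on numeric leaves under pure conjunctions.

## Known limitations

The shipped rule base is structurally conformant but clinically
illustrative; thresholds and frequencies are representative placeholders.
Chemotherapy dose facts compare mg/m² quantities and do not convert
mg/kg-dosed agents. The exposure map is binary (exposed / not exposed) and
does not grade partial organ coverage within a field. Pauses interact with
already-notified entries by re-deriving the calendar; a notified entry
whose date shifts reverts to pending. Deselections do not persist across
plan regeneration (surfaced via the audit log instead). Only departmental
EDI quintiles are implemented.
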