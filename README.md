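# survplan

Survivors of childhood and young-adult cancer carry lifelong, organ-specific
risks determined by what treated them: cumulative anthracycline dose,
radiation dose to individual organs, alkylating agents, platinum compounds,
transplantation, surgical organ loss. International harmonized guidelines
(IGHG, complemented by PENTEC dose–effect reports for radiotherapy) map
these exposures to surveillance recommendations, but applying them by hand
to a 20-year-old treatment chart is error-prone — and the chart is often
incomplete, most typically missing per-organ dosimetry.

`survplan` is an offline R engine for this problem, aimed at long-term
follow-up (LTFU) teams and survivorship-informatics developers. From a
structured treatment summary it:

* evaluates a declarative **guideline rule base** — 53 endpoints
  (examinations, consultations, educational tools), each with 1–34
  conditions pairing a predicate over derived facts with a frequency and an
  evidence level — under **strong Kleene three-valued logic**: a fact such
  as `organ_mean_dose(breast)` is UNKNOWN (not 0) when the breast lay in an
  irradiated field without dosimetry, and `TRUE ∨ U = TRUE`,
  `FALSE ∧ U = FALSE`, `¬U = U`. UNKNOWN means *propose with a caveat*
  (`data_quality = "degraded"`), never omit — while recorded dosimetry
  showing a spared organ evaluates FALSE and suppresses the proposal, and
  a surgically removed organ suppresses its second-tumor surveillance with
  a logged reason;
* turns the validated plan into a **surveillance calendar**
  (`anchor + offset + k·interval`) with pauses (shift-then-respace),
  permanent stops, window-based notifications to patient and attending
  physician, and overdue detection;
* renders a **harmonized treatment summary** (Markdown/JSON), resolves
  theoretical cumulative chemotherapy doses from a protocol/arm catalogue,
  and exports **pseudonymized cohort tables** (keyed generated identifiers,
  birth year only, consent-aware);
* assigns **European Deprivation Index quintiles** within departments
  (quintile 1 most affluent, ⌈5·rank/n⌉ with min-rank ties);
* generates **synthetic survivor cohorts** calibrated to a published
  registered-cohort profile (n = 2558: disease mix, sex ratio, age
  distribution, first-line treatment marginals, tumor-bank rate,
  recurrences, second cancers), so every engine path is testable without
  real data.

The shipped rule base is structurally conformant and clinically
illustrative — **not a medical product**.

## Worked example

```r
library(survplan)

p <- validate_patient(example_patient())
p
#> <survplan_patient PT-000001> female, born 2005-04-12
#>   first diagnosis: lymphoma (2018-03-01, age 12.9 y), 1 diagnosis/es, 1 treatment line(s)

plan <- generate_plan(p, load_rulebase(), as_of = "2024-01-01")
plan$items[["breast_imaging"]]$data_quality
#> [1] "degraded"
plan$items[["breast_imaging"]]$missing_data_notes
#> [1] "organ_mean_dose(breast)"
```

This survivor received 200 mg/m² doxorubicin and supra-diaphragmatic
radiotherapy **without organ dosimetry**. Printing the plan shows the
consequences: echocardiography is proposed every 2 years (the anthracycline
dose alone matches the moderate rule at 5-yearly, but the cardiac-dose rule
*might* apply, so the shortest interval wins and the item is flagged), and
breast imaging is proposed with the explicit caveat that precise dosimetric
data are missing:

```
<survplan_plan> patient PT-000001, rule base 2026.1-illustrative, generated 2024-01-01
  17 item(s) (11 degraded), 0 suppressed, 0 audit entr(ies)
  - echocardiography    (complementary_examination) every P2Y [high]  DEGRADED: missing organ_mean_dose(heart)
  - breast_imaging      (complementary_examination) every P1Y [high]  DEGRADED: missing organ_mean_dose(breast)
  - thyroid_ultrasound  (complementary_examination) every P1Y [moderate]  DEGRADED: missing organ_mean_dose(thyroid)
  ...
```

Had the radiotherapy course carried dosimetry showing a spared breast
(mean dose 0.4 Gy), `breast_imaging` would be absent. A thyroidectomy
recorded during follow-up suppresses `thyroid_ultrasound` with a logged
reason while thyroid *function* testing survives.

Scheduling and audit:

```r
sched <- build_schedule(plan, patient_anchors(p))
head(sched$entries$due_date[sched$entries$endpoint_id == "echocardiography"])
#> [1] "2020-09-20" "2022-09-20" "2024-09-20" "2026-09-20" "2028-09-20"
plan2 <- apply_modification(plan,
  list(type = "deselect", endpoint_id = "breast_imaging"), actor = "dr_x")
length(plan2$audit_log)   # every modification traced, replayable
#> [1] 1
```

Synthetic cohorts:

```r
cohort <- generate_cohort(cohort_preset("table1"), n = 2558, seed = 1)
cohort_profile(cohort)
#> <survplan_profile> n = 2558
#>   mean age at diagnosis 8.56 y [0.1-23.1]
#>   male 55.4%, tumor bank 67.6%
#>   ...
#>   first line: surgery 42.3%, medical 87.3%, RT 20.6%, RT+medical 18.9%, ...
```

A thin command-line wrapper ships at `inst/cli/survplan`
(`survplan validate`, `generate-plan`, `schedule`, `simulate`, `profile`,
`export`, `edi-quintiles`, ...).

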