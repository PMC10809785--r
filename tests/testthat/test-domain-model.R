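test_that("valid records are accepted and canonicalized", {
  p <- validate_patient(make_patient(
    surgeries = list(surgery_record("kidney", functional = "partial_removal",
                                    carcinological = "complete_resection"))))
  expect_s3_class(p, "survplan_patient")
  expect_equal(p$diagnoses[[1]]$treatment_lines[[1]]$surgeries[[1]]$carcinological_impact,
               "complete_resection")
  # a line with no treatment at all is legal "simple monitoring"
  mon <- validate_patient(make_patient())
  expect_true(is_monitoring_line(mon$diagnoses[[1]]$treatment_lines[[1]]))
})

test_that("schema violations are rejected with the offending field named", {
  bad_grade <- make_patient(follow_up_events = list(
    list(date = "2020-01-01", organ_category = "thyroid",
         event_type = "late_effect", ctcae_grade = 7)))
  expect_error(validate_patient(bad_grade), "ctcae_grade")

  bad_surgery <- make_patient(surgeries = list(
    surgery_record("kidney", carcinological = "partial")))
  expect_error(validate_patient(bad_surgery), "carcinological_impact")

  bad_organ <- make_patient(surgeries = list(surgery_record("elbow")))
  expect_error(validate_patient(bad_organ), "organ")

  no_dx <- make_patient()
  no_dx$diagnoses <- list()
  expect_error(validate_patient(no_dx), "diagnos")

  gap <- make_patient(extra_lines = list(list(
    line_number = 3, start_date = "2017-01-01", end_date = "2017-06-01")))
  expect_error(validate_patient(gap), "numbered 1")

  dosim <- make_patient(rt_courses = list(
    list(start_date = "2016-01-05", end_date = "2016-02-20",
         fields_irradiated = list("cranial"), prescribed_dose = 30,
         organ_doses = list(), dosimetry_available = TRUE)))
  expect_error(validate_patient(dosim), "dosimetry_available")
})

test_that("eligibility requires age under 25 years at first diagnosis", {
  too_old <- make_patient(birth_date = "1990-01-01", dx_date = "2015-06-01")
  expect_error(validate_patient(too_old), "inclusion")
  # 24.9 years is eligible
  ok <- make_patient(birth_date = "1990-08-01", dx_date = "2015-06-01")
  expect_s3_class(validate_patient(ok), "survplan_patient")
})

test_that("validation is idempotent and survives a JSON round trip", {
  p <- validate_patient(make_patient(
    chemo_courses = list(chemo_course(c(doxorubicin = 150.5))),
    rt_courses = list(rt_course("cervical", 30, organ_doses = c(thyroid = 28.4)))))
  expect_identical(validate_patient(p), p)
  f <- tempfile(fileext = ".json")
  write_patient(p, f)
  expect_identical(read_patient(f), p)
})

test_that("organ status follows the functional-impact / organ-loss truth table", {
  # hand-enumerated expectations over (surgery functional impact x event)
  cases <- list(
    list(surg = NULL, event = FALSE, expected = "intact"),
    list(surg = "none", event = FALSE, expected = "intact"),
    list(surg = "partial_removal", event = FALSE, expected = "partially_removed"),
    list(surg = "complete_removal", event = FALSE, expected = "removed"),
    list(surg = NULL, event = TRUE, expected = "removed"),
    list(surg = "partial_removal", event = TRUE, expected = "removed"))
  for (cs in cases) {
    p <- make_patient(
      surgeries = if (is.null(cs$surg)) list() else
        list(surgery_record("kidney", functional = cs$surg)),
      follow_up_events = if (cs$event)
        list(list(date = "2020-05-01", organ_category = "kidney",
                  event_type = "organ_loss", description = "nephrectomy")) else list())
    st <- derive_organ_status(p, as_of = "2024-01-01")
    expect_equal(unname(st[["kidney"]]), cs$expected,
                 label = paste("surg =", cs$surg %||% "none", "event =", cs$event))
    # organs never mentioned stay intact
    expect_equal(unname(st[["thyroid"]]), "intact")
  }
})

test_that("organ removal is monotone in time", {
  p <- make_patient(follow_up_events = list(
    list(date = "2020-05-01", organ_category = "thyroid",
         event_type = "organ_loss", description = "thyroidectomy")))
  expect_equal(unname(derive_organ_status(p, "2019-12-31")[["thyroid"]]), "intact")
  for (d in c("2020-05-01", "2021-01-01", "2030-01-01"))
    expect_equal(unname(derive_organ_status(p, d)[["thyroid"]]), "removed")
})

test_that("calendar periods parse and add calendar-safely", {
  expect_equal(format(parse_period("P1Y6M")), "P1Y6M")
  expect_error(parse_period("P"), "period")
  expect_error(parse_period("2Y"), "period")
  expect_equal(add_period(as.Date("2020-06-01"), "P2Y"), as.Date("2022-06-01"))
  # day-of-month clamping
  expect_equal(add_period(as.Date("2020-01-31"), "P1M"), as.Date("2020-02-29"))
  expect_equal(add_period(as.Date("2021-01-31"), "P1M"), as.Date("2021-02-28"))
  expect_equal(add_period(as.Date("2020-06-01"), "P2Y", k = 3), as.Date("2026-06-01"))
})
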