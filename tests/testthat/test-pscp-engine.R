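rb <- load_rulebase()
emap <- load_exposure_map()

test_that("derived facts encode recorded doses, degraded doses and additivity", {
  # recorded dosimetry: breast spared at 0.4 Gy
  p <- make_patient(rt_courses = list(
    rt_course("supra_diaphragmatic", 19.8,
              organ_doses = c(breast = 0.4, heart = 12, lung = 8, thyroid = 15,
                              esophagus = 10))))
  facts <- derive_facts(p, emap, as_of = "2024-01-01")
  expect_equal(facts[["organ_mean_dose(breast)"]]$value, 0.4)
  expect_equal(facts[["organ_mean_dose(breast)"]]$provenance, "recorded")
  # same field without dosimetry: dose is UNKNOWN, not 0
  pd <- make_patient(rt_courses = list(rt_course("supra_diaphragmatic", 19.8)))
  fd <- derive_facts(pd, emap, as_of = "2024-01-01")
  expect_true(is.na(fd[["organ_mean_dose(breast)"]]$value))
  expect_equal(fd[["organ_mean_dose(breast)"]]$provenance, "missing")
  # organs in no irradiated field are 0, not UNKNOWN
  expect_equal(fd[["organ_mean_dose(kidney)"]]$value, 0)
  expect_true(fd[["field_irradiated(supra_diaphragmatic)"]]$value)
  expect_false(fd[["field_irradiated(cranial)"]]$value)

  # cumulative doses sum across lines
  p2 <- make_patient(
    chemo_courses = list(chemo_course(c(doxorubicin = 150))),
    extra_lines = list(list(
      line_number = 2, start_date = "2017-01-01", end_date = "2017-06-01",
      chemo_courses = list(chemo_course(c(doxorubicin = 150),
                                        start = "2017-01-01", end = "2017-04-01")))))
  f2 <- derive_facts(p2, emap, as_of = "2024-01-01")
  expect_equal(f2[["cumulative_dose(doxorubicin)"]]$value, 300)

  bad <- make_patient(rt_courses = list(rt_course("mediastinal", 20)))
  expect_error(derive_facts(bad, emap, as_of = "2024-01-01"), "mediastinal")
})

test_that("comparisons and connectives follow strong Kleene semantics", {
  leaf <- function(val) {
    facts <- structure(list(`organ_mean_dose(breast)` = list(value = val,
                                                             provenance = "recorded")),
                       class = "survplan_facts")
    eval_predicate(list(fact = "organ_mean_dose(breast)", op = ">=", value = 10), facts)
  }
  expect_false(leaf(0.4))
  expect_true(leaf(25))
  expect_true(is.na(leaf(NA)))

  u <- list(fact = "cumulative_dose(f1)", op = ">=", value = 1)
  t <- list(fact = "cumulative_dose(f2)", op = ">=", value = 1)
  f <- list(fact = "cumulative_dose(f3)", op = ">=", value = 1)
  facts <- structure(list(
    `cumulative_dose(f1)` = list(value = NA, provenance = "missing"),
    `cumulative_dose(f2)` = list(value = 5, provenance = "recorded"),
    `cumulative_dose(f3)` = list(value = 0, provenance = "recorded")),
    class = "survplan_facts")
  expect_true(is.na(eval_predicate(list(not = u), facts)))
  expect_true(eval_predicate(list(`or` = list(t, u)), facts))
  expect_false(eval_predicate(list(`and` = list(f, u)), facts))
  expect_true(is.na(eval_predicate(list(`and` = list(t, u)), facts)))
  expect_true(is.na(eval_predicate(list(`or` = list(f, u)), facts)))
})

test_that("eval_predicate agrees with the substitution oracle on all shapes up to 4 leaves", {
  vals3 <- c(TRUE, FALSE, NA)
  for (n in 1:4) {
    shapes <- predicate_shapes(n)
    grid <- expand.grid(rep(list(vals3), n))
    for (shape in shapes) {
      pred <- shape_to_predicate(shape)
      for (r in seq_len(nrow(grid))) {
        lv <- unlist(grid[r, ], use.names = FALSE)
        got <- eval_predicate(pred, facts_for_leaves(lv))
        want <- kleene_oracle(shape, lv)
        expect_identical(got, want,
                         label = sprintf("shape %s on (%s)", deparse(shape),
                                         paste(lv, collapse = ",")))
      }
    }
  }
})

test_that("plan generation handles precise, degraded and suppressed surveillance", {
  # cervical irradiation with recorded thyroid dose: precise inclusion
  p_precise <- make_patient(rt_courses = list(
    rt_course("cervical", 30, organ_doses = c(thyroid = 28, salivary_glands = 12,
                                              carotid = 20, esophagus = 10))))
  plan <- generate_plan(p_precise, rb, emap, as_of = "2024-01-01")
  it <- plan$items[["thyroid_ultrasound"]]
  expect_false(is.null(it))
  expect_equal(it$data_quality, "precise")

  # same exposure plus thyroidectomy recorded during follow-up: suppressed
  p_thyr <- p_precise
  p_thyr$follow_up_events <- list(list(date = "2020-01-01", organ_category = "thyroid",
                                       event_type = "organ_loss",
                                       description = "thyroidectomy"))
  plan2 <- generate_plan(p_thyr, rb, emap, as_of = "2024-01-01")
  expect_null(plan2$items[["thyroid_ultrasound"]])
  expect_match(plan2$suppressed[["thyroid_ultrasound"]]$reason, "removed")
  # thyroid function testing is not organ-targeted and survives
  expect_false(is.null(plan2$items[["thyroid_function_tests"]]))

  # chest field without dosimetry: conservative degraded proposal
  p_degraded <- make_patient(rt_courses = list(rt_course("supra_diaphragmatic", 19.8)))
  plan3 <- generate_plan(p_degraded, rb, emap, as_of = "2024-01-01")
  bi <- plan3$items[["breast_imaging"]]
  expect_equal(bi$data_quality, "degraded")
  expect_true("organ_mean_dose(breast)" %in% bi$missing_data_notes)

  # recorded dosimetry showing a spared breast: no breast surveillance
  p_spared <- make_patient(rt_courses = list(
    rt_course("supra_diaphragmatic", 19.8,
              organ_doses = c(breast = 0.4, heart = 12, lung = 8, thyroid = 15,
                              esophagus = 10))))
  plan4 <- generate_plan(p_spared, rb, emap, as_of = "2024-01-01")
  expect_null(plan4$items[["breast_imaging"]])

  # untreated simple-monitoring patient without predisposition: empty plan
  plan5 <- generate_plan(make_patient(), rb, emap, as_of = "2024-01-01")
  expect_length(plan5$items, 0L)
})

test_that("multiple matching conditions take the shortest interval and highest evidence", {
  # doxorubicin 300 matches both the high (P2Y) and moderate (P5Y) echo rules
  p <- make_patient(chemo_courses = list(chemo_course(c(doxorubicin = 300))))
  plan <- generate_plan(p, rb, emap, as_of = "2024-01-01")
  echo <- plan$items[["echocardiography"]]
  expect_equal(echo$frequency$interval, "P2Y")
  expect_equal(echo$evidence_level, "high")
  expect_equal(echo$data_quality, "precise")
})

test_that("removing dosimetry never removes plan items (conservatism of degraded mode)", {
  preset <- cohort_preset("table1")
  cohort <- generate_cohort(preset, n = 200, seed = 424)
  checked <- 0L
  for (p in cohort) {
    has_dosim <- any(unlist(lapply(p$diagnoses, function(dx)
      lapply(dx$treatment_lines, function(ln)
        lapply(ln$rt_courses, `[[`, "dosimetry_available")))))
    if (!has_dosim) next
    p_blind <- p
    for (i in seq_along(p_blind$diagnoses))
      for (j in seq_along(p_blind$diagnoses[[i]]$treatment_lines)) {
        ln <- p_blind$diagnoses[[i]]$treatment_lines[[j]]
        for (k in seq_along(ln$rt_courses)) {
          ln$rt_courses[[k]]$organ_doses <- list()
          ln$rt_courses[[k]]$dosimetry_available <- FALSE
        }
        p_blind$diagnoses[[i]]$treatment_lines[[j]] <- ln
      }
    full <- generate_plan(p, rb, emap, as_of = "2024-01-01")
    blind <- generate_plan(validate_patient(p_blind), rb, emap, as_of = "2024-01-01")
    expect_true(all(names(full$items) %in% names(blind$items)),
                label = paste("conservatism for", p$patient_id))
    checked <- checked + 1L
  }
  expect_gt(checked, 10L)
})

test_that("an organ-loss event always suppresses endpoints targeting that organ", {
  preset <- cohort_preset("table1")
  cohort <- generate_cohort(preset, n = 80, seed = 77)
  for (p in cohort[1:40]) {
    p2 <- p
    p2$follow_up_events <- c(p2$follow_up_events,
                             list(list(date = "2023-01-01", organ_category = "thyroid",
                                       event_type = "organ_loss", description = "")))
    before <- generate_plan(p, rb, emap, as_of = "2024-01-01")
    after <- generate_plan(validate_patient(p2), rb, emap, as_of = "2024-01-01")
    targets <- vapply(after$items, function(it) it$target_organ %||% "", "")
    expect_false(any(targets == "thyroid"))
    # and nothing new appears
    expect_true(all(names(after$items) %in% names(before$items)))
  }
})

test_that("plan generation is deterministic", {
  p <- make_patient(rt_courses = list(rt_course("cranial", 40)),
                    chemo_courses = list(chemo_course(c(cisplatin = 400))))
  a <- generate_plan(p, rb, emap, as_of = "2024-01-01")
  b <- generate_plan(p, rb, emap, as_of = "2024-01-01")
  expect_identical(a, b)
})

test_that("modifications are audited and replayable", {
  p <- make_patient(rt_courses = list(rt_course("supra_diaphragmatic", 19.8)))
  plan <- generate_plan(p, rb, emap, as_of = "2024-01-01")
  expect_length(plan$audit_log, 0L)

  m1 <- apply_modification(plan, list(type = "deselect", endpoint_id = "breast_imaging"),
                           actor = "dr_a")
  expect_equal(m1$items[["breast_imaging"]]$status, "removed")
  expect_length(m1$audit_log, 1L)
  expect_equal(m1$audit_log[[1]]$action, "deselect")
  expect_equal(m1$audit_log[[1]]$before$status, "proposed")

  m2 <- apply_modification(m1, list(type = "add_endpoint",
                                    endpoint_id = "dermatology_extra",
                                    label = "Dermatology consult"),
                           actor = "dr_a")
  expect_equal(m2$items[["dermatology_extra"]]$status, "accepted")
  expect_equal(m2$items[["dermatology_extra"]]$cause, "physician_added")

  m3 <- apply_modification(m2, list(type = "modify_frequency",
                                    endpoint_id = "echocardiography",
                                    frequency = list(interval = "P1Y",
                                                     anchor = "end_of_treatment")),
                           actor = "dr_b")
  expect_equal(m3$items[["echocardiography"]]$frequency$interval, "P1Y")
  expect_length(m3$audit_log, 3L)

  # event-sourcing replay reproduces the final state
  replayed <- replay_audit(plan, m3$audit_log)
  expect_identical(replayed, m3)

  expect_error(apply_modification(plan, list(type = "deselect",
                                             endpoint_id = "nonexistent"), "dr_a"),
               "non-existent")
})
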