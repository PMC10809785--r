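rb <- load_rulebase()

plan_with_items <- function(intervals = c(echo = "P2Y"),
                            anchor = "end_of_treatment", start_offset = "P1Y",
                            end = "lifelong", anchor_age = NULL) {
  items <- lapply(names(intervals), function(id) list(
    endpoint_id = id, label = id, kind = "complementary_examination",
    target_organ = NULL, matched_conditions = list(),
    frequency = list(interval = unname(intervals[[id]]), anchor = anchor,
                     anchor_age = anchor_age, start_offset = start_offset, end = end),
    evidence_level = "moderate", bibliography = character(),
    data_quality = "precise", missing_data_notes = character(),
    cause = "rule_match", status = "proposed", notes = character()))
  names(items) <- names(intervals)
  structure(list(patient_id = "PT-1", generated_at = "2020-06-01",
                 rulebase_version = "test", items = items,
                 suppressed = list(), audit_log = list()),
            class = "survplan_plan")
}

anchors <- list(end_of_treatment = as.Date("2020-06-01"),
                diagnosis = as.Date("2019-01-15"),
                birth_date = as.Date("2004-03-10"))

test_that("due dates are anchor + offset + k * interval up to the horizon", {
  s <- build_schedule(plan_with_items(), anchors, horizon = as.Date("2027-01-01"))
  expect_equal(s$entries$due_date,
               as.Date(c("2021-06-01", "2023-06-01", "2025-06-01")))
  expect_true(all(s$entries$status == "pending"))
  expect_true(all(s$entries$recipients == "patient,attending_physician"))

  empty <- plan_with_items()
  empty$items <- list()
  expect_equal(nrow(build_schedule(empty, anchors)$entries), 0L)
})

test_that("age bounds stop the series at the stated birthday", {
  s <- build_schedule(plan_with_items(end = 25), anchors,
                      horizon = as.Date("2040-01-01"))
  cutoff <- as.Date("2004-03-10") + ceiling(25 * 365.25)
  expect_true(all(s$entries$due_date <= cutoff))
  expect_gt(nrow(s$entries), 0L)

  expect_error(build_schedule(plan_with_items(anchor = "fixed_age", anchor_age = 25),
                              anchors["end_of_treatment"]),
               "anchor")
})

test_that("a pause shifts covered due dates and re-spaces the series", {
  s <- build_schedule(plan_with_items(), anchors, horizon = as.Date("2027-01-01"))
  s2 <- apply_pause(s, "2023-01-01", "2024-01-01", reason = "pregnancy")
  expect_equal(s2$entries$due_date,
               as.Date(c("2021-06-01", "2024-01-01", "2026-01-01")))

  # a pause covering no due date leaves the calendar unchanged
  s3 <- apply_pause(s, "2022-01-01", "2022-03-01", reason = "long_trip")
  expect_equal(s3$entries$due_date, s$entries$due_date)

  # open-ended pause suspends everything from its start
  s4 <- apply_pause(s, "2023-01-01", NULL, reason = "intercurrent_health_event")
  expect_equal(s4$entries$due_date, as.Date("2021-06-01"))

  expect_error(apply_pause(s2, "2023-06-01", "2023-09-01", reason = "other"),
               "overlap")
})

test_that("stopping is permanent, cancels pending entries, and cannot repeat", {
  s <- build_schedule(plan_with_items(), anchors, horizon = as.Date("2027-01-01"))
  st <- stop_schedule(s, reason = "replanning initial -> LTFU")
  expect_true(st$stopped)
  expect_true(all(st$entries$status == "cancelled"))
  expect_equal(nrow(next_notifications(st, c(as.Date("2020-01-01"),
                                             as.Date("2030-01-01")))), 0L)
  expect_error(stop_schedule(st, "again"), "already stopped")
  # a pause applied after the stop changes no entries
  stp <- apply_pause(st, "2024-01-01", "2025-01-01", reason = "other")
  expect_identical(stp$entries, st$entries)
})

test_that("notifications cover the window, respect pauses, and are idempotent", {
  s <- build_schedule(plan_with_items(), anchors, horizon = as.Date("2027-01-01"))
  w <- c(as.Date("2023-05-01"), as.Date("2023-07-01"))
  nn <- next_notifications(s, w)
  expect_equal(nrow(nn), 1L)
  expect_equal(nn$due_date, as.Date("2023-06-01"))
  expect_equal(nn$recipients, "patient,attending_physician")

  s2 <- mark_notified(s, nn)
  expect_equal(nrow(next_notifications(s2, w)), 0L)
  expect_identical(mark_notified(s2, nn), s2)

  # window inside an open pause yields nothing
  sp <- apply_pause(s, "2023-01-01", NULL, reason = "pregnancy")
  expect_equal(nrow(next_notifications(sp, w)), 0L)
})

test_that("overdue detection compares due date + grace against the as-of date", {
  s <- build_schedule(plan_with_items(start_offset = NULL), anchors,
                      horizon = as.Date("2027-01-01"))
  # first due 2020-06-01; grace 6 months
  od <- flag_overdue(s, as_of = "2021-01-01", grace = "P6M")
  expect_equal(nrow(od), 1L)
  expect_equal(od$status, "overdue")
  expect_equal(nrow(flag_overdue(s, as_of = "2020-11-30", grace = "P6M")), 0L)
  s_done <- mark_done(s, "echo", "2020-06-01")
  expect_equal(nrow(flag_overdue(s_done, as_of = "2021-01-01", grace = "P6M")), 0L)
  expect_equal(nrow(flag_overdue(s, as_of = "2020-01-01", grace = "P6M")), 0L)
})

test_that("schedules round-trip through JSON with state intact", {
  p <- make_patient(chemo_courses = list(chemo_course(c(cisplatin = 400))))
  plan <- generate_plan(p, rb, as_of = "2017-01-01")
  s <- build_schedule(plan, patient_anchors(p))
  s <- apply_pause(s, "2018-01-01", "2018-06-01", reason = "pregnancy")
  nn <- next_notifications(s, c(as.Date("2017-01-01"), as.Date("2020-01-01")))
  if (nrow(nn)) s <- mark_notified(s, nn[1, , drop = FALSE])
  f <- tempfile(fileext = ".json")
  write_schedule(s, f)
  s2 <- read_schedule(f)
  expect_equal(s2$entries, s$entries)
  expect_equal(s2$pauses, s$pauses)
  expect_equal(s2$horizon, s$horizon)
  expect_equal(s2$stopped, s$stopped)
  # the reloaded schedule still supports operations
  s3 <- stop_schedule(s2, "done testing")
  expect_true(all(s3$entries$status %in% c("cancelled", "done")))
})

test_that("random operation sequences never lose entries and replay purely", {
  set.seed(99)
  for (rep in 1:120) {
    iv <- sample(c("P6M", "P1Y", "P2Y"), 2L, replace = TRUE)
    names(iv) <- c("a", "b")
    s <- build_schedule(plan_with_items(iv), anchors,
                        horizon = as.Date("2026-01-01"))
    total0 <- nrow(s$entries)
    did_stop <- FALSE
    for (op in sample(c("pause", "done", "notify", "stop"),
                      sample(1:4, 1L), replace = TRUE)) {
      if (op == "pause" && !length(s$pauses)) {
        ps <- as.Date("2021-01-01") + sample.int(700L, 1L)
        s <- apply_pause(s, ps, ps + sample(30:300, 1L), reason = "other")
      } else if (op == "done" && !did_stop) {
        pend <- which(s$entries$status == "pending")
        if (length(pend))
          s <- mark_done(s, s$entries$endpoint_id[pend[1]],
                         s$entries$due_date[pend[1]])
      } else if (op == "notify") {
        nn <- next_notifications(s, c(as.Date("2020-01-01"), as.Date("2026-01-01")))
        if (nrow(nn)) s <- mark_notified(s, nn)
      } else if (op == "stop" && !did_stop) {
        s <- stop_schedule(s, "test")
        did_stop <- TRUE
      }
    }
    # conservation: every entry has exactly one status from the lifecycle
    expect_true(all(s$entries$status %in%
                      c("pending", "notified", "done", "cancelled")))
    expect_equal(sum(table(s$entries$status)), nrow(s$entries))
    # regeneration from stored inputs reproduces the stored pending calendar
    if (!s$stopped) {
      s_regen <- survplan:::regenerate_entries(s)
      expect_identical(s_regen$entries, s$entries)
    }
  }
})
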