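#' Surveillance calendar: due dates, pauses, stops, notifications
#'
#' A validated plan becomes a calendar of due dates per endpoint: for each
#' item, `anchor + start_offset + k * interval` for `k = 0, 1, ...` up to a
#' horizon or the item's end bound (an age or lifelong). Follow-up can be
#' paused (pregnancy, intercurrent health event, long trip, ...): due dates
#' falling inside a closed pause are *shifted to the first date after the
#' pause and the series re-spaced* from there — a missed examination is
#' delayed, never dropped. An open-ended pause suspends all later entries
#' until it is closed. A schedule can also be permanently stopped (e.g.
#' when replanning from initial follow-up to long-term follow-up); stopping
#' cancels all pending entries and is irreversible on the schedule object.
#' The whole schedule is a pure function of (plan, anchors, pauses,
#' stopped), so it can be regenerated identically at any time.
#'
#' @name planner
NULL

# due-date series for one frequency: base + k * interval (k-multiples from a
# fixed base, so month-end clamping never drifts); a pause shift restarts the
# series base at the first date after the pause
schedule_dates <- function(anchor_date, frequency, birth_date, horizon,
                           pauses = list(), max_n = 1000L) {
  base <- as.Date(anchor_date)
  if (!is.null(frequency$start_offset)) base <- add_period(base, frequency$start_offset)
  bound <- as.Date(horizon)
  if (!is.null(frequency$end) && !identical(frequency$end, "lifelong")) {
    if (is.null(birth_date))
      stop("frequency has an age bound but no birth date anchor supplied", call. = FALSE)
    bound <- min(bound, date_at_age(birth_date, frequency$end))
  }
  out <- as.Date(character())
  k <- 0L
  for (i in seq_len(max_n)) {
    d <- add_period(base, frequency$interval, k = k)
    shifted <- defer_past_pauses(d, pauses)
    if (is.na(shifted) || shifted > bound) break
    if (shifted != d) {        # re-space the series from the shifted date
      base <- shifted
      k <- 0L
      d <- shifted
    }
    out <- c(out, d)
    k <- k + 1L
  }
  out
}

# shift a date out of any pause containing it; NA if caught in an open pause
defer_past_pauses <- function(d, pauses) {
  repeat {
    moved <- FALSE
    for (p in pauses) {
      if (d >= p$start && (is.null(p$end) || d < p$end)) {
        if (is.null(p$end)) return(as.Date(NA))
        d <- p$end
        moved <- TRUE
      }
    }
    if (!moved) return(d)
  }
}

empty_entries <- function() {
  data.frame(endpoint_id = character(), due_date = as.Date(character()),
             recipients = character(), status = character(),
             stringsAsFactors = FALSE)
}

#' Build the surveillance calendar for a plan
#'
#' @param plan a `survplan_plan`; items with status `removed` are skipped.
#' @param anchors named list of dates: `end_of_treatment`, `diagnosis`, and
#'   `birth_date` (needed for `fixed_age` anchors and age bounds). See
#'   [patient_anchors()].
#' @param horizon last calendar date to schedule (default: 5 years after
#'   plan generation).
#' @param pauses optional list of pauses (see [apply_pause()]).
#' @return a `survplan_schedule`.
#' @export
build_schedule <- function(plan, anchors,
                           horizon = add_period(as.Date(plan$generated_at), "P5Y"),
                           pauses = list()) {
  stopifnot(inherits(plan, "survplan_plan"))
  sched <- structure(list(plan_id = paste0(plan$patient_id, "/", plan$generated_at),
                          plan = plan, anchors = anchors,
                          horizon = as.Date(horizon),
                          pauses = pauses,
                          stopped = FALSE, stop_reason = NULL,
                          entries = empty_entries()),
                     class = "survplan_schedule")
  regenerate_entries(sched)
}

anchor_date_for <- function(frequency, anchors, endpoint_id) {
  a <- switch(frequency$anchor,
    end_of_treatment = anchors$end_of_treatment,
    diagnosis = anchors$diagnosis,
    fixed_age = if (!is.null(anchors$birth_date))
      date_at_age(anchors$birth_date, frequency$anchor_age))
  if (is.null(a))
    stop("item '", endpoint_id, "' needs anchor '", frequency$anchor,
         "' but it was not supplied", call. = FALSE)
  as.Date(a)
}

# recompute pending entries from (plan, anchors, pauses); entries already
# done (or notified before any new pause) keep their status
regenerate_entries <- function(sched) {
  keep <- sched$entries[sched$entries$status %in% c("done", "cancelled"), , drop = FALSE]
  notified <- sched$entries[sched$entries$status == "notified", , drop = FALSE]
  if (sched$stopped) {
    sched$entries <- sched$entries
    return(sched)
  }
  rows <- list()
  for (it in sched$plan$items) {
    if (it$status == "removed") next
    anchor <- anchor_date_for(it$frequency, sched$anchors, it$endpoint_id)
    dates <- schedule_dates(anchor, it$frequency, sched$anchors$birth_date,
                            sched$horizon, sched$pauses)
    done_dates <- keep$due_date[keep$endpoint_id == it$endpoint_id]
    dates <- dates[!dates %in% done_dates]
    if (length(dates))
      rows[[it$endpoint_id]] <- data.frame(
        endpoint_id = it$endpoint_id, due_date = dates,
        recipients = "patient,attending_physician",
        status = "pending", stringsAsFactors = FALSE)
  }
  fresh <- if (length(rows)) do.call(rbind, rows) else empty_entries()
  # entries already notified keep that status if their due date survived
  if (nrow(notified)) {
    key <- paste(fresh$endpoint_id, fresh$due_date)
    nkey <- paste(notified$endpoint_id, notified$due_date)
    fresh$status[key %in% nkey] <- "notified"
  }
  out <- rbind(keep, fresh)
  out <- out[order(out$endpoint_id, out$due_date), , drop = FALSE]
  rownames(out) <- NULL
  sched$entries <- out
  sched
}

#' @export
print.survplan_schedule <- function(x, ...) {
  cat("<survplan_schedule ", x$plan_id, "> horizon ", format(x$horizon),
      if (x$stopped) paste0(", STOPPED (", x$stop_reason, ")") else "",
      "\n  ", nrow(x$entries), " entries: ",
      paste(names(table(x$entries$status)), table(x$entries$status),
            sep = "=", collapse = ", "),
      if (length(x$pauses)) paste0("\n  ", length(x$pauses), " pause(s)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Pause the follow-up calendar
#'
#' @param schedule a `survplan_schedule`.
#' @param start first paused date (inclusive).
#' @param end first date after the pause (exclusive), or `NULL` for an
#'   open-ended pause.
#' @param reason one of `pregnancy`, `intercurrent_health_event`,
#'   `long_trip`, `other`.
#' @export
apply_pause <- function(schedule, start, end = NULL,
                        reason = c("pregnancy", "intercurrent_health_event",
                                   "long_trip", "other")) {
  stopifnot(inherits(schedule, "survplan_schedule"))
  reason <- match.arg(reason)
  start <- as.Date(start)
  if (!is.null(end)) {
    end <- as.Date(end)
    if (!start < end) stop("pause start must precede its end", call. = FALSE)
  }
  for (p in schedule$pauses) {
    p_end <- p$end %||% as.Date("9999-12-31")
    new_end <- end %||% as.Date("9999-12-31")
    if (start < p_end && p$start < new_end)
      stop("pause overlaps an existing pause starting ", format(p$start), call. = FALSE)
  }
  schedule$pauses <- c(schedule$pauses,
                       list(list(start = start, end = end, reason = reason)))
  regenerate_entries(schedule)
}

#' Permanently stop a schedule
#'
#' Cancels all pending/notified entries; irreversible on this schedule
#' object. Stopping an already-stopped schedule is an error.
#'
#' @param schedule a `survplan_schedule`.
#' @param reason free-text reason (e.g. replanning from initial follow-up
#'   to long-term follow-up).
#' @export
stop_schedule <- function(schedule, reason) {
  stopifnot(inherits(schedule, "survplan_schedule"))
  if (schedule$stopped) stop("schedule is already stopped", call. = FALSE)
  schedule$stopped <- TRUE
  schedule$stop_reason <- as.character(reason)
  schedule$entries$status[schedule$entries$status %in% c("pending", "notified")] <- "cancelled"
  schedule
}

in_any_pause <- function(dates, pauses) {
  out <- rep(FALSE, length(dates))
  for (p in pauses)
    out <- out | (dates >= p$start & (is.null(p$end) | dates < (p$end %||% as.Date("9999-12-31"))))
  out
}

#' Notifications due in a window
#'
#' Returns the pending entries whose due date falls inside `window`, is not
#' under a pause, and whose schedule is not stopped, together with their
#' recipients (patient and attending physician). Use [mark_notified()] on
#' the result; marking is idempotent and notified entries are not returned
#' again.
#'
#' @param schedule a `survplan_schedule`.
#' @param window length-2 vector of dates (inclusive).
#' @export
next_notifications <- function(schedule, window) {
  stopifnot(inherits(schedule, "survplan_schedule"), length(window) == 2L)
  if (schedule$stopped) return(empty_entries())
  w <- as.Date(window)
  e <- schedule$entries
  sel <- e$status == "pending" & e$due_date >= w[1] & e$due_date <= w[2] &
    !in_any_pause(e$due_date, schedule$pauses)
  out <- e[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @param notifications entry rows returned by [next_notifications()].
#' @rdname next_notifications
#' @export
mark_notified <- function(schedule, notifications) {
  key <- paste(schedule$entries$endpoint_id, schedule$entries$due_date)
  nkey <- paste(notifications$endpoint_id, notifications$due_date)
  hit <- key %in% nkey & schedule$entries$status == "pending"
  schedule$entries$status[hit] <- "notified"
  schedule
}

#' @param endpoint_id,due_date identify the completed entry.
#' @rdname next_notifications
#' @export
mark_done <- function(schedule, endpoint_id, due_date) {
  hit <- schedule$entries$endpoint_id == endpoint_id &
    schedule$entries$due_date == as.Date(due_date)
  if (!any(hit)) stop("no such schedule entry", call. = FALSE)
  schedule$entries$status[hit] <- "done"
  schedule
}

#' Overdue entries
#'
#' Entries whose due date plus a grace period has passed without the
#' examination being done identify survivors becoming less responsive to
#' follow-up. Cancelled entries and entries under an open pause are never
#' overdue.
#'
#' @param schedule a `survplan_schedule`.
#' @param as_of evaluation date.
#' @param grace grace period (ISO-8601, default 3 months).
#' @return the overdue entry rows.
#' @export
flag_overdue <- function(schedule, as_of, grace = "P3M") {
  stopifnot(inherits(schedule, "survplan_schedule"))
  as_of <- as.Date(as_of)
  e <- schedule$entries
  deadline <- add_period(e$due_date, grace)
  sel <- e$status %in% c("pending", "notified") & deadline < as_of &
    !in_any_pause(e$due_date, schedule$pauses)
  out <- e[sel, , drop = FALSE]
  if (nrow(out)) out$status <- "overdue"
  rownames(out) <- NULL
  out
}

#' Read / write schedules as JSON
#'
#' Persists the full schedule state (plan, anchors, horizon, pauses, stop
#' flag, entries with statuses), so pause/stop/notify operations can be
#' chained across command-line invocations.
#'
#' @param schedule a `survplan_schedule`.
#' @param path JSON file path.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "survplan_schedule"))
  x <- list(plan_id = schedule$plan_id,
            plan = strip_class(schedule$plan),
            anchors = lapply(schedule$anchors, format),
            horizon = format(schedule$horizon),
            pauses = lapply(schedule$pauses, function(p)
              list(start = format(p$start),
                   end = if (is.null(p$end)) NULL else format(p$end),
                   reason = p$reason)),
            stopped = schedule$stopped,
            stop_reason = schedule$stop_reason,
            entries = schedule$entries)
  x$entries$due_date <- format(x$entries$due_date)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  plan <- jsonlite::fromJSON(jsonlite::toJSON(x$plan, auto_unbox = TRUE,
                                              digits = NA, null = "null"),
                             simplifyVector = FALSE)
  plan$items <- lapply(plan$items, function(it) {
    it$missing_data_notes <- as.character(unlist(it$missing_data_notes))
    it$bibliography <- as.character(unlist(it$bibliography))
    it$notes <- as.character(unlist(it$notes))
    it
  })
  class(plan) <- "survplan_plan"
  entries <- if (length(x$entries)) {
    e <- as.data.frame(x$entries, stringsAsFactors = FALSE)
    e$due_date <- as.Date(e$due_date)
    e
  } else empty_entries()
  structure(list(plan_id = x$plan_id,
                 plan = plan,
                 anchors = lapply(x$anchors, as.Date),
                 horizon = as.Date(x$horizon),
                 pauses = lapply(seq_len(NROW(x$pauses)), function(i)
                   list(start = as.Date(x$pauses$start[i]),
                        end = if (is.na(x$pauses$end[i] %||% NA)) NULL else
                          as.Date(x$pauses$end[i]),
                        reason = x$pauses$reason[i])),
                 stopped = isTRUE(x$stopped),
                 stop_reason = x$stop_reason,
                 entries = entries),
            class = "survplan_schedule")
}

#' Standard anchors for a patient
#'
#' `end_of_treatment` is the end of the last treatment line, `diagnosis`
#' the first diagnosis date.
#' @param patient validated `survplan_patient`.
#' @export
patient_anchors <- function(patient) {
  patient <- validate_patient(patient)
  ends <- unlist(lapply(patient$diagnoses, function(dx)
    lapply(dx$treatment_lines, `[[`, "end_date")))
  list(end_of_treatment = max(as.Date(ends)),
       diagnosis = as.Date(patient$diagnoses[[1]]$date),
       birth_date = as.Date(patient$birth_date))
}
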