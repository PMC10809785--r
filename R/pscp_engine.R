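#' Plan generation under three-valued (Kleene) logic
#'
#' The engine evaluates every rule-base condition against a *fact set*
#' derived from the patient record. Facts can be UNKNOWN — most importantly
#' per-organ radiation doses when an organ lies inside an irradiated field
#' but no dosimetry was recorded. Predicates are evaluated under strong
#' Kleene semantics, where UNKNOWN propagates unless the known operands
#' already decide the result (`TRUE OR UNKNOWN = TRUE`,
#' `FALSE AND UNKNOWN = FALSE`, `NOT UNKNOWN = UNKNOWN`). An endpoint whose
#' best condition is UNKNOWN is *proposed with a caveat* ("degraded mode"),
#' never silently dropped: when a supra-diaphragmatic field was irradiated
#' without dosimetry, breast surveillance is proposed while flagging that
#' precise dosimetric data are missing. Conversely, recorded dosimetry
#' showing a spared organ (e.g. breast mean dose 0.4 Gy) evaluates FALSE
#' and suppresses the proposal.
#'
#' @name pscp_engine
NULL

UNKNOWN <- NA

fact <- function(value, provenance) list(value = value, provenance = provenance)

#' Derive the fact set for a patient
#'
#' Computes every fact the rule base can reference: per-agent cumulative
#' doses summed over all lines and courses; per-organ mean radiation doses
#' (recorded dosimetry where available; UNKNOWN when the organ lies in an
#' irradiated field without dosimetry; 0 when it lies in no irradiated
#' field); per-organ status from surgery and follow-up events; irradiated
#' fields; transplantation; predispositions, comorbidities, supportive
#' care; sex and ages.
#'
#' @param patient validated `survplan_patient`.
#' @param exposure_map field-to-organ map, see [load_exposure_map()].
#' @param as_of evaluation date (drives `age_at_evaluation` and organ
#'   status, so events recorded during follow-up are taken into account).
#' @return a `survplan_facts` object: named list of
#'   `list(value, provenance)`, `value = NA` meaning UNKNOWN.
#' @export
derive_facts <- function(patient, exposure_map = load_exposure_map(), as_of) {
  patient <- validate_patient(patient)
  as_of <- as.Date(as_of)
  facts <- list()
  put <- function(key, value, provenance) facts[[key]] <<- fact(value, provenance)

  courses <- list(); chemo <- list(); lines <- list()
  for (dx in patient$diagnoses) for (ln in dx$treatment_lines) {
    lines[[length(lines) + 1L]] <- ln
    for (rc in ln$rt_courses) courses[[length(courses) + 1L]] <- rc
    for (cc in ln$chemo_courses) chemo[[length(chemo) + 1L]] <- cc
  }

  # cumulative chemotherapy doses, additive across lines and courses
  agent_tot <- list()
  for (cc in chemo) for (ad in cc$agent_doses) {
    agent_tot[[ad$agent]] <- (agent_tot[[ad$agent]] %||% 0) + ad$dose
  }
  for (agent in names(agent_tot))
    put(paste0("cumulative_dose(", agent, ")"), agent_tot[[agent]], "recorded")

  # irradiated fields and per-organ doses
  all_fields <- unique(unlist(lapply(courses, `[[`, "fields_irradiated")))
  bad <- setdiff(all_fields, names(exposure_map))
  if (length(bad))
    stop("unknown anatomical field code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (f in names(exposure_map))
    put(paste0("field_irradiated(", f, ")"), f %in% all_fields, "derived")

  organs <- organ_codes()
  recorded <- stats::setNames(rep(0, length(organs)), organs)
  has_recorded <- stats::setNames(rep(FALSE, length(organs)), organs)
  exposed_blind <- stats::setNames(rep(FALSE, length(organs)), organs)
  for (rc in courses) {
    exposed <- unique(unlist(exposure_map[rc$fields_irradiated]))
    if (rc$dosimetry_available) {
      for (od in rc$organ_doses) {
        recorded[od$organ] <- recorded[od$organ] + od$mean_dose
        has_recorded[od$organ] <- TRUE
      }
      # organs in the field but absent from a complete dosimetry are spared
      for (o in setdiff(exposed, vapply(rc$organ_doses, `[[`, "", "organ")))
        has_recorded[o] <- has_recorded[o] || TRUE
    } else {
      exposed_blind[exposed] <- TRUE
    }
  }
  for (o in organs) {
    key <- paste0("organ_mean_dose(", o, ")")
    if (exposed_blind[o]) put(key, UNKNOWN, "missing")
    else if (has_recorded[o]) put(key, recorded[[o]], "recorded")
    else put(key, 0, "derived")
  }

  status <- derive_organ_status(patient, as_of)
  for (o in organs) put(paste0("organ_status(", o, ")"), status[[o]], "derived")

  hsct_types <- unlist(lapply(lines, function(ln) ln$hsct$type))
  conditioning <- any(vapply(chemo, `[[`, TRUE, "hsct_conditioning"))
  put("hsct_received", length(hsct_types) > 0L || conditioning, "recorded")
  put("hsct_allograft", "allograft" %in% hsct_types, "recorded")
  put("rt_received", length(courses) > 0L, "derived")
  put("chemo_received", length(chemo) > 0L, "derived")

  sc <- unique(unlist(lapply(lines, `[[`, "supportive_care")))
  for (code in supportive_care_codes())
    put(paste0("supportive_care(", code, ")"), code %in% sc, "derived")

  confirmed <- vapply(patient$predispositions, function(p) isTRUE(p$confirmed), TRUE)
  for (p in patient$predispositions)
    put(paste0("predisposition(", p$name, ")"), isTRUE(p$confirmed), "recorded")
  put("predisposition(any)", length(patient$predispositions) > 0L && any(confirmed), "recorded")
  for (code in patient$comorbidities)
    put(paste0("comorbidity(", code, ")"), TRUE, "recorded")

  put("sex", patient$sex, "recorded")
  dx1 <- patient$diagnoses[[1]]
  put("age_at_diagnosis", age_years(patient$birth_date, dx1$date), "derived")
  first_line <- dx1$treatment_lines[[1]]
  put("age_at_treatment", age_years(patient$birth_date, first_line$start_date), "derived")
  put("age_at_evaluation", age_years(patient$birth_date, as_of), "derived")
  put("cancer_count", max(vapply(patient$diagnoses, `[[`, 1L, "cancer_rank")), "derived")

  structure(facts, class = "survplan_facts")
}

# fill defaults for fact keys a rule base references but the record lacks
complete_facts <- function(facts, rulebase) {
  defaults <- c(cumulative_dose = 0, organ_mean_dose = 0)
  for (key in rulebase_fact_keys(rulebase)) {
    if (!is.null(facts[[key]])) next
    base <- parse_fact_key(key)$base
    facts[[key]] <- switch(base,
      cumulative_dose = fact(0, "derived"),
      organ_mean_dose = fact(0, "derived"),
      predisposition = ,
      comorbidity = ,
      supportive_care = ,
      field_irradiated = fact(FALSE, "derived"),
      organ_status = fact("intact", "derived"),
      stop("fact '", key, "' cannot be derived from the record", call. = FALSE))
  }
  facts
}

k3_label <- function(x) if (is.na(x)) "unknown" else if (x) "true" else "false"

compare_fact <- function(value, op, target) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(UNKNOWN)
  if (op == "in") {
    target <- unlist(target)
    return(value %in% target)
  }
  if (is.logical(target) || is.logical(value)) {
    if (!op %in% c("==", "!="))
      stop("comparator '", op, "' not legal for boolean facts", call. = FALSE)
    return(if (op == "==") identical(as.logical(value), as.logical(target))
           else !identical(as.logical(value), as.logical(target)))
  }
  if (is.character(value) || is.character(target)) {
    if (!op %in% c("==", "!="))
      stop("comparator '", op, "' not legal for categorical facts", call. = FALSE)
    return(if (op == "==") identical(as.character(value), as.character(target))
           else !identical(as.character(value), as.character(target)))
  }
  switch(op,
         "==" = value == target, "!=" = value != target,
         ">=" = value >= target, "<=" = value <= target,
         ">" = value > target, "<" = value < target,
         stop("unknown comparator: ", op, call. = FALSE))
}

#' Evaluate a predicate under strong Kleene three-valued logic
#'
#' Leaves compare a fact value against a constant; a comparison with an
#' UNKNOWN operand is UNKNOWN. Internal AND/OR/NOT nodes follow strong
#' Kleene semantics, so known operands can decide a result despite UNKNOWN
#' siblings.
#'
#' @param predicate a parsed predicate tree (from [load_rulebase()]).
#' @param facts a `survplan_facts` fact set; every leaf fact key must be
#'   present (possibly UNKNOWN).
#' @return logical scalar: `TRUE`, `FALSE` or `NA` (= UNKNOWN).
#' @export
eval_predicate <- function(predicate, facts) {
  if (!is.null(predicate$fact)) {
    f <- facts[[predicate$fact]]
    if (is.null(f)) stop("fact '", predicate$fact, "' absent from fact set", call. = FALSE)
    return(compare_fact(f$value, predicate$op, predicate$value))
  }
  if (!is.null(predicate$not)) return(!eval_predicate(predicate$not, facts))
  if (!is.null(predicate$and)) {
    vals <- vapply(predicate$and, eval_predicate, NA, facts = facts)
    return(all(vals))   # base-R all/any over logicals implement strong Kleene
  }
  if (!is.null(predicate$or)) {
    vals <- vapply(predicate$or, eval_predicate, NA, facts = facts)
    return(any(vals))
  }
  stop("malformed predicate node", call. = FALSE)
}

# fact keys whose UNKNOWN value can be blamed for an UNKNOWN result
unknown_fact_keys <- function(predicate, facts) {
  keys <- predicate_fact_keys(predicate)
  keys[vapply(keys, function(k) {
    f <- facts[[k]]
    !is.null(f) && length(f$value) == 1L && is.na(f$value)
  }, TRUE)]
}

evidence_rank <- function(level, scale) match(level, scale)

#' Generate a personalized surveillance plan
#'
#' Evaluates every endpoint of the rule base against the patient's derived
#' facts. An endpoint enters the plan iff at least one of its conditions
#' evaluates TRUE or UNKNOWN; UNKNOWN-driven inclusions are marked
#' `data_quality = "degraded"` with the missing fact keys listed. Endpoints
#' targeting an organ whose status is `removed` are excluded, with the
#' suppression reason logged (removal of the organ ends second-tumor
#' surveillance of that organ). When several conditions match, the item
#' takes the shortest interval and the highest evidence level among them.
#' The function is a pure function of its arguments.
#'
#' @param patient validated `survplan_patient`.
#' @param rulebase a `survplan_rulebase`.
#' @param exposure_map field-to-organ map.
#' @param as_of plan-generation date.
#' @return a `survplan_plan`: items, suppressions, and an (initially empty)
#'   append-only audit log.
#' @examples
#' plan <- generate_plan(example_patient(), load_rulebase(), as_of = "2024-01-01")
#' plan$items[["breast_imaging"]]$data_quality
#' @export
generate_plan <- function(patient, rulebase, exposure_map = load_exposure_map(), as_of) {
  patient <- validate_patient(patient)
  stopifnot(inherits(rulebase, "survplan_rulebase"))
  as_of <- as.Date(as_of)
  facts <- complete_facts(derive_facts(patient, exposure_map, as_of), rulebase)
  scale <- rulebase$evidence_scale

  items <- list(); suppressed <- list()
  for (ep in rulebase$endpoints) {
    evals <- lapply(ep$conditions, function(cn) eval_predicate(cn$predicate, facts))
    hit <- vapply(evals, function(v) is.na(v) || isTRUE(v), TRUE)
    if (!any(hit)) next
    if (!is.null(ep$target_organ) &&
        facts[[paste0("organ_status(", ep$target_organ, ")")]]$value == "removed") {
      suppressed[[ep$endpoint_id]] <- list(
        endpoint_id = ep$endpoint_id,
        reason = paste0("target organ '", ep$target_organ,
                        "' removed; surveillance of this organ no longer justified"))
      next
    }
    matched <- ep$conditions[hit]
    mvals <- evals[hit]
    ivals <- vapply(matched, function(cn) period_approx_days(cn$frequency$interval), 0)
    best_freq <- matched[[which.min(ivals)]]$frequency
    ranks <- vapply(matched, function(cn) evidence_rank(cn$evidence_level, scale), 0L)
    degraded <- any(vapply(mvals, is.na, TRUE))
    missing <- if (degraded)
      unique(unlist(lapply(matched[vapply(mvals, is.na, TRUE)], function(cn)
        unknown_fact_keys(cn$predicate, facts))))
    else character()
    items[[ep$endpoint_id]] <- list(
      endpoint_id = ep$endpoint_id,
      label = ep$label,
      kind = ep$kind,
      target_organ = ep$target_organ,
      matched_conditions = Map(function(cn, v)
        list(condition_id = cn$condition_id, result = k3_label(v)), matched, mvals),
      frequency = best_freq,
      evidence_level = scale[min(ranks)],
      bibliography = unique(unlist(lapply(matched, `[[`, "bibliography"))),
      data_quality = if (degraded) "degraded" else "precise",
      missing_data_notes = as.character(missing),
      cause = if (any(vapply(mvals, isTRUE, TRUE))) "rule_match" else "rule_match_degraded",
      status = "proposed",
      notes = character())
  }

  structure(list(patient_id = patient$patient_id,
                 generated_at = format(as_of),
                 rulebase_version = rulebase$version,
                 items = items,
                 suppressed = suppressed,
                 audit_log = list()),
            class = "survplan_plan")
}

#' @export
print.survplan_plan <- function(x, ...) {
  qual <- vapply(x$items, `[[`, "", "data_quality")
  cat("<survplan_plan> patient ", x$patient_id, ", rule base ", x$rulebase_version,
      ", generated ", x$generated_at, "\n  ", length(x$items), " item(s) (",
      sum(qual == "degraded"), " degraded), ", length(x$suppressed),
      " suppressed, ", length(x$audit_log), " audit entr(ies)\n", sep = "")
  for (it in x$items)
    cat(sprintf("  - %-34s %-12s every %-4s [%s]%s\n", it$endpoint_id,
                paste0("(", it$kind, ")"), it$frequency$interval, it$evidence_level,
                if (it$data_quality == "degraded")
                  paste0("  DEGRADED: missing ", paste(it$missing_data_notes, collapse = ", "))
                else ""))
  invisible(x)
}

#' Apply a physician modification to a plan
#'
#' The physician can deselect an item, modify its frequency, accept it,
#' annotate it, or add an endpoint the rules did not trigger. Every
#' modification appends exactly one audit entry with before/after
#' snapshots; the audit log is append-only and a plan can be reproduced by
#' replaying its log onto the originally generated plan
#' ([replay_audit()]).
#'
#' @param plan a `survplan_plan`.
#' @param action a list with `type` (one of `deselect`, `modify_frequency`,
#'   `add_endpoint`, `accept`, `annotate`), `endpoint_id`, and
#'   type-specific fields (`frequency` for modify_frequency, `note` for
#'   annotate, optional `label`/`kind`/`frequency` for add_endpoint).
#' @param actor actor identifier recorded in the audit entry.
#' @param timestamp audit timestamp (defaults to the plan generation date
#'   so replays are reproducible).
#' @export
apply_modification <- function(plan, action, actor, timestamp = plan$generated_at) {
  stopifnot(inherits(plan, "survplan_plan"), is.list(action))
  type <- action$type
  if (is.null(type) || !type %in% c("deselect", "modify_frequency", "add_endpoint",
                                    "accept", "annotate"))
    stop("unknown modification type: ", type %||% "<missing>", call. = FALSE)
  id <- action$endpoint_id
  if (is.null(id)) stop("action needs an endpoint_id", call. = FALSE)
  before <- plan$items[[id]]
  if (is.null(before) && type != "add_endpoint")
    stop("cannot ", type, " non-existent plan item '", id, "'", call. = FALSE)
  if (!is.null(before) && type == "add_endpoint")
    stop("endpoint '", id, "' already in plan", call. = FALSE)

  item <- before
  item <- switch(type,
    deselect = { item$status <- "removed"; item },
    accept = { item$status <- "accepted"; item },
    annotate = {
      item$notes <- c(item$notes, as.character(action$note %||% ""))
      item
    },
    modify_frequency = {
      errs <- new.env(); errs$msgs <- character()
      fq <- validate_frequency(action$frequency, paste0("item '", id, "'"), errs)
      if (length(errs$msgs)) stop(paste(errs$msgs, collapse = "; "), call. = FALSE)
      item$frequency <- fq
      item$status <- "modified"
      item
    },
    add_endpoint = {
      fq <- action$frequency %||% list(interval = "P1Y", anchor = "end_of_treatment")
      errs <- new.env(); errs$msgs <- character()
      fq <- validate_frequency(fq, paste0("item '", id, "'"), errs)
      if (length(errs$msgs)) stop(paste(errs$msgs, collapse = "; "), call. = FALSE)
      list(endpoint_id = id,
           label = action$label %||% id,
           kind = action$kind %||% "specialized_consultation",
           target_organ = NULL,
           matched_conditions = list(),
           frequency = fq,
           evidence_level = "expert_consensus",
           bibliography = character(),
           data_quality = "precise",
           missing_data_notes = character(),
           cause = "physician_added",
           status = "accepted",
           notes = character())
    })

  plan$items[[id]] <- item
  plan$audit_log[[length(plan$audit_log) + 1L]] <- list(
    timestamp = as.character(timestamp),
    actor = as.character(actor),
    action = type,
    endpoint_id = id,
    before = before_snapshot(before, type),
    after = item)
  plan
}

before_snapshot <- function(before, type) {
  if (type == "add_endpoint") NULL else before
}

#' Replay an audit log onto a freshly generated plan
#'
#' Event-sourcing check: applying the recorded actions to the original plan
#' reproduces the modified plan state.
#'
#' @param plan the originally generated plan (empty audit log).
#' @param audit_log an audit log recorded by [apply_modification()].
#' @export
replay_audit <- function(plan, audit_log) {
  for (entry in audit_log) {
    action <- list(type = entry$action, endpoint_id = entry$endpoint_id)
    if (entry$action == "modify_frequency") action$frequency <- entry$after$frequency
    if (entry$action == "annotate")
      action$note <- utils::tail(entry$after$notes, 1L)
    if (entry$action == "add_endpoint") {
      action$label <- entry$after$label
      action$kind <- entry$after$kind
      action$frequency <- entry$after$frequency
    }
    plan <- apply_modification(plan, action, entry$actor, entry$timestamp)
  }
  plan
}

#' Render a plan as Markdown
#' @param plan a `survplan_plan`.
#' @return character scalar (Markdown document).
#' @export
render_plan <- function(plan) {
  stopifnot(inherits(plan, "survplan_plan"))
  lines <- c(sprintf("# Personalized surveillance plan — patient %s", plan$patient_id),
             sprintf("Generated %s with rule base %s.", plan$generated_at, plan$rulebase_version), "")
  for (it in plan$items) {
    if (it$status == "removed") next
    fq <- it$frequency
    lines <- c(lines,
      sprintf("## %s (%s)", it$label, gsub("_", " ", it$kind)),
      sprintf("- Frequency: every %s, anchored on %s%s", fq$interval,
              gsub("_", " ", fq$anchor),
              if (!is.null(fq$end)) paste0(", until ",
                if (identical(fq$end, "lifelong")) "lifelong" else paste0("age ", fq$end)) else ""),
      sprintf("- Evidence level: %s", it$evidence_level),
      if (length(it$bibliography))
        sprintf("- Bibliography: %s", paste(it$bibliography, collapse = "; ")),
      if (it$data_quality == "degraded")
        sprintf("- **Caveat: precise dosimetric data are missing (%s); proposed conservatively.**",
                paste(it$missing_data_notes, collapse = ", ")),
      "")
  }
  if (length(plan$suppressed)) {
    lines <- c(lines, "## Suppressed endpoints", "")
    for (s in plan$suppressed) lines <- c(lines, sprintf("- %s: %s", s$endpoint_id, s$reason))
  }
  paste(lines, collapse = "\n")
}
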