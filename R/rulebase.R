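#' Guideline rule bases
#'
#' A rule base is a versioned, declarative set of surveillance *endpoints*
#' (a complementary examination, a specialized consultation, or an
#' educational tool), each carrying 1 to 34 *conditions*. A condition pairs
#' a predicate over derived patient facts (an AND/OR/NOT expression tree
#' whose leaves compare fact values such as `cumulative_dose(doxorubicin)`
#' or `organ_mean_dose(breast)` against thresholds) with a surveillance
#' frequency, an evidence level on a five-value ordinal scale, and a
#' bibliography. Predicates are data (YAML), not code, so the rule base can
#' be edited and versioned without touching the engine.
#'
#' The packaged default rule base contains 53 illustrative endpoints
#' assembled from public surveillance topics (echocardiography after
#' anthracyclines or cardiac irradiation, breast imaging after chest
#' irradiation, audiometry after platinum agents, ...). It is structurally
#' conformant but clinically illustrative only — not for clinical use.
#'
#' @name rulebase
NULL

fact_base_names <- function() {
  c("organ_mean_dose", "field_irradiated", "cumulative_dose", "predisposition",
    "organ_status", "comorbidity", "supportive_care", "sex", "age_at_diagnosis",
    "age_at_treatment", "age_at_evaluation", "hsct_received", "hsct_allograft",
    "rt_received", "chemo_received", "cancer_count")
}

parameterized_facts <- function() {
  c("organ_mean_dose", "field_irradiated", "cumulative_dose", "predisposition",
    "organ_status", "comorbidity", "supportive_care")
}

#' Split a fact key into base name and parameter
#' @param key e.g. `"organ_mean_dose(breast)"` or `"sex"`.
#' @return list with elements `base` and `param` (`NULL` when bare).
#' @keywords internal
parse_fact_key <- function(key) {
  m <- regmatches(key, regexec("^([a-z_]+)(?:\\(([^()]+)\\))?$", key))[[1]]
  if (length(m) == 0L) stop("malformed fact key: ", key, call. = FALSE)
  list(base = m[2], param = if (m[3] == "") NULL else m[3])
}

check_fact_key <- function(key, fields) {
  k <- tryCatch(parse_fact_key(key), error = function(e) NULL)
  if (is.null(k)) return(paste0("malformed fact key '", key, "'"))
  if (!k$base %in% fact_base_names())
    return(paste0("unknown fact key '", key, "'"))
  if (k$base %in% parameterized_facts() && is.null(k$param))
    return(paste0("fact '", k$base, "' requires a parameter"))
  if (!k$base %in% parameterized_facts() && !is.null(k$param))
    return(paste0("fact '", k$base, "' takes no parameter"))
  if (k$base %in% c("organ_mean_dose", "organ_status") && !k$param %in% organ_codes())
    return(paste0("fact '", key, "' references unknown organ '", k$param, "'"))
  if (k$base == "field_irradiated" && !k$param %in% fields)
    return(paste0("fact '", key, "' references unknown field '", k$param, "'"))
  NULL
}

predicate_ops <- function() c("==", "!=", ">=", "<=", ">", "<", "in")

# Parse one predicate node; appends messages to `errs` (an environment).
parse_predicate_node <- function(node, path, fields, errs) {
  bad <- function(msg) {
    errs$msgs <- c(errs$msgs, paste0(path, ": ", msg))
    NULL
  }
  if (!is.list(node)) return(bad("predicate node must be a mapping"))
  keys <- intersect(names(node), c("and", "or", "not", "fact"))
  if (length(keys) != 1L)
    return(bad("predicate node must have exactly one of: and, or, not, fact"))
  switch(keys,
    fact = {
      err <- check_fact_key(node$fact, fields)
      if (!is.null(err)) return(bad(err))
      if (is.null(node$op) || !node$op %in% predicate_ops())
        return(bad(paste0("comparator must be one of ", paste(predicate_ops(), collapse = " "))))
      if (is.null(node$value)) return(bad("missing comparison value"))
      list(fact = node$fact, op = node$op, value = node$value)
    },
    not = {
      sub <- parse_predicate_node(node$not, paste0(path, ".not"), fields, errs)
      if (is.null(sub)) NULL else list(not = sub)
    },
    {
      kids <- node[[keys]]
      if (!is.list(kids) || length(kids) < 1L || !is.null(names(kids)))
        return(bad(paste0("'", keys, "' needs a sequence of sub-predicates")))
      subs <- lapply(seq_along(kids), function(i)
        parse_predicate_node(kids[[i]], sprintf("%s.%s[%d]", path, keys, i), fields, errs))
      if (any(vapply(subs, is.null, TRUE))) NULL else stats::setNames(list(subs), keys)
    })
}

validate_frequency <- function(fq, path, errs) {
  bad <- function(msg) {
    errs$msgs <- c(errs$msgs, paste0(path, ": ", msg))
    NULL
  }
  if (!is.list(fq)) return(bad("frequency must be a mapping"))
  iv <- tryCatch(parse_period(fq$interval), error = function(e) NULL)
  if (is.null(iv)) return(bad("invalid or missing interval (ISO-8601 period)"))
  anchor <- fq$anchor %||% "end_of_treatment"
  if (!anchor %in% c("end_of_treatment", "diagnosis", "fixed_age"))
    return(bad("anchor must be end_of_treatment, diagnosis or fixed_age"))
  if (anchor == "fixed_age" && !is.numeric(fq$anchor_age))
    return(bad("anchor_age (years) required when anchor = fixed_age"))
  if (anchor != "fixed_age" && !is.null(fq$anchor_age))
    return(bad("anchor_age only allowed when anchor = fixed_age"))
  off <- fq$start_offset
  if (!is.null(off)) {
    off_p <- tryCatch(parse_period(off), error = function(e) NULL)
    if (is.null(off_p)) return(bad("invalid start_offset period"))
    off <- format(off_p)
  }
  end <- fq$end
  if (!is.null(end) && !identical(end, "lifelong") && !is.numeric(end))
    return(bad("end must be 'lifelong' or an age in years"))
  list(interval = format(iv), anchor = anchor,
       anchor_age = if (anchor == "fixed_age") as.numeric(fq$anchor_age) else NULL,
       start_offset = off, end = end)
}

#' Load and validate a guideline rule base
#'
#' Parses a YAML rule base, compiles every predicate to an expression tree,
#' and enforces the structural contract: unique endpoint ids, 1 to 34
#' conditions per endpoint, a patient-facing note on every endpoint, a
#' recognized evidence level on every condition, and fact keys drawn from
#' the declared fact vocabulary. All violations are collected and reported
#' together.
#'
#' @param path YAML file; defaults to the packaged illustrative rule base.
#' @param exposure_map field-to-organ map used to validate
#'   `field_irradiated(...)` fact keys.
#' @return a `survplan_rulebase`.
#' @examples
#' rb <- load_rulebase()
#' length(rb$endpoints)
#' @export
load_rulebase <- function(path = survplan_extdata("rulebase_default.yaml"),
                          exposure_map = load_exposure_map()) {
  raw <- yaml::read_yaml(path)
  errs <- new.env()
  errs$msgs <- character()
  bad <- function(msg) errs$msgs <- c(errs$msgs, msg)
  fields <- names(exposure_map)

  if (!is.character(raw$version %||% NULL)) bad("missing rule base version")
  scale <- raw$evidence_scale %||% evidence_levels()
  if (!is.list(raw$endpoints) && !is.null(raw$endpoints)) bad("endpoints must be a sequence")
  eps <- raw$endpoints %||% list()
  ids <- vapply(eps, function(e) as.character(e$endpoint_id %||% ""), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) bad(paste0("duplicate endpoint id(s): ", paste(dup, collapse = ", ")))

  endpoints <- lapply(seq_along(eps), function(i) {
    e <- eps[[i]]
    id <- as.character(e$endpoint_id %||% sprintf("<endpoint %d>", i))
    ep_bad <- function(msg) bad(paste0("endpoint '", id, "': ", msg))
    if (!nzchar(e$endpoint_id %||% "")) ep_bad("missing endpoint_id")
    if (!isTRUE(e$kind %in% c("complementary_examination", "specialized_consultation",
                              "educational_tool")))
      ep_bad("kind must be complementary_examination, specialized_consultation or educational_tool")
    if (!is.null(e$target_organ) && !e$target_organ %in% organ_codes())
      ep_bad(paste0("unknown target_organ '", e$target_organ, "'"))
    if (!nzchar(e$patient_note %||% "")) ep_bad("patient_note is required")
    conds <- e$conditions %||% list()
    if (length(conds) < 1L) ep_bad("must have at least 1 condition")
    if (length(conds) > 34L)
      ep_bad(paste0("has ", length(conds), " conditions; at most 34 allowed"))
    conditions <- lapply(seq_along(conds), function(j) {
      cn <- conds[[j]]
      cid <- as.character(cn$condition_id %||% sprintf("%s.c%d", id, j))
      cpath <- paste0("endpoint '", id, "' condition '", cid, "'")
      if (is.null(cn$evidence_level) || !cn$evidence_level %in% scale)
        bad(paste0(cpath, ": missing or unrecognized evidence_level"))
      pred <- if (is.null(cn$predicate)) {
        bad(paste0(cpath, ": missing predicate"))
        NULL
      } else parse_predicate_node(cn$predicate, cpath, fields, errs)
      freq <- if (is.null(cn$frequency)) {
        bad(paste0(cpath, ": missing frequency"))
        NULL
      } else validate_frequency(cn$frequency, cpath, errs)
      list(condition_id = cid, predicate = pred, frequency = freq,
           evidence_level = cn$evidence_level %||% NA_character_,
           bibliography = as.character(unlist(cn$bibliography)))
    })
    list(endpoint_id = id,
         label = as.character(e$label %||% id),
         kind = e$kind %||% NA_character_,
         target_organ = e$target_organ,
         conditions = conditions,
         professional_note = as.character(e$professional_note %||% ""),
         patient_note = as.character(e$patient_note %||% ""))
  })

  if (length(errs$msgs))
    stop("rule base failed to load:\n  - ", paste(errs$msgs, collapse = "\n  - "),
         call. = FALSE)

  structure(list(version = raw$version,
                 evidence_scale = scale,
                 guideline_sources = as.character(unlist(raw$sources)),
                 endpoints = endpoints),
            class = "survplan_rulebase")
}

#' @export
print.survplan_rulebase <- function(x, ...) {
  nc <- vapply(x$endpoints, function(e) length(e$conditions), 0L)
  cat("<survplan_rulebase v", x$version, "> ", length(x$endpoints),
      " endpoints, ", sum(nc), " conditions (per endpoint: ",
      min(nc), "-", max(nc), ")\n", sep = "")
  invisible(x)
}

# all fact keys referenced by a predicate tree
predicate_fact_keys <- function(pred) {
  if (!is.null(pred$fact)) return(pred$fact)
  if (!is.null(pred$not)) return(predicate_fact_keys(pred$not))
  kids <- pred$and %||% pred$or
  unique(unlist(lapply(kids, predicate_fact_keys)))
}

rulebase_fact_keys <- function(rulebase) {
  unique(unlist(lapply(rulebase$endpoints, function(e)
    lapply(e$conditions, function(cn) predicate_fact_keys(cn$predicate)))))
}

# numeric bounds per fact implied by the conjunction of leaves under an AND;
# used for the contradiction heuristic in validate_rulebase()
conjunction_contradiction <- function(pred) {
  leaves <- function(p) {
    if (!is.null(p$fact)) return(list(p))
    if (!is.null(p$and)) return(unlist(lapply(p$and, leaves), recursive = FALSE))
    list()  # OR / NOT break the pure-conjunction pattern; skip
  }
  ls <- leaves(pred)
  if (length(ls) < 2L) return(FALSE)
  keys <- unique(vapply(ls, `[[`, "", "fact"))
  for (k in keys) {
    sub <- Filter(function(l) identical(l$fact, k) && is.numeric(l$value), ls)
    if (length(sub) < 2L) next
    lo <- -Inf; hi <- Inf
    for (l in sub) {
      if (l$op %in% c(">=", ">")) lo <- max(lo, l$value)
      if (l$op %in% c("<=", "<")) hi <- min(hi, l$value)
      if (l$op == "==") { lo <- max(lo, l$value); hi <- min(hi, l$value) }
    }
    if (lo > hi) return(TRUE)
  }
  FALSE
}

#' Structural report on a loaded rule base
#'
#' Report-only companion to [load_rulebase()]: per-endpoint condition
#' counts, the min/max condition count, and warnings for conditions whose
#' predicate is an unsatisfiable conjunction (e.g. `age >= 30 AND age <= 20`).
#'
#' @param rulebase a `survplan_rulebase`.
#' @return list with `errors`, `warnings`, `condition_counts` (named integer
#'   vector), `min_conditions`, `max_conditions`.
#' @export
validate_rulebase <- function(rulebase) {
  stopifnot(inherits(rulebase, "survplan_rulebase"))
  counts <- vapply(rulebase$endpoints, function(e) length(e$conditions), 0L)
  names(counts) <- vapply(rulebase$endpoints, `[[`, "", "endpoint_id")
  warnings <- character()
  for (e in rulebase$endpoints) for (cn in e$conditions) {
    if (conjunction_contradiction(cn$predicate))
      warnings <- c(warnings, paste0("endpoint '", e$endpoint_id, "' condition '",
                                     cn$condition_id, "': contradictory conjunction (never satisfiable)"))
  }
  list(errors = character(), warnings = warnings,
       condition_counts = counts,
       min_conditions = min(counts), max_conditions = max(counts))
}

#' Reserialize a rule base to YAML
#' @param rulebase a `survplan_rulebase`.
#' @param path output file.
#' @export
write_rulebase <- function(rulebase, path) {
  stopifnot(inherits(rulebase, "survplan_rulebase"))
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- Filter(Negate(is.null), x)
    lapply(x, drop_null)
  }
  yaml::write_yaml(drop_null(list(
    version = rulebase$version,
    evidence_scale = rulebase$evidence_scale,
    sources = as.list(rulebase$guideline_sources),
    endpoints = strip_class(rulebase$endpoints))), path)
  invisible(path)
}
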