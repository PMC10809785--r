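#' Theoretical cumulative dose tables
#'
#' Chemotherapy cumulative doses are abstracted against a protocol/arm
#' catalogue of theoretical cumulative doses, limiting transcription
#' errors; recorded doses may then be adapted per patient. The packaged
#' catalogue (`dose_table.csv`) is a versioned, illustrative set of
#' protocols; sites replace it with their own.
#'
#' @param path CSV with columns `protocol,arm,agent,cumulative_dose,units`.
#' @return data.frame of the catalogue.
#' @export
load_dose_table <- function(path = survplan_extdata("dose_table.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protocol", "arm", "agent", "cumulative_dose", "units") %in% names(df)))
  if (any(df$cumulative_dose <= 0))
    stop("dose table contains non-positive cumulative doses", call. = FALSE)
  key <- paste(df$protocol, df$arm, df$agent)
  if (anyDuplicated(key))
    stop("duplicate (protocol, arm, agent) entries in dose table", call. = FALSE)
  df
}

#' Resolve theoretical cumulative doses for a protocol arm
#'
#' Returns the catalogue doses for `(protocol, arm)` flagged
#' `source = "table_default"`; any per-patient adaptation overrides the
#' catalogue value and is flagged `source = "adapted"`. An adaptation for
#' an agent absent from the arm is included with a warning.
#'
#' @param protocol,arm catalogue keys.
#' @param adaptations named numeric vector (or list) of adapted cumulative
#'   doses per agent.
#' @param dose_table catalogue, see [load_dose_table()].
#' @return data.frame with columns `agent`, `dose`, `units`, `source`.
#' @examples
#' resolve_cumulative_doses("LYMPH02", "standard",
#'                          adaptations = c(doxorubicin = 150))
#' @export
resolve_cumulative_doses <- function(protocol, arm, adaptations = NULL,
                                     dose_table = load_dose_table()) {
  rows <- dose_table[dose_table$protocol == protocol & dose_table$arm == arm, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown (protocol, arm): (", protocol, ", ", arm, ")", call. = FALSE)
  out <- data.frame(agent = rows$agent, dose = rows$cumulative_dose,
                    units = rows$units, source = "table_default",
                    stringsAsFactors = FALSE)
  adaptations <- unlist(adaptations)
  for (agent in names(adaptations)) {
    i <- match(agent, out$agent)
    if (is.na(i)) {
      warning("adaptation for agent '", agent, "' absent from arm ", protocol,
              "/", arm, "; included", call. = FALSE)
      out <- rbind(out, data.frame(agent = agent, dose = adaptations[[agent]],
                                   units = "mg/m2", source = "adapted",
                                   stringsAsFactors = FALSE))
    } else {
      out$dose[i] <- adaptations[[agent]]
      out$source[i] <- "adapted"
    }
  }
  rownames(out) <- NULL
  out
}

#' Render the harmonized treatment summary
#'
#' One document covering the survivor's whole oncological history:
#' diagnoses with dates and categories; per line surgery (carcinological
#' and functional impact), chemotherapy, radiotherapy (fields, prescribed
#' dose, organ doses or an explicit missing-dosimetry caveat),
#' transplantation and supportive care; per-agent cumulative doses summed
#' across all lines; recurrences and second cancers; follow-up events.
#' Suitable for deposit in the patient's medical record.
#'
#' @param patient validated `survplan_patient`.
#' @param format `"markdown"` (character scalar) or `"json"` (JSON string).
#' @export
render_treatment_summary <- function(patient, format = c("markdown", "json")) {
  patient <- validate_patient(patient)
  format <- match.arg(format)
  agent_tot <- list()
  for (dx in patient$diagnoses) for (ln in dx$treatment_lines)
    for (cc in ln$chemo_courses) for (ad in cc$agent_doses) {
      k <- paste0(ad$agent, " (", ad$units, ")")
      agent_tot[[k]] <- (agent_tot[[k]] %||% 0) + ad$dose
    }

  if (format == "json") {
    return(jsonlite::toJSON(list(
      patient_id = patient$patient_id, sex = patient$sex,
      birth_date = patient$birth_date,
      diagnoses = strip_class(patient$diagnoses),
      cumulative_doses = agent_tot,
      follow_up_events = strip_class(patient$follow_up_events)),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE))
  }

  L <- c(sprintf("# Treatment summary — patient %s", patient$patient_id),
         sprintf("%s, born %s, %s.", patient$sex, patient$birth_date, patient$vital_status), "")
  for (dx in patient$diagnoses) {
    L <- c(L, sprintf("## %s (%s, cancer #%d)%s",
                      gsub("_", " ", dx$disease_category), dx$date, dx$cancer_rank,
                      if (dx$tumor_bank_sample) " — tumor bank sample available" else ""))
    for (ln in dx$treatment_lines) {
      L <- c(L, sprintf("### Line %d (%s to %s)%s", ln$line_number,
                        ln$start_date, ln$end_date,
                        if (ln$line_number >= 2L) " — recurrence therapy" else ""))
      if (is_monitoring_line(ln)) {
        L <- c(L, "- Surveillance only (no oncological treatment).")
        next
      }
      for (s in ln$surgeries)
        L <- c(L, sprintf("- Surgery (%s): %s; carcinological impact: %s; functional impact: %s.",
                          s$date, s$organ, gsub("_", " ", s$carcinological_impact),
                          gsub("_", " ", s$functional_impact)))
      for (cc in ln$chemo_courses)
        L <- c(L, sprintf("- Chemotherapy %s/%s (%s to %s): %s.", cc$protocol_id, cc$arm_id,
                          cc$start_date, cc$end_date,
                          paste(vapply(cc$agent_doses, function(a)
                            sprintf("%s %g %s%s", a$agent, a$dose, a$units,
                                    if (a$source == "adapted") " (adapted)" else ""), ""),
                            collapse = ", ")))
      for (rc in ln$rt_courses)
        L <- c(L, sprintf("- Radiotherapy (%s to %s): field(s) %s, prescribed %g Gy; %s",
                          rc$start_date, rc$end_date,
                          paste(rc$fields_irradiated, collapse = ", "), rc$prescribed_dose,
                          if (rc$dosimetry_available)
                            paste0("organ doses: ",
                                   paste(vapply(rc$organ_doses, function(d)
                                     sprintf("%s %g Gy", d$organ, d$mean_dose), ""),
                                     collapse = ", "), ".")
                          else "precise dosimetric data missing (field and prescribed dose only)."))
      if (!is.null(ln$hsct))
        L <- c(L, sprintf("- Hematopoietic stem-cell transplantation (%s): %s%s.",
                          ln$hsct$date, ln$hsct$type,
                          if (!is.null(ln$hsct$graft_source))
                            paste0(", graft: ", ln$hsct$graft_source) else ""))
      if (length(ln$supportive_care))
        L <- c(L, sprintf("- Supportive care: %s.",
                          paste(gsub("_", " ", ln$supportive_care), collapse = ", ")))
    }
  }
  if (length(agent_tot)) {
    L <- c(L, "", "## Cumulative chemotherapy doses (all lines)")
    for (k in names(agent_tot)) L <- c(L, sprintf("- %s: %g", k, agent_tot[[k]]))
  }
  if (length(patient$follow_up_events)) {
    L <- c(L, "", "## Follow-up events")
    for (ev in patient$follow_up_events)
      L <- c(L, sprintf("- %s: %s (%s)%s%s", ev$date, gsub("_", " ", ev$event_type),
                        ev$organ_category,
                        if (!is.null(ev$ctcae_grade)) sprintf(", CTCAE grade %d", ev$ctcae_grade) else "",
                        if (nzchar(ev$description)) paste0(" — ", ev$description) else ""))
  }
  paste(L, collapse = "\n")
}

# keyed FNV-1a hash of a string, folded into a valid RNG seed
keyed_hash <- function(key, s) {
  bytes <- utf8ToInt(paste0(key, "\x1f", s))
  h <- 18652614L   # FNV offset basis reduced mod 2^31 - 1
  for (b in bytes) {
    h <- bitwXor(h, b)                 # stays within integer range
    h <- (h * 16777619) %% 2147483647  # double-precision exact below 2^53
  }
  as.integer(h)
}

#' Build a pseudonymization map
#'
#' Generates one random-looking 12-character identifier per patient id,
#' keyed on a secret: the same key always yields the same identifiers
#' (reproducible exports), a different key yields an unrelated set, and
#' the identifiers carry no information from the patient id without the
#' key. The map is injective by construction.
#'
#' @param patient_ids character vector of patient ids.
#' @param key secret key string; keep it out of any export.
#' @return a `survplan_pseudonyms`: named character vector
#'   patient_id -> pseudonym, with the key stored as an attribute.
#' @export
pseudonym_map <- function(patient_ids, key) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  ids <- sort(unique(patient_ids))
  seen <- character()
  tokens <- vapply(ids, function(id) {
    salt <- 0L
    repeat {
      h <- keyed_hash(key, paste0(id, ":", salt))
      chars <- character(12L)
      for (j in 1:12) {            # minstd Lehmer stream from the keyed hash
        h <- (h * 48271) %% 2147483647
        chars[j] <- letters[h %% 26L + 1L]
      }
      tok <- paste(chars, collapse = "")
      if (!tok %in% seen) break
      salt <- salt + 1L
    }
    seen <<- c(seen, tok)
    tok
  }, "")
  structure(stats::setNames(tokens, ids), class = "survplan_pseudonyms", key = key)
}

first_line_flags <- function(patient) {
  ln <- patient$diagnoses[[1]]$treatment_lines[[1]]
  list(surgery = length(ln$surgeries) > 0L,
       medical = length(ln$chemo_courses) > 0L,
       radiotherapy = length(ln$rt_courses) > 0L,
       autotransplant = !is.null(ln$hsct) && ln$hsct$type == "autograft",
       allograft = !is.null(ln$hsct) && ln$hsct$type == "allograft",
       monitoring = is_monitoring_line(ln))
}

#' Export a pseudonymized cohort for research
#'
#' One patient-level table plus long tables for treatments and follow-up
#' events. Patient ids are replaced by generated identifiers; direct
#' identifiers are excluded (the birth date is exported as birth year only,
#' with ages pre-computed). Patients without research consent are excluded
#' and counted in the manifest, unless listed in `consent_override`.
#'
#' @param patients list of validated `survplan_patient`s.
#' @param pseudonyms a `survplan_pseudonyms` map covering all exported ids
#'   (or a key string, from which a map is built).
#' @param consent_override patient ids to export despite missing consent.
#' @return list with data.frames `patients`, `treatments`, `events` and a
#'   `manifest` (counts, versions).
#' @export
export_cohort <- function(patients, pseudonyms, consent_override = character()) {
  patients <- lapply(patients, validate_patient)
  ids <- vapply(patients, `[[`, "", "patient_id")
  if (is.character(pseudonyms) && is.null(attr(pseudonyms, "key")))
    pseudonyms <- pseudonym_map(ids, key = pseudonyms)
  consented <- vapply(patients, function(p)
    isTRUE(p$consent_research) || p$patient_id %in% consent_override, TRUE)
  excluded <- sum(!consented)
  patients <- patients[consented]

  prow <- function(p) {
    dx1 <- p$diagnoses[[1]]
    fl <- first_line_flags(p)
    data.frame(
      pseudonym = unname(pseudonyms[[p$patient_id]]),
      sex = p$sex,
      birth_year = as.integer(format(as.Date(p$birth_date), "%Y")),
      vital_status = p$vital_status,
      disease_category = dx1$disease_category,
      age_at_diagnosis = round(age_years(p$birth_date, dx1$date), 2),
      n_diagnoses = length(p$diagnoses),
      n_treatment_lines = sum(vapply(p$diagnoses, function(d) length(d$treatment_lines), 0L)),
      first_line_surgery = fl$surgery,
      first_line_medical = fl$medical,
      first_line_radiotherapy = fl$radiotherapy,
      first_line_monitoring = fl$monitoring,
      hsct = fl$autotransplant || fl$allograft ||
        any(vapply(p$diagnoses, function(d) any(vapply(d$treatment_lines, function(l)
          !is.null(l$hsct), TRUE)), TRUE)),
      tumor_bank = any(vapply(p$diagnoses, `[[`, TRUE, "tumor_bank_sample")),
      edi_quintile = as.character(p$edi_quintile %||% NA_character_),
      stringsAsFactors = FALSE)
  }

  trow <- function(p) {
    out <- list()
    for (dx in p$diagnoses) for (ln in dx$treatment_lines) {
      add <- function(modality, detail, value, units) {
        out[[length(out) + 1L]] <<- data.frame(
          pseudonym = unname(pseudonyms[[p$patient_id]]),
          cancer_rank = dx$cancer_rank, line_number = ln$line_number,
          year = as.integer(format(as.Date(ln$start_date), "%Y")),
          modality = modality, detail = detail,
          value = value, units = units, stringsAsFactors = FALSE)
      }
      for (s in ln$surgeries) add("surgery", s$organ, NA_real_, s$functional_impact)
      for (cc in ln$chemo_courses) for (ad in cc$agent_doses)
        add("chemotherapy", ad$agent, ad$dose, ad$units)
      for (rc in ln$rt_courses)
        add("radiotherapy", paste(rc$fields_irradiated, collapse = "+"),
            rc$prescribed_dose, "Gy")
      if (!is.null(ln$hsct)) add("hsct", ln$hsct$type, NA_real_, "")
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  erow <- function(p) {
    if (!length(p$follow_up_events)) return(NULL)
    do.call(rbind, lapply(p$follow_up_events, function(ev) data.frame(
      pseudonym = unname(pseudonyms[[p$patient_id]]),
      year = as.integer(format(as.Date(ev$date), "%Y")),
      event_type = ev$event_type, organ_category = ev$organ_category,
      ctcae_grade = if (is.null(ev$ctcae_grade)) NA_integer_ else ev$ctcae_grade,
      stringsAsFactors = FALSE)))
  }

  rbind_or_empty <- function(xs, proto) {
    xs <- Filter(Negate(is.null), xs)
    if (length(xs)) do.call(rbind, xs) else proto
  }

  list(
    patients = rbind_or_empty(lapply(patients, prow),
                              data.frame(pseudonym = character())),
    treatments = rbind_or_empty(lapply(patients, trow),
                                data.frame(pseudonym = character())),
    events = rbind_or_empty(lapply(patients, erow),
                            data.frame(pseudonym = character())),
    manifest = list(n_exported = length(patients),
                    n_excluded_no_consent = excluded,
                    exported_fields_note = "birth date reduced to year; ages pre-computed",
                    package_version = as.character(utils::packageVersion("survplan"))))
}
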