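#' Validate a structured treatment-summary record
#'
#' Checks a parsed patient mapping (from JSON or YAML) against the treatment
#' summary data model: administrative data, one or more diagnoses each with
#' numbered treatment lines (surgery with carcinological and functional
#' impact, chemotherapy courses with per-agent cumulative doses, radiotherapy
#' courses with fields/prescribed dose and optional per-organ dosimetry,
#' transplantation, supportive care), follow-up events with optional CTCAE
#' grades, predisposition syndromes, lifestyle and social data.
#'
#' Validation is canonicalizing and idempotent: optional collections default
#' to empty lists, and validating an already-valid record returns an equal
#' record. Eligibility requires age under 25 years at first diagnosis,
#' checked at the date of diagnosis.
#'
#' @param record a named list (parsed JSON/YAML), or an already validated
#'   `survplan_patient`.
#' @return the canonicalized record, classed `survplan_patient`.
#' @examples
#' p <- example_patient()
#' validate_patient(p)$patient_id
#' @export
validate_patient <- function(record) {
  if (!is.list(record)) stop("patient record must be a named list", call. = FALSE)
  v <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("patient record invalid at '", field, "': ", msg, call. = FALSE)
  }
  req_chr <- function(x, field) {
    v(is.character(x) && length(x) == 1L && nzchar(x), field, "required non-empty string")
    x
  }
  req_enum <- function(x, field, values) {
    v(is.character(x) && length(x) == 1L && x %in% values, field,
      paste0("must be one of {", paste(values, collapse = ", "), "}"))
    x
  }
  opt_num <- function(x, field) {
    if (is.null(x)) return(NULL)
    v(is.numeric(x) && length(x) == 1L && is.finite(x), field, "must be a number")
    as.numeric(x)
  }
  as_list <- function(x) if (is.null(x)) list() else {
    if (!is.list(x)) stop("expected a list", call. = FALSE)
    x
  }

  out <- list()
  out$patient_id <- req_chr(record$patient_id, "patient_id")
  out$sex <- req_enum(record$sex, "sex", c("male", "female"))
  birth <- as_iso_date(req_chr(record$birth_date, "birth_date"), "birth_date")
  out$birth_date <- format(birth)
  out$vital_status <- req_enum(record$vital_status %||% "alive", "vital_status",
                               c("alive", "deceased"))
  centers <- record$centers
  v(length(centers) >= 1L, "centers", "at least one center required")
  out$centers <- unique(vapply(centers, as.character, ""))

  diagnoses <- as_list(record$diagnoses)
  v(length(diagnoses) >= 1L, "diagnoses", "at least one diagnosis required")
  out$diagnoses <- lapply(seq_along(diagnoses), function(i) {
    validate_diagnosis(diagnoses[[i]], birth, sprintf("diagnoses[%d]", i))
  })
  dx_dates <- as.Date(vapply(out$diagnoses, `[[`, "", "date"))
  v(!is.unsorted(dx_dates), "diagnoses", "diagnoses must be ordered by date")
  age1 <- age_years(birth, dx_dates[1])
  if (age1 >= 25)
    stop("inclusion error: age at first diagnosis is ", round(age1, 1),
         " years; eligibility requires under 25 years", call. = FALSE)

  fue <- as_list(record$follow_up_events)
  out$follow_up_events <- lapply(seq_along(fue), function(i) {
    validate_followup_event(fue[[i]], birth, sprintf("follow_up_events[%d]", i))
  })

  pre <- as_list(record$predispositions)
  out$predispositions <- lapply(seq_along(pre), function(i) {
    e <- pre[[i]]
    list(name = req_chr(e$name, sprintf("predispositions[%d].name", i)),
         gene = if (is.null(e$gene)) NULL else as.character(e$gene),
         confirmed = isTRUE(e$confirmed))
  })

  out$comorbidities <- as.character(unlist(record$comorbidities))
  ls <- as_list(record$lifestyle)
  out$lifestyle <- list(
    smoking_status = req_enum(ls$smoking_status %||% "unknown", "lifestyle.smoking_status", yes_no_unknown()),
    cannabis_use = req_enum(ls$cannabis_use %||% "unknown", "lifestyle.cannabis_use", yes_no_unknown()),
    unhealthy_alcohol_use = req_enum(ls$unhealthy_alcohol_use %||% "unknown", "lifestyle.unhealthy_alcohol_use", yes_no_unknown()),
    physical_activity = req_enum(ls$physical_activity %||% "unknown", "lifestyle.physical_activity",
                                 c("none", "occasional", "regular", "unknown")))
  so <- as_list(record$social)
  out$social <- list(
    current_class_or_occupation = if (is.null(so$current_class_or_occupation)) "" else
      as.character(so$current_class_or_occupation),
    sports_practice = req_enum(so$sports_practice %||% "unknown", "social.sports_practice", yes_no_unknown()))
  out$residence_unit <- if (is.null(record$residence_unit)) NULL else
    req_chr(record$residence_unit, "residence_unit")
  if (!is.null(record$edi_quintile)) out$edi_quintile <- record$edi_quintile
  out$consent_research <- isTRUE(record$consent_research %||% TRUE)

  structure(out, class = "survplan_patient")
}

validate_diagnosis <- function(dx, birth, path) {
  v <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("patient record invalid at '", path, ".", field, "': ", msg, call. = FALSE)
  }
  date <- as_iso_date(dx$date, paste0(path, ".date"))
  v(date >= birth, "date", "diagnosis date precedes birth date")
  v(dx$disease_category %in% disease_categories(), "disease_category",
    paste0("must be one of {", paste(disease_categories(), collapse = ", "), "}"))
  rank <- dx$cancer_rank %||% 1L
  v(is.numeric(rank) && rank >= 1 && rank == as.integer(rank), "cancer_rank", "integer >= 1")
  lines <- dx$treatment_lines
  v(is.list(lines) && length(lines) >= 1L, "treatment_lines", "at least one treatment line required")
  lines <- lapply(seq_along(lines), function(i) {
    validate_treatment_line(lines[[i]], sprintf("%s.treatment_lines[%d]", path, i))
  })
  nums <- vapply(lines, `[[`, 0L, "line_number")
  v(identical(nums, seq_along(lines)), "treatment_lines",
    "lines must be numbered 1..k without gaps")
  list(date = format(date),
       disease_category = dx$disease_category,
       cancer_rank = as.integer(rank),
       treatment_lines = lines,
       tumor_bank_sample = isTRUE(dx$tumor_bank_sample))
}

validate_treatment_line <- function(ln, path) {
  v <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("patient record invalid at '", path, ".", field, "': ", msg, call. = FALSE)
  }
  start <- as_iso_date(ln$start_date, paste0(path, ".start_date"))
  end <- as_iso_date(ln$end_date, paste0(path, ".end_date"))
  v(start <= end, "end_date", "end_date precedes start_date")
  num <- ln$line_number
  v(is.numeric(num) && num >= 1 && num == as.integer(num), "line_number", "integer >= 1")

  surgeries <- lapply(seq_along(ln$surgeries %||% list()), function(i) {
    s <- ln$surgeries[[i]]
    sp <- sprintf("%s.surgeries[%d]", path, i)
    vv <- function(cond, f, m) if (!isTRUE(cond))
      stop("patient record invalid at '", sp, ".", f, "': ", m, call. = FALSE)
    vv(s$organ %in% organ_codes(), "organ", "unknown organ code")
    vv(s$carcinological_impact %in% carcinological_impacts(), "carcinological_impact",
       "unknown carcinological impact")
    vv(s$functional_impact %in% functional_impacts(), "functional_impact",
       "unknown functional impact")
    list(date = format(as_iso_date(s$date, paste0(sp, ".date"))),
         organ = s$organ,
         carcinological_impact = s$carcinological_impact,
         functional_impact = s$functional_impact)
  })

  chemo <- lapply(seq_along(ln$chemo_courses %||% list()), function(i) {
    cc <- ln$chemo_courses[[i]]
    cp <- sprintf("%s.chemo_courses[%d]", path, i)
    doses <- lapply(seq_along(cc$agent_doses %||% list()), function(j) {
      ad <- cc$agent_doses[[j]]
      ap <- sprintf("%s.agent_doses[%d]", cp, j)
      if (!(is.numeric(ad$dose) && ad$dose >= 0))
        stop("patient record invalid at '", ap, ".dose': cumulative dose must be >= 0", call. = FALSE)
      units <- ad$units %||% "mg/m2"
      if (!units %in% c("mg/m2", "mg/kg"))
        stop("patient record invalid at '", ap, ".units': must be mg/m2 or mg/kg", call. = FALSE)
      src <- ad$source %||% "table_default"
      if (!src %in% c("table_default", "adapted"))
        stop("patient record invalid at '", ap, ".source': must be table_default or adapted", call. = FALSE)
      list(agent = as.character(ad$agent), dose = as.numeric(ad$dose),
           units = units, source = src)
    })
    list(protocol_id = as.character(cc$protocol_id %||% ""),
         arm_id = as.character(cc$arm_id %||% ""),
         start_date = format(as_iso_date(cc$start_date, paste0(cp, ".start_date"))),
         end_date = format(as_iso_date(cc$end_date, paste0(cp, ".end_date"))),
         agent_doses = doses,
         hsct_conditioning = isTRUE(cc$hsct_conditioning))
  })

  rt <- lapply(seq_along(ln$rt_courses %||% list()), function(i) {
    rc <- ln$rt_courses[[i]]
    rp <- sprintf("%s.rt_courses[%d]", path, i)
    if (!(is.numeric(rc$prescribed_dose) && rc$prescribed_dose > 0))
      stop("patient record invalid at '", rp, ".prescribed_dose': must be > 0 Gy", call. = FALSE)
    fields <- as.character(unlist(rc$fields_irradiated))
    if (length(fields) == 0L)
      stop("patient record invalid at '", rp, ".fields_irradiated': at least one field required", call. = FALSE)
    od <- lapply(seq_along(rc$organ_doses %||% list()), function(j) {
      d <- rc$organ_doses[[j]]
      op <- sprintf("%s.organ_doses[%d]", rp, j)
      if (!d$organ %in% organ_codes())
        stop("patient record invalid at '", op, ".organ': unknown organ code", call. = FALSE)
      if (!(is.numeric(d$mean_dose) && d$mean_dose >= 0))
        stop("patient record invalid at '", op, ".mean_dose': must be >= 0 Gy", call. = FALSE)
      maxd <- d$max_dose
      if (!is.null(maxd) && (!is.numeric(maxd) || maxd < d$mean_dose))
        stop("patient record invalid at '", op, ".max_dose': must be >= mean_dose", call. = FALSE)
      c(list(organ = d$organ, mean_dose = as.numeric(d$mean_dose)),
        if (!is.null(maxd)) list(max_dose = as.numeric(maxd)))
    })
    dosim <- isTRUE(rc$dosimetry_available %||% (length(od) > 0L))
    if (dosim != (length(od) > 0L))
      stop("patient record invalid at '", rp,
           "': dosimetry_available must be true iff organ_doses are present", call. = FALSE)
    list(start_date = format(as_iso_date(rc$start_date, paste0(rp, ".start_date"))),
         end_date = format(as_iso_date(rc$end_date, paste0(rp, ".end_date"))),
         fields_irradiated = fields,
         prescribed_dose = as.numeric(rc$prescribed_dose),
         organ_doses = od,
         dosimetry_available = dosim)
  })

  hsct <- ln$hsct
  if (!is.null(hsct)) {
    if (!hsct$type %in% c("autograft", "allograft"))
      stop("patient record invalid at '", path, ".hsct.type': must be autograft or allograft", call. = FALSE)
    hsct <- list(date = format(as_iso_date(hsct$date, paste0(path, ".hsct.date"))),
                 type = hsct$type,
                 graft_source = if (is.null(hsct$graft_source)) NULL else as.character(hsct$graft_source))
  }

  sc <- as.character(unlist(ln$supportive_care))
  bad <- setdiff(sc, supportive_care_codes())
  v(length(bad) == 0L, "supportive_care", paste0("unknown code(s): ", paste(bad, collapse = ", ")))

  anthro <- function(a, field) {
    if (is.null(a)) return(NULL)
    if (!(is.numeric(a$height_cm) && is.numeric(a$weight_kg)))
      stop("patient record invalid at '", path, ".", field,
           "': needs height_cm and weight_kg", call. = FALSE)
    list(height_cm = as.numeric(a$height_cm), weight_kg = as.numeric(a$weight_kg))
  }

  list(line_number = as.integer(num),
       start_date = format(start), end_date = format(end),
       surgeries = surgeries, chemo_courses = chemo, rt_courses = rt,
       hsct = hsct, supportive_care = sc,
       anthropometry_start = anthro(ln$anthropometry_start, "anthropometry_start"),
       anthropometry_end = anthro(ln$anthropometry_end, "anthropometry_end"))
}

validate_followup_event <- function(ev, birth, path) {
  date <- as_iso_date(ev$date, paste0(path, ".date"))
  if (!ev$event_type %in% followup_event_types())
    stop("patient record invalid at '", path, ".event_type': unknown event type", call. = FALSE)
  grade <- ev$ctcae_grade
  if (!is.null(grade)) {
    if (!(is.numeric(grade) && grade %in% 1:5))
      stop("patient record invalid at '", path, ".ctcae_grade': must be an integer 1-5", call. = FALSE)
    grade <- as.integer(grade)
  }
  list(date = format(date),
       organ_category = as.character(ev$organ_category %||% ""),
       event_type = ev$event_type,
       ctcae_grade = grade,
       description = as.character(ev$description %||% ""))
}

#' Is a treatment line "simple monitoring"?
#'
#' A line with no surgery, chemotherapy, radiotherapy or transplantation is
#' a watch-and-wait ("simple monitoring") line.
#' @param line a validated treatment line.
#' @export
is_monitoring_line <- function(line) {
  length(line$surgeries) == 0L && length(line$chemo_courses) == 0L &&
    length(line$rt_courses) == 0L && is.null(line$hsct)
}

#' Derive per-organ status at a reference date
#'
#' An organ is `removed` if any surgery with complete functional removal, or
#' any follow-up event of type `organ_loss`, affected it on or before
#' `as_of`; `partially_removed` ranks below `removed`; organs never
#' mentioned are `intact`. Removal drives suppression of second-tumor
#' surveillance targeting the organ (e.g. a thyroidectomy recorded during
#' follow-up ends thyroid second-tumor surveillance).
#'
#' @param patient a validated `survplan_patient`.
#' @param as_of reference date.
#' @return named character vector over the full organ vocabulary with values
#'   in `intact`, `partially_removed`, `removed`.
#' @export
derive_organ_status <- function(patient, as_of) {
  patient <- validate_patient(patient)
  as_of <- as.Date(as_of)
  status <- stats::setNames(rep("intact", length(organ_codes())), organ_codes())
  rank <- c(intact = 0L, partially_removed = 1L, removed = 2L)
  bump <- function(organ, level) {
    if (rank[[level]] > rank[[status[[organ]]]]) status[[organ]] <<- level
  }
  for (dx in patient$diagnoses) for (ln in dx$treatment_lines) for (s in ln$surgeries) {
    if (as.Date(s$date) > as_of) next
    if (s$functional_impact == "complete_removal") bump(s$organ, "removed")
    else if (s$functional_impact == "partial_removal") bump(s$organ, "partially_removed")
  }
  for (ev in patient$follow_up_events) {
    if (ev$event_type == "organ_loss" && as.Date(ev$date) <= as_of &&
        ev$organ_category %in% organ_codes())
      bump(ev$organ_category, "removed")
  }
  status
}

#' Read / write patient records (JSON canonical, YAML for authoring)
#'
#' @param path file path; `.yaml`/`.yml` files are parsed as YAML, anything
#'   else as JSON.
#' @return `read_patient()` returns a validated `survplan_patient`.
#' @export
read_patient <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_patient(raw)
}

#' @param patient a validated record.
#' @rdname read_patient
#' @export
write_patient <- function(patient, path) {
  patient <- validate_patient(patient)
  jsonlite::write_json(strip_class(patient), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_class)
  }
  x
}

#' @export
print.survplan_patient <- function(x, ...) {
  dx1 <- x$diagnoses[[1]]
  cat("<survplan_patient ", x$patient_id, "> ", x$sex, ", born ", x$birth_date,
      "\n  first diagnosis: ", dx1$disease_category, " (", dx1$date, ", age ",
      sprintf("%.1f", age_years(x$birth_date, dx1$date)), " y), ",
      length(x$diagnoses), " diagnosis/es, ",
      sum(vapply(x$diagnoses, function(d) length(d$treatment_lines), 0L)),
      " treatment line(s)\n", sep = "")
  invisible(x)
}

#' A small worked example record
#'
#' A synthetic survivor of Hodgkin-type lymphoma treated with chemotherapy
#' and supra-diaphragmatic radiotherapy without organ dosimetry; used in
#' examples and the README.
#' @export
example_patient <- function() {
  list(
    patient_id = "PT-000001", sex = "female", birth_date = "2005-04-12",
    vital_status = "alive", centers = list("C1"),
    diagnoses = list(list(
      date = "2018-03-01", disease_category = "lymphoma", cancer_rank = 1,
      tumor_bank_sample = TRUE,
      treatment_lines = list(list(
        line_number = 1, start_date = "2018-03-10", end_date = "2018-09-20",
        chemo_courses = list(list(
          protocol_id = "LYMPH02", arm_id = "standard",
          start_date = "2018-03-10", end_date = "2018-07-15",
          agent_doses = list(
            list(agent = "doxorubicin", dose = 200, units = "mg/m2", source = "table_default"),
            list(agent = "bleomycin", dose = 60, units = "mg/m2", source = "table_default")))),
        rt_courses = list(list(
          start_date = "2018-08-01", end_date = "2018-09-10",
          fields_irradiated = list("supra_diaphragmatic"),
          prescribed_dose = 19.8, dosimetry_available = FALSE)))))),
    consent_research = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
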