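#' Synthetic survivor cohorts
#'
#' Generates cohorts of structurally valid patient records whose marginal
#' statistics reproduce the registered-cohort profile the package is
#' calibrated to: the nine-category disease mix, sex ratio, mean age at
#' diagnosis 8.34 years on [0, 23.2], first-line treatment marginals
#' (surgery, medical treatment, radiotherapy and their joint rate,
#' surgery-only share, transplants, simple monitoring), tumor-bank
#' availability, recurrences with their disease composition, and second
#' cancers with their type mix. Age at diagnosis is drawn from a gamma
#' distribution truncated to the observed range, with the scale solved
#' numerically so the truncated mean matches the calibration target.
#'
#' Half of the generated radiotherapy courses omit organ dosimetry so the
#' plan engine's degraded mode is exercised; every record passes
#' [validate_patient()].
#'
#' @name synthetic_cohort
NULL

#' Load a cohort preset
#'
#' @param name packaged preset name (currently `"table1"`) or a YAML path.
#' @return a validated `survplan_preset`.
#' @export
cohort_preset <- function(name = "table1") {
  path <- if (file.exists(name)) name else
    survplan_extdata(file.path("presets", paste0(name, ".yaml")))
  p <- yaml::read_yaml(path)
  probs <- c("sex_prob_male", "p_surgery", "p_medical_treatment", "p_radiotherapy",
             "p_rt_and_medical", "p_surgery_only", "p_autotransplant", "p_allograft",
             "p_simple_monitoring", "p_tumor_bank", "p_recurrence", "p_second_cancer",
             "p_third_cancer_given_second", "p_predisposition",
             "p_allograft_second_line", "p_dosimetry", "p_retrospective_era")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("preset field '", nm, "' must be a probability in [0, 1]", call. = FALSE)
  }
  dp <- unlist(p$disease_probs)
  if (!setequal(names(dp), disease_categories()))
    stop("disease_probs must cover exactly the nine disease categories", call. = FALSE)
  if (abs(sum(dp) - 1) > 1e-9)
    stop("disease_probs must sum to 1 (got ", sum(dp), ")", call. = FALSE)
  if (p$p_rt_and_medical > min(p$p_radiotherapy, p$p_medical_treatment) + 1e-12)
    stop("inconsistent preset: p_rt_and_medical exceeds min(p_radiotherapy, p_medical_treatment)",
         call. = FALSE)
  if (min(unlist(profile_cells(p))) < -1e-9)
    stop("inconsistent preset: p_medical_treatment incompatible with the simple ",
         "monitoring, surgery-only and radiotherapy shares", call. = FALSE)
  if (p$p_autotransplant + p$p_allograft > p$p_medical_treatment + 1e-12)
    stop("inconsistent preset: transplant rates exceed medical-treatment rate", call. = FALSE)
  structure(p, class = "survplan_preset")
}

# explicit first-line treatment-profile cells; any probability mass the
# marginals leave unallocated is absorbed by the surgery-only cell, so the
# monitoring, surgery, medical, radiotherapy and joint marginals hold exactly
profile_cells <- function(p) {
  cells <- list(
    monitoring = p$p_simple_monitoring,
    surgery_only = p$p_surgery * p$p_surgery_only,
    rt_only = p$p_radiotherapy - p$p_rt_and_medical,
    rt_medical = p$p_rt_and_medical,
    medical_only = p$p_medical_treatment - p$p_rt_and_medical)
  cells$surgery_only <- cells$surgery_only + (1 - sum(unlist(cells)))
  cells
}

# gamma scale such that the [0, b]-truncated mean equals target, shape fixed
solve_trunc_gamma_scale <- function(shape, b, target) {
  trunc_mean <- function(scale)
    scale * shape * stats::pgamma(b, shape + 1, scale = scale) /
      stats::pgamma(b, shape, scale = scale)
  stats::uniroot(function(s) trunc_mean(s) - target,
                 lower = 1e-3, upper = 100, tol = 1e-10)$root
}

r_trunc_gamma <- function(n, shape, scale, lo, hi) {
  p_hi <- stats::pgamma(hi, shape, scale = scale)
  p_lo <- stats::pgamma(lo, shape, scale = scale)
  stats::qgamma(p_lo + stats::runif(n) * (p_hi - p_lo), shape, scale = scale)
}

disease_protocols <- function() {
  list(leukemia = list(c("ALL01", "standard"), c("ALL01", "high_risk")),
       cerebral_tumor = list(c("BRAIN08", "pcv_like")),
       lymphoma = list(c("LYMPH02", "standard"), c("LYMPH02", "intensified")),
       sarcoma = list(c("SARC03", "vdc_ie"), c("OSTEO04", "map")),
       kidney_tumor = list(c("WILMS06", "avd")),
       neuroblastoma = list(c("NEURO05", "induction")),
       rare_tumor = list(c("RARE10", "platinum_based")),
       extra_cerebral_germ_cell_tumor = list(c("GERM07", "bep")),
       other = list(c("RARE10", "platinum_based")))
}

disease_rt_fields <- function() {
  list(leukemia = c("cranial"),
       cerebral_tumor = c("cranial"),
       lymphoma = c("supra_diaphragmatic", "supra_diaphragmatic", "cervical"),
       sarcoma = c("spinal", "pelvic"),
       kidney_tumor = c("abdominal"),
       neuroblastoma = c("abdominal"),
       rare_tumor = c("abdominal", "pelvic", "cervical"),
       extra_cerebral_germ_cell_tumor = c("abdominal", "pelvic"),
       other = c("abdominal", "cranial", "cervical"))
}

disease_surgery_organs <- function() {
  list(leukemia = "bone_marrow", cerebral_tumor = "brain", lymphoma = "spleen",
       sarcoma = "soft_tissue", kidney_tumor = "kidney", neuroblastoma = "kidney",
       rare_tumor = "liver", extra_cerebral_germ_cell_tumor = "ovary",
       other = "soft_tissue")
}

rand_date <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, 1L) - 1L
}

make_chemo_course <- function(protocol, arm, start, end, dose_table,
                              conditioning = FALSE) {
  rows <- dose_table[dose_table$protocol == protocol & dose_table$arm == arm, , drop = FALSE]
  list(protocol_id = protocol, arm_id = arm,
       start_date = format(start), end_date = format(end),
       agent_doses = lapply(seq_len(nrow(rows)), function(i)
         list(agent = rows$agent[i], dose = rows$cumulative_dose[i],
              units = rows$units[i], source = "table_default")),
       hsct_conditioning = conditioning)
}

make_rt_course <- function(field, start, end, exposure_map, with_dosimetry) {
  dose <- if (field == "TBI") 12 else round(stats::runif(1, 15, 50), 1)
  organs <- exposure_map[[field]]
  od <- list()
  if (with_dosimetry) {
    fr <- stats::runif(length(organs), 0.02, 1)
    od <- lapply(seq_along(organs), function(i) {
      md <- round(dose * fr[i], 1)
      list(organ = organs[i], mean_dose = md, max_dose = round(md * 1.2, 1))
    })
  }
  list(start_date = format(start), end_date = format(end),
       fields_irradiated = list(field), prescribed_dose = dose,
       organ_doses = od, dosimetry_available = with_dosimetry)
}

#' Generate a synthetic cohort
#'
#' @param preset a `survplan_preset` (see [cohort_preset()]).
#' @param n cohort size (default: the preset's `n`).
#' @param seed RNG seed (default: the preset's `seed`); the same seed and
#'   preset always reproduce the identical cohort.
#' @return list of validated `survplan_patient` records.
#' @examples
#' cohort <- generate_cohort(cohort_preset("table1"), n = 50, seed = 1)
#' cohort_profile(cohort)
#' @export
generate_cohort <- function(preset, n = preset$n, seed = preset$seed) {
  stopifnot(inherits(preset, "survplan_preset"))
  n <- as.integer(n)
  if (n == 0L) return(list())
  set.seed(as.integer(seed))
  dose_table <- load_dose_table()
  exposure_map <- load_exposure_map()

  dp <- unlist(preset$disease_probs)
  disease <- sample(names(dp), n, replace = TRUE, prob = dp)
  sex <- ifelse(stats::runif(n) < preset$sex_prob_male, "male", "female")
  shape <- preset$age_shape
  scale <- solve_trunc_gamma_scale(shape, preset$age_range[2], preset$age_mean)
  age <- r_trunc_gamma(n, shape, scale, preset$age_range[1], preset$age_range[2])

  # first-line treatment profile drawn from explicit cells so the monitoring,
  # surgery, medical, radiotherapy and RT-and-medical marginals hold exactly;
  # additional (non-exclusive) surgery is layered over the treated cells
  cells <- profile_cells(preset)
  profile <- sample(names(cells), n, replace = TRUE, prob = unlist(cells))
  monitoring <- profile == "monitoring"
  surgery_only <- profile == "surgery_only"
  medical <- profile %in% c("rt_medical", "medical_only")
  rt <- profile %in% c("rt_only", "rt_medical")
  denom <- 1 - cells$monitoring - cells$surgery_only
  q_surg <- if (denom > 0) max(0, (preset$p_surgery - cells$surgery_only) / denom) else 0
  surgery <- surgery_only | (!monitoring & !surgery_only & stats::runif(n) < q_surg)
  u_tx <- stats::runif(n)
  auto <- medical & u_tx < preset$p_autotransplant / preset$p_medical_treatment
  allo <- medical & !auto &
    u_tx < (preset$p_autotransplant + preset$p_allograft) / preset$p_medical_treatment
  tumor_bank <- stats::runif(n) < preset$p_tumor_bank
  predis <- stats::runif(n) < preset$p_predisposition
  rw <- unlist(preset$recurrence_disease_weights)
  p_rec <- pmin(1, preset$p_recurrence * rw[disease] / dp[disease])
  recurrence <- stats::runif(n) < p_rec
  second <- stats::runif(n) < preset$p_second_cancer
  third <- second & stats::runif(n) < preset$p_third_cancer_given_second
  retro <- stats::runif(n) < preset$p_retrospective_era
  dosim <- stats::runif(n) < preset$p_dosimetry

  scw <- unlist(preset$second_cancer_type_weights)
  protos <- disease_protocols()
  rt_fields <- disease_rt_fields()
  surg_organs <- disease_surgery_organs()

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    d <- disease[i]
    dx_date <- if (retro[i]) rand_date("1968-01-01", "2011-12-31") else
      rand_date("2012-01-01", "2022-11-30")
    birth <- dx_date - round(age[i] * 365.25)

    lines <- list()
    if (monitoring[i]) {
      lines[[1]] <- list(line_number = 1, start_date = format(dx_date),
                         end_date = format(add_period(dx_date, "P1Y")),
                         surgeries = list(), chemo_courses = list(),
                         rt_courses = list(), hsct = NULL,
                         supportive_care = list(), anthropometry_start = NULL,
                         anthropometry_end = NULL)
    } else {
      start <- dx_date + 10
      dur_days <- if (d == "leukemia") 900L else sample(180:400, 1L)
      end <- start + dur_days
      surgeries <- list()
      if (surgery[i]) {
        organ <- surg_organs[[d]]
        fi <- sample(c("partial_removal", "complete_removal", "none"), 1L,
                     prob = c(0.45, 0.35, 0.20))
        surgeries[[1]] <- list(date = format(start + 20),
                               organ = organ,
                               carcinological_impact = sample(carcinological_impacts(), 1L,
                                                              prob = c(0.7, 0.2, 0.1)),
                               functional_impact = fi)
      }
      chemo <- list(); hsct <- NULL
      if (medical[i]) {
        pa <- protos[[d]][[sample.int(length(protos[[d]]), 1L)]]
        chemo[[1]] <- make_chemo_course(pa[1], pa[2], start, min(end, start + 200), dose_table)
        if (auto[i] || allo[i]) {
          chemo[[2]] <- make_chemo_course("HDC09", "busmel", end - 30, end - 20,
                                          dose_table, conditioning = TRUE)
          hsct <- list(date = format(end - 15),
                       type = if (auto[i]) "autograft" else "allograft",
                       graft_source = if (allo[i]) "unrelated donor" else "peripheral blood")
        }
      }
      rtc <- list()
      if (rt[i]) {
        field <- if (allo[i]) "TBI" else {
          fs <- rt_fields[[d]]
          fs[sample.int(length(fs), 1L)]
        }
        rtc[[1]] <- make_rt_course(field, end - 60, end - 20, exposure_map, dosim[i])
      }
      supportive <- character()
      if (medical[i]) {
        if (d %in% c("leukemia", "lymphoma") && stats::runif(1) < 0.8)
          supportive <- c(supportive, "corticotherapy")
        if (stats::runif(1) < 0.5) supportive <- c(supportive, "transfusion")
      }
      lines[[1]] <- list(line_number = 1, start_date = format(start),
                         end_date = format(end),
                         surgeries = surgeries, chemo_courses = chemo,
                         rt_courses = rtc, hsct = hsct,
                         supportive_care = as.list(supportive),
                         anthropometry_start = NULL, anthropometry_end = NULL)
    }

    if (recurrence[i]) {
      l1_end <- as.Date(lines[[1]]$end_date)
      r_start <- l1_end + sample(200:1000, 1L)
      r_end <- r_start + sample(150:350, 1L)
      allo2 <- stats::runif(1) < preset$p_allograft_second_line
      chemo2 <- list(make_chemo_course("RARE10", "platinum_based", r_start,
                                       min(r_end, r_start + 120), dose_table))
      hsct2 <- NULL
      if (allo2) {
        chemo2[[2]] <- make_chemo_course("HDC09", "busmel", r_end - 30, r_end - 20,
                                         dose_table, conditioning = TRUE)
        hsct2 <- list(date = format(r_end - 15), type = "allograft",
                      graft_source = "unrelated donor")
      }
      lines[[2]] <- list(line_number = 2, start_date = format(r_start),
                         end_date = format(r_end), surgeries = list(),
                         chemo_courses = chemo2, rt_courses = list(), hsct = hsct2,
                         supportive_care = list(), anthropometry_start = NULL,
                         anthropometry_end = NULL)
    }

    diagnoses <- list(list(date = format(dx_date), disease_category = d,
                           cancer_rank = 1, treatment_lines = lines,
                           tumor_bank_sample = tumor_bank[i]))
    if (second[i]) {
      last_end <- as.Date(lines[[length(lines)]]$end_date)
      ranks <- if (third[i]) 2:3 else 2L
      for (r in ranks) {
        d2 <- sample(names(scw), 1L, prob = scw)
        d2_date <- last_end + sample(1000:4000, 1L)
        d2_start <- d2_date + 10
        d2_end <- d2_start + 200
        diagnoses[[r]] <- list(
          date = format(d2_date), disease_category = d2, cancer_rank = r,
          treatment_lines = list(list(
            line_number = 1, start_date = format(d2_start), end_date = format(d2_end),
            surgeries = list(),
            chemo_courses = list(make_chemo_course("RARE10", "platinum_based",
                                                   d2_start, d2_end, dose_table)),
            rt_courses = list(), hsct = NULL, supportive_care = list(),
            anthropometry_start = NULL, anthropometry_end = NULL)),
          tumor_bank_sample = FALSE)
        last_end <- d2_end
      }
    }

    rec <- list(patient_id = sprintf("PT-%06d", i), sex = sex[i],
                birth_date = format(birth), vital_status = "alive",
                centers = list(sprintf("C%d", sample.int(11L, 1L))),
                diagnoses = diagnoses,
                follow_up_events = list(),
                predispositions = if (predis[i])
                  list(list(name = sample(c("li_fraumeni", "nf1", "dicer1",
                                            "fanconi_anemia", "other_cps"), 1L),
                            gene = NULL, confirmed = TRUE)) else list(),
                comorbidities = list(), lifestyle = list(), social = list(),
                consent_research = TRUE)
    cohort[[i]] <- validate_patient(rec)
  }
  enforce_coverage(cohort)
}

# engine-path coverage quota: at least one degraded-mode patient, one
# organ-removal patient and one confirmed predisposition carrier, whenever
# the cohort contains eligible patients to carry the flag
enforce_coverage <- function(cohort) {
  has_rt_blind <- FALSE; has_removed <- FALSE; has_predis <- FALSE
  first_rt <- NA_integer_; first_surg <- NA_integer_
  for (i in seq_along(cohort)) {
    for (dx in cohort[[i]]$diagnoses) for (ln in dx$treatment_lines) {
      if (length(ln$rt_courses)) {
        if (is.na(first_rt)) first_rt <- i
        if (any(!vapply(ln$rt_courses, `[[`, TRUE, "dosimetry_available")))
          has_rt_blind <- TRUE
      }
      if (length(ln$surgeries)) {
        if (is.na(first_surg)) first_surg <- i
        if (any(vapply(ln$surgeries, `[[`, "", "functional_impact") == "complete_removal"))
          has_removed <- TRUE
      }
    }
    if (length(cohort[[i]]$predispositions)) has_predis <- TRUE
  }
  if (!has_rt_blind && !is.na(first_rt)) {
    p <- cohort[[first_rt]]
    rc <- p$diagnoses[[1]]$treatment_lines[[1]]$rt_courses[[1]]
    rc$organ_doses <- list(); rc$dosimetry_available <- FALSE
    p$diagnoses[[1]]$treatment_lines[[1]]$rt_courses[[1]] <- rc
    cohort[[first_rt]] <- validate_patient(p)
  }
  if (!has_removed && !is.na(first_surg)) {
    p <- cohort[[first_surg]]
    p$diagnoses[[1]]$treatment_lines[[1]]$surgeries[[1]]$functional_impact <- "complete_removal"
    cohort[[first_surg]] <- validate_patient(p)
  }
  if (!has_predis && length(cohort)) {
    p <- cohort[[1]]
    p$predispositions <- list(list(name = "other_cps", gene = NULL, confirmed = TRUE))
    cohort[[1]] <- validate_patient(p)
  }
  cohort
}

#' Profile a cohort (counts and percentages)
#'
#' Exact counting over a cohort: disease mix of the first cancer, sex
#' split, mean age at first diagnosis with range, tumor-bank availability,
#' first-line treatment modality counts (a patient counts under a modality
#' iff the first line of the first cancer includes it), transplants,
#' simple monitoring, recurrences (second-line therapy registered) and
#' second cancers.
#'
#' @param patients list of validated `survplan_patient`s.
#' @return a `survplan_profile` list of counts and percentages (percentages
#'   `NULL` for an empty cohort).
#' @export
cohort_profile <- function(patients) {
  n <- length(patients)
  if (n == 0L)
    return(structure(list(n = 0L, counts = list(), percentages = NULL,
                          age_mean = NULL, age_range = NULL), class = "survplan_profile"))
  patients <- lapply(patients, function(p)
    if (inherits(p, "survplan_patient")) p else validate_patient(p))
  dx1 <- lapply(patients, function(p) p$diagnoses[[1]])
  disease <- vapply(dx1, `[[`, "", "disease_category")
  ages <- vapply(patients, function(p)
    age_years(p$birth_date, p$diagnoses[[1]]$date), 0)
  flags <- lapply(patients, first_line_flags)
  g <- function(nm) vapply(flags, `[[`, TRUE, nm)
  counts <- list(
    disease = table(factor(disease, levels = disease_categories())),
    male = sum(vapply(patients, `[[`, "", "sex") == "male"),
    tumor_bank = sum(vapply(patients, function(p)
      any(vapply(p$diagnoses, `[[`, TRUE, "tumor_bank_sample")), TRUE)),
    surgery = sum(g("surgery")),
    medical = sum(g("medical")),
    radiotherapy = sum(g("radiotherapy")),
    rt_and_medical = sum(g("radiotherapy") & g("medical")),
    surgery_only = sum(g("surgery") & !g("medical") & !g("radiotherapy")),
    autotransplant = sum(g("autotransplant")),
    allograft = sum(g("allograft")),
    monitoring = sum(g("monitoring")),
    recurrence = sum(vapply(patients, function(p)
      any(vapply(p$diagnoses, function(d) length(d$treatment_lines) > 1L, TRUE)), TRUE)),
    second_cancer = sum(vapply(patients, function(p) length(p$diagnoses) > 1L, TRUE)))
  pct <- lapply(counts, function(x) 100 * as.numeric(x) / n)
  names(pct$disease) <- names(counts$disease)
  structure(list(n = n, counts = counts, percentages = pct,
                 age_mean = mean(ages), age_range = range(ages)),
            class = "survplan_profile")
}

#' @export
print.survplan_profile <- function(x, ...) {
  cat("<survplan_profile> n =", x$n, "\n")
  if (x$n == 0L) return(invisible(x))
  cat(sprintf("  mean age at diagnosis %.2f y [%.1f-%.1f]\n",
              x$age_mean, x$age_range[1], x$age_range[2]))
  cat(sprintf("  male %.1f%%, tumor bank %.1f%%\n",
              x$percentages$male, x$percentages$tumor_bank))
  cat("  disease mix (%):\n")
  d <- x$percentages$disease
  for (nm in names(d)) cat(sprintf("    %-32s %5.1f\n", nm, d[[nm]]))
  cat(sprintf(paste0("  first line: surgery %.1f%%, medical %.1f%%, RT %.1f%%, ",
                     "RT+medical %.1f%%,\n    autotransplant %.1f%%, allograft %.1f%%, ",
                     "monitoring %.1f%%\n"),
              x$percentages$surgery, x$percentages$medical, x$percentages$radiotherapy,
              x$percentages$rt_and_medical, x$percentages$autotransplant,
              x$percentages$allograft, x$percentages$monitoring))
  cat(sprintf("  recurrence %.1f%%, second cancer %.1f%%\n",
              x$percentages$recurrence, x$percentages$second_cancer))
  invisible(x)
}

#' Write a cohort to disk (one JSON per patient + CSV index)
#' @param patients cohort list.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(patient_id = character(), file = character(),
                    disease_category = character(), stringsAsFactors = FALSE)
  for (p in patients) {
    f <- file.path(dir, paste0(p$patient_id, ".json"))
    write_patient(p, f)
    idx <- rbind(idx, data.frame(patient_id = p$patient_id, file = basename(f),
                                 disease_category = p$diagnoses[[1]]$disease_category,
                                 stringsAsFactors = FALSE))
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory containing `index.csv`.
#' @export
read_cohort <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  lapply(idx$file, function(f) read_patient(file.path(dir, f)))
}
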