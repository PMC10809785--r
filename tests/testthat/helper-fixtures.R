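# Fixture builders and independent oracles shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid patient, customizable per test.
make_patient <- function(patient_id = "PT-900001", sex = "female",
                         birth_date = "2005-04-12",
                         dx_date = "2015-06-01", disease = "lymphoma",
                         surgeries = list(), chemo_courses = list(),
                         rt_courses = list(), hsct = NULL,
                         supportive_care = list(),
                         follow_up_events = list(), predispositions = list(),
                         extra_lines = list(),
                         line_start = "2015-06-15", line_end = "2016-03-01",
                         consent_research = TRUE, residence_unit = NULL) {
  lines <- c(list(list(line_number = 1, start_date = line_start, end_date = line_end,
                       surgeries = surgeries, chemo_courses = chemo_courses,
                       rt_courses = rt_courses, hsct = hsct,
                       supportive_care = supportive_care)),
             extra_lines)
  list(patient_id = patient_id, sex = sex, birth_date = birth_date,
       vital_status = "alive", centers = list("C1"),
       diagnoses = list(list(date = dx_date, disease_category = disease,
                             cancer_rank = 1, treatment_lines = lines,
                             tumor_bank_sample = FALSE)),
       follow_up_events = follow_up_events,
       predispositions = predispositions,
       consent_research = consent_research,
       residence_unit = residence_unit)
}

chemo_course <- function(agents, start = "2015-06-15", end = "2015-12-01",
                         protocol = "LYMPH02", arm = "standard") {
  list(protocol_id = protocol, arm_id = arm, start_date = start, end_date = end,
       agent_doses = lapply(names(agents), function(a)
         list(agent = a, dose = agents[[a]], units = "mg/m2", source = "adapted")),
       hsct_conditioning = FALSE)
}

rt_course <- function(fields, prescribed = 30, organ_doses = NULL,
                      start = "2016-01-05", end = "2016-02-20") {
  list(start_date = start, end_date = end,
       fields_irradiated = as.list(fields), prescribed_dose = prescribed,
       organ_doses = if (is.null(organ_doses)) list() else
         lapply(names(organ_doses), function(o)
           list(organ = o, mean_dose = organ_doses[[o]])),
       dosimetry_available = !is.null(organ_doses))
}

surgery_record <- function(organ, functional = "none",
                           carcinological = "complete_resection",
                           date = "2015-06-20") {
  list(date = date, organ = organ, carcinological_impact = carcinological,
       functional_impact = functional)
}

# --- Kleene brute-force oracle -------------------------------------------
# Result is TRUE iff every TRUE/FALSE substitution of the UNKNOWN leaves is
# true, FALSE iff every substitution is false, UNKNOWN (NA) otherwise.
# Works on leaf truth values, independently of the comparator machinery.
kleene_oracle <- function(shape, leaf_values) {
  leaf_values <- unname(leaf_values)
  unknown <- which(is.na(leaf_values))
  if (length(unknown) == 0L) {
    return(two_valued_eval(shape, leaf_values))
  }
  results <- logical(0)
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(unknown)))
  for (r in seq_len(nrow(grid))) {
    filled <- leaf_values
    filled[unknown] <- unlist(grid[r, ])
    results <- c(results, two_valued_eval(shape, filled))
  }
  if (all(results)) TRUE else if (all(!results)) FALSE else NA
}

two_valued_eval <- function(shape, leaf_values) {
  i <- 0L
  rec <- function(node) {
    if (identical(node, "leaf")) {
      i <<- i + 1L
      return(leaf_values[i])
    }
    op <- node[[1]]
    if (op == "not") return(!rec(node[[2]]))
    kids <- vapply(node[-1], rec, NA)
    if (op == "and") all(kids) else any(kids)
  }
  rec(shape)
}

# enumerate predicate shapes with exactly n leaves (nodes: and/or binary, not)
predicate_shapes <- function(n, depth = 0) {
  if (depth > 4) return(list())
  if (n == 1) {
    base <- list("leaf")
    return(c(base, lapply(base, function(s) list("not", s))))
  }
  out <- list()
  for (k in 1:(n - 1)) {
    left <- predicate_shapes(k, depth + 1)
    right <- predicate_shapes(n - k, depth + 1)
    for (l in left) for (r in right) {
      out <- c(out, list(list("and", l, r), list("or", l, r)))
    }
  }
  # cap the combinatorial explosion but keep shape diversity
  if (length(out) > 40) out <- out[seq(1, length(out), length.out = 40)]
  out
}

# turn a shape into a survplan predicate whose leaves read distinct numeric
# facts f1..fn compared with ">= 1", so leaf truth is driven by fact values
shape_to_predicate <- function(shape) {
  i <- 0L
  rec <- function(node) {
    if (identical(node, "leaf")) {
      i <<- i + 1L
      return(list(fact = paste0("cumulative_dose(f", i, ")"), op = ">=", value = 1))
    }
    op <- node[[1]]
    if (op == "not") return(list(not = rec(node[[2]])))
    kids <- lapply(node[-1], rec)
    stats::setNames(list(kids), op)
  }
  rec(shape)
}

count_leaves <- function(shape) {
  if (identical(shape, "leaf")) return(1L)
  if (shape[[1]] == "not") return(count_leaves(shape[[2]]))
  sum(vapply(shape[-1], count_leaves, 0L))
}

facts_for_leaves <- function(leaf_values) {
  fs <- lapply(seq_along(leaf_values), function(i) {
    v <- leaf_values[i]
    # leaf predicate is "fact >= 1": TRUE -> 1, FALSE -> 0, UNKNOWN -> NA
    list(value = if (is.na(v)) NA else if (v) 1 else 0, provenance = "recorded")
  })
  names(fs) <- paste0("cumulative_dose(f", seq_along(leaf_values), ")")
  structure(fs, class = "survplan_facts")
}

# write a small rule base YAML from endpoint specs (for loader error tests)
write_mini_rulebase <- function(endpoints, path = tempfile(fileext = ".yaml")) {
  yaml::write_yaml(list(version = "test", endpoints = endpoints), path)
  path
}

mini_endpoint <- function(id, n_conditions = 1, fact = "cumulative_dose(cisplatin)",
                          kind = "complementary_examination",
                          evidence = "moderate", patient_note = "note") {
  list(endpoint_id = id, label = id, kind = kind, patient_note = patient_note,
       conditions = lapply(seq_len(n_conditions), function(j)
         list(condition_id = paste0(id, "_c", j),
              predicate = list(fact = fact, op = ">=", value = j),
              frequency = list(interval = "P1Y", anchor = "end_of_treatment"),
              evidence_level = evidence, bibliography = list("ref"))))
}

# preset with modified fields, revalidated through cohort_preset()
modified_preset <- function(...) {
  p <- yaml::read_yaml(system.file("extdata", "presets", "table1.yaml",
                                   package = "survplan"))
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(p, path)
  cohort_preset(path)
}
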