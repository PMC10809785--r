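#' Closed code lists: organs, anatomical fields, disease categories
#'
#' The organ and anatomical-field vocabularies are closed, versioned code
#' lists shipped as plain-text data files under `inst/extdata/`. Unknown
#' codes are rejected by the validators, never coerced.
#'
#' @name vocabularies
NULL

survplan_extdata <- function(file) {
  path <- system.file("extdata", file, package = "survplan")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' @describeIn vocabularies character vector of valid organ codes.
#' @export
organ_codes <- function() {
  organ_table()$code
}

organ_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- utils::read.csv(survplan_extdata("organs.csv"), stringsAsFactors = FALSE)
    cache
  }
})

#' Radiotherapy field-to-organ exposure map
#'
#' Maps each anatomical irradiation field to the set of organs potentially
#' exposed by it. Shipped as an editable CSV (`field,organ`); the special
#' organ `*` on the TBI row expands to every organ in the vocabulary.
#'
#' @param path CSV path; defaults to the packaged map.
#' @return named list: field code -> character vector of organ codes.
#' @export
load_exposure_map <- function(path = survplan_extdata("exposure_map.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("field", "organ") %in% names(df)))
  organs <- organ_codes()
  bad <- setdiff(unique(df$organ), c(organs, "*"))
  if (length(bad))
    stop("exposure map references unknown organ code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  map <- lapply(split(df$organ, df$field), function(o) {
    if ("*" %in% o) organs else unique(o)
  })
  map[order(names(map))]
}

#' @describeIn vocabularies the nine registered disease categories.
#' @export
disease_categories <- function() {
  c("leukemia", "cerebral_tumor", "lymphoma", "sarcoma", "kidney_tumor",
    "neuroblastoma", "rare_tumor", "extra_cerebral_germ_cell_tumor", "other")
}

carcinological_impacts <- function() {
  c("complete_resection", "microscopically_incomplete", "macroscopically_incomplete")
}

functional_impacts <- function() c("none", "partial_removal", "complete_removal")

followup_event_types <- function() {
  c("late_effect", "organ_loss", "chronic_pain", "chronic_fatigue",
    "aesthetic_sequela", "other")
}

supportive_care_codes <- function() {
  c("corticotherapy", "transfusion", "fertility_preservation", "other")
}

evidence_levels <- function() {
  c("high", "moderate", "low", "very_low", "expert_consensus")
}

yes_no_unknown <- function() c("yes", "no", "unknown")
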