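#' Departmental deprivation quintiles (EDI)
#'
#' The European Deprivation Index (EDI) gives each small geographic unit
#' (IRIS, ~2000 inhabitants) a deprivation score, higher meaning more
#' deprived. Scores are categorized into quintiles *within each
#' department*: quintile 1 the most affluent fifth, quintile 5 the most
#' deprived. The cut uses min-rank with a ceiling
#' (`quintile = ceiling(5 * rank / n)`), so tied scores share the lower
#' quintile — a deterministic tie rule.
#'
#' @param records data.frame with columns `unit_code`, `department_code`,
#'   `edi_score` (or a CSV path with that header).
#' @return named integer vector unit_code -> quintile (1..5); units with a
#'   missing score get `NA` ("unknown") and are listed in the
#'   `"missing_score"` attribute.
#' @examples
#' df <- data.frame(unit_code = paste0("u", 1:10), department_code = "D1",
#'                  edi_score = 1:10)
#' assign_quintiles(df)
#' @export
assign_quintiles <- function(records) {
  if (is.character(records)) records <- utils::read.csv(records, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_code", "department_code", "edi_score") %in% names(records)))
  if (anyDuplicated(records$unit_code))
    stop("duplicate unit_code entries: one score per unit", call. = FALSE)
  if (any(!nzchar(as.character(records$department_code))))
    stop("empty department_code", call. = FALSE)
  out <- stats::setNames(rep(NA_integer_, nrow(records)), records$unit_code)
  missing <- records$unit_code[is.na(records$edi_score)]
  ok <- records[!is.na(records$edi_score), , drop = FALSE]
  for (dep in unique(ok$department_code)) {
    sub <- ok[ok$department_code == dep, , drop = FALSE]
    r <- rank(sub$edi_score, ties.method = "min")
    out[sub$unit_code] <- as.integer(ceiling(5 * r / nrow(sub)))
  }
  structure(out, missing_score = missing)
}

#' Attach EDI quintiles to patient records
#'
#' Patients whose `residence_unit` appears in the quintile map get an
#' `edi_quintile`; the rest get `"unknown"`. Idempotent.
#'
#' @param patients list of validated `survplan_patient`s.
#' @param quintile_map result of [assign_quintiles()].
#' @export
attach_quintile <- function(patients, quintile_map) {
  lapply(patients, function(p) {
    p <- validate_patient(p)
    unit <- p$residence_unit
    q <- if (!is.null(unit) && unit %in% names(quintile_map) &&
             !is.na(quintile_map[[unit]])) quintile_map[[unit]] else "unknown"
    p$edi_quintile <- q
    p
  })
}
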