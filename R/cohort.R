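#' Expand an ICD-10-style 3-character code range
#'
#' `expand_code_range("O10", "O16")` gives `O10, O11, ..., O16`.
#'
#' @param from,to 3-character codes sharing a letter prefix.
#' @return character vector of inclusive 3-character prefixes.
#' @export
expand_code_range <- function(from, to) {
  stopifnot(nchar(from) == 3, nchar(to) == 3,
            substr(from, 1, 1) == substr(to, 1, 1))
  lo <- as.integer(substr(from, 2, 3)); hi <- as.integer(substr(to, 2, 3))
  stopifnot(!is.na(lo), !is.na(hi), lo <= hi)
  sprintf("%s%02d", substr(from, 1, 1), lo:hi)
}

#' Case/control code rule set
#'
#' Matching is prefix-based on the dotted code string: rule `"O24"` matches
#' sample codes `"O24"` and `"O24.0"` but not `"O2"`-anything else. Ranges
#' should be pre-expanded with [expand_code_range()].
#'
#' @param case_codes codes (or prefixes) that make a sample a case.
#' @param case_exclusions codes that veto case status.
#' @param control_required_codes at least one required for control status
#'   (live-birth / uncomplicated-pregnancy codes).
#' @param control_exclusions codes that veto control status.
#' @param strict_preeclampsia when `TRUE`, gestational hypertension without
#'   proteinuria (`O13`) no longer qualifies as a case code, focusing the case
#'   group on preeclampsia/eclampsia; samples whose only case code is O13 are
#'   then excluded (they still carry a control-exclusion code).
#' @return object of class `code_rules`.
#' @export
code_rules <- function(case_codes, case_exclusions = character(),
                       control_required_codes,
                       control_exclusions = character(),
                       strict_preeclampsia = FALSE) {
  stopifnot(length(case_codes) > 0, length(control_required_codes) > 0)
  clash <- intersect(case_codes, case_exclusions)
  if (length(clash))
    abort_ghd(paste0("codes in both case_codes and case_exclusions: ",
                     paste(clash, collapse = ", ")), "ghdpgs_rule_clash")
  structure(list(case_codes = as.character(case_codes),
                 case_exclusions = as.character(case_exclusions),
                 control_required_codes = as.character(control_required_codes),
                 control_exclusions = as.character(control_exclusions),
                 strict_preeclampsia = isTRUE(strict_preeclampsia)),
            class = "code_rules")
}

#' Default gestational-hypertension/preeclampsia rule set
#'
#' Cases: self-reported gestational hypertension/preeclampsia (pseudo-code
#' `SR1073`, from the self-report questionnaire field), gestational
#' hypertension without (`O13`) and with (`O14`) significant proteinuria, and
#' eclampsia (`O15`). Controls: women with a live-birth / uncomplicated
#' pregnancy code (the listed `Z3x` codes plus chapter-O pregnancy codes
#' outside the hypertensive block) and none of the hypertensive-disorder
#' (`O10`-`O16`) or diabetes-in-pregnancy (`O24.x`) codes. The reading of the
#' control-inclusion code list "O2-O9" as chapter-O pregnancy codes outside
#' O10-O16 is an interpretation, flagged here rather than asserted.
#'
#' @param strict_preeclampsia drop `O13` from the case codes (preeclampsia-
#'   focused analysis).
#' @param general_controls when `TRUE`, control exclusions are waived (a
#'   general-population control group of all women with live births).
#' @return a [code_rules()] object.
#' @export
default_ghd_rules <- function(strict_preeclampsia = FALSE,
                              general_controls = FALSE) {
  case_codes <- c("SR1073", "O13", "O14", "O15")
  if (strict_preeclampsia) case_codes <- setdiff(case_codes, "O13")
  control_req <- c(expand_code_range("O02", "O09"),
                   expand_code_range("O20", "O23"),
                   expand_code_range("O25", "O99"),
                   "Z34.8", "Z37.0", "Z37.2", "Z37.3", "Z37.5", "Z37.6",
                   "Z38.1", "Z38.3", "Z38.6", "Z39")
  # the O24 prefix covers gestational (O24.4) and pre-existing diabetes
  control_excl <- if (general_controls) character() else
    c(expand_code_range("O10", "O16"), "O24")
  code_rules(case_codes = case_codes,
             control_required_codes = control_req,
             control_exclusions = control_excl,
             strict_preeclampsia = strict_preeclampsia)
}

# TRUE where any of `codes` matches any rule prefix (exact or dotted-prefix)
matches_any <- function(codes, rules) {
  if (!length(codes) || !length(rules)) return(FALSE)
  any(vapply(codes, function(cd)
    any(cd == rules | startsWith(cd, paste0(rules, "."))), logical(1)))
}

#' Label a coded cohort as cases, controls, or excluded
#'
#' A sample is a case iff it carries a case code and no case-exclusion code;
#' otherwise it is a control iff it carries a control-required code and no
#' control-exclusion code; otherwise it is excluded. Under
#' `strict_preeclampsia` rules, `O13` is not a case code, so samples whose
#' only hypertensive code is O13 fall through to the exclusion arm.
#'
#' @param cohort a [ghd_cohort()] with `diagnosis_codes`.
#' @param rules a [code_rules()] object.
#' @return list with `cohort` (input plus a `label` column in
#'   case/control/excluded) and `counts` (named integer vector).
#' @export
assign_case_control <- function(cohort, rules) {
  stopifnot(inherits(cohort, "ghd_cohort"), inherits(rules, "code_rules"))
  if (nrow(cohort) == 0)
    abort_ghd("empty cohort", "ghdpgs_empty_cohort")
  codes <- cohort$diagnosis_codes
  if (any(vapply(codes, function(x) any(!nzchar(x)), logical(1))))
    abort_ghd("empty-string diagnosis code found", "ghdpgs_bad_code")
  is_case <- vapply(codes, function(cd)
    matches_any(cd, rules$case_codes) &&
      !matches_any(cd, rules$case_exclusions), logical(1))
  is_ctrl <- !is_case & vapply(codes, function(cd)
    matches_any(cd, rules$control_required_codes) &&
      !matches_any(cd, rules$control_exclusions), logical(1))
  label <- ifelse(is_case, "case", ifelse(is_ctrl, "control", "excluded"))
  cohort$label <- label
  counts <- c(cases = sum(is_case), controls = sum(is_ctrl),
              excluded = sum(label == "excluded"))
  list(cohort = cohort, counts = counts)
}

#' Drop samples with missing or low BMI
#'
#' Samples whose BMI is missing or below `min_bmi` are removed; sample order
#' is preserved. The default threshold 18.5 kg/m^2 (the lower edge of the
#' "low" BMI band) is retained inclusively: BMI exactly 18.5 stays.
#'
#' @param cohort a [ghd_cohort()].
#' @param min_bmi minimum BMI retained (> 0).
#' @return the filtered cohort.
#' @export
filter_bmi <- function(cohort, min_bmi = 18.5) {
  stopifnot(inherits(cohort, "ghd_cohort"), min_bmi > 0)
  keep <- !is.na(cohort$bmi) & cohort$bmi >= min_bmi
  out <- cohort[keep, , drop = FALSE]
  class(out) <- c("ghd_cohort", "data.frame")
  out
}

#' Read a code rule set from a JSON config
#'
#' The JSON object must have keys `case_codes`, `control_required_codes` and
#' may have `case_exclusions`, `control_exclusions`, `strict_preeclampsia`.
#'
#' @param path path to a JSON file.
#' @return a [code_rules()] object.
#' @export
read_code_rules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  code_rules(case_codes = x$case_codes,
             case_exclusions = x$case_exclusions %||% character(),
             control_required_codes = x$control_required_codes,
             control_exclusions = x$control_exclusions %||% character(),
             strict_preeclampsia = isTRUE(x$strict_preeclampsia))
}

#' Write a code rule set to JSON
#' @param rules a [code_rules()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_code_rules <- function(rules, path) {
  stopifnot(inherits(rules, "code_rules"))
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
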