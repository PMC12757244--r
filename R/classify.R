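#' Define an exposure of interest
#'
#' An exposure specification names the target drug, the drug role it must
#' carry, any co-reported drugs that must also appear in the case (in any
#' role), and optional regimen and demographic refinements used for
#' stratified analyses. Refinements narrow the exposed set; reports failing
#' a refinement on an observed field fall into the comparator, while reports
#' missing a field a refinement needs are "not classifiable" and excluded
#' from that analysis only.
#'
#' @param target_drug standardized drug name (case-insensitive).
#' @param required_role `"PS"` to require the target drug as primary suspect
#'   (the usual case definition), `"any"` to accept any role.
#' @param co_drugs character vector of standardized drug names that must be
#'   co-reported within the same case, in any role.
#' @param regimen optional regimen filter: `"q6m_60mg"`, `"q4w_120mg"` or
#'   `"other"`.
#' @param sex optional demographic filter, `"male"` or `"female"`.
#' @param age_min,age_max optional age band in years; `age_min` inclusive,
#'   `age_max` exclusive, so `age_min = 65` means age >= 65 and
#'   `age_max = 65` means age < 65.
#' @param label display label for result tables; defaults to a description
#'   assembled from the filters.
#' @return an object of class `exposure_spec`.
#' @export
exposure_spec <- function(target_drug, required_role = c("PS", "any"),
                          co_drugs = character(), regimen = NULL,
                          sex = NULL, age_min = NULL, age_max = NULL,
                          label = NULL) {
  required_role <- match.arg(required_role)
  stopifnot(is.character(target_drug), length(target_drug) == 1,
            nzchar(target_drug))
  if (!is.null(regimen)) {
    stopifnot(regimen %in% c("q6m_60mg", "q4w_120mg", "other"))
  }
  if (!is.null(sex)) stopifnot(sex %in% c("male", "female"))
  if (is.null(label)) {
    bits <- c(target_drug,
              if (length(co_drugs)) paste0("*", paste(co_drugs, collapse = "+")),
              regimen, sex,
              if (!is.null(age_min)) paste0("age>=", age_min),
              if (!is.null(age_max)) paste0("age<", age_max))
    label <- paste(bits, collapse = " ")
  }
  structure(
    list(target_drug = normalize_drug_name(target_drug),
         required_role = required_role,
         co_drugs = normalize_drug_name(co_drugs),
         regimen = regimen, sex = sex, age_min = age_min, age_max = age_max,
         label = label),
    class = "exposure_spec"
  )
}

#' @export
print.exposure_spec <- function(x, ...) {
  cat(sprintf("<exposure_spec> %s (role: %s)\n", x$label, x$required_role))
  invisible(x)
}

#' Define the target adverse event
#'
#' Events are matched on the preferred-term string, case-insensitively on
#' normalized whitespace; a numeric PT code is compared only when both the
#' label and the report event carry one.
#'
#' @param pt_name preferred-term string, e.g. `"Osteonecrosis of jaw"`.
#' @param pt_code optional numeric MedDRA PT code.
#' @return an object of class `event_label`.
#' @export
event_label <- function(pt_name, pt_code = NULL) {
  stopifnot(is.character(pt_name), length(pt_name) == 1, nzchar(trimws(pt_name)))
  structure(list(pt_name = pt_name, pt_code = pt_code), class = "event_label")
}

# Evaluate every exposure condition per report, without combining them:
# drug+role presence, co-drug presence, regimen pass/missing (referenced only
# for reports carrying the target drug with the required role), and
# demographic pass/missing (referenced for every report).
classify_parts <- function(reports, exposure) {
  demo <- reports$demo
  drugs <- reports$drugs
  n <- nrow(demo)
  ids <- demo$primary_id

  is_target <- drugs$name_std == exposure$target_drug
  role_ok <- if (exposure$required_role == "PS") drugs$role == "PS" else TRUE
  target_ids <- unique(drugs$primary_id[is_target & role_ok])
  has_target <- ids %in% target_ids

  co_ok <- rep(TRUE, n)
  for (cd in exposure$co_drugs) {
    co_ids <- unique(drugs$primary_id[drugs$name_std == cd])
    co_ok <- co_ok & (ids %in% co_ids)
  }

  reg_pass <- rep(TRUE, n)
  reg_missing <- rep(FALSE, n)
  if (!is.null(exposure$regimen)) {
    trows <- drugs[is_target & role_ok, , drop = FALSE]
    known <- tapply(!is.na(trows$regimen), trows$primary_id, any)
    matches <- tapply(!is.na(trows$regimen) & trows$regimen == exposure$regimen,
                      trows$primary_id, any)
    idx <- match(ids, as.integer(names(known)))
    known_v <- ifelse(is.na(idx), FALSE, as.logical(known)[idx])
    match_v <- ifelse(is.na(idx), FALSE, as.logical(matches)[idx])
    reg_missing <- has_target & !known_v
    reg_pass <- ifelse(has_target, known_v & match_v, TRUE)
  }

  demo_pass <- rep(TRUE, n)
  demo_missing <- rep(FALSE, n)
  if (!is.null(exposure$sex)) {
    demo_missing <- demo_missing | is.na(demo$sex)
    demo_pass <- demo_pass & !is.na(demo$sex) & demo$sex == exposure$sex
  }
  if (!is.null(exposure$age_min) || !is.null(exposure$age_max)) {
    demo_missing <- demo_missing | is.na(demo$age_years)
    if (!is.null(exposure$age_min)) {
      demo_pass <- demo_pass & !is.na(demo$age_years) &
        demo$age_years >= exposure$age_min
    }
    if (!is.null(exposure$age_max)) {
      demo_pass <- demo_pass & !is.na(demo$age_years) &
        demo$age_years < exposure$age_max
    }
  }

  list(ids = ids, has_target = has_target, co_ok = co_ok,
       reg_pass = reg_pass, reg_missing = reg_missing,
       demo_pass = demo_pass, demo_missing = demo_missing)
}

# Per-report logical: does any event row match the target label?
match_event <- function(reports, event) {
  ev <- reports$events
  by_name <- normalize_pt(ev$pt_name) == normalize_pt(event$pt_name)
  hit <- by_name
  if (!is.null(event$pt_code)) {
    has_code <- !is.na(ev$pt_code)
    hit <- ifelse(has_code, ev$pt_code == event$pt_code, by_name)
  }
  unique(ev$primary_id[hit])
}

#' Classify reports into the case/non-case 2x2 cells
#'
#' Implements the case/non-case design: a report is *exposed* when the target
#' drug appears with the required role, every required co-drug is co-reported,
#' and all regimen/demographic refinements pass; it is a *case* when any of
#' its events matches the target label. Reports missing a field that a
#' refinement references (e.g. unknown sex under a sex refinement, or an
#' unknown regimen for a target-drug report under a regimen refinement) are
#' labelled `not_classifiable` and are excluded from that analysis only.
#'
#' @param reports a deduplicated [faers_reports] object.
#' @param exposure an [exposure_spec].
#' @param event an [event_label].
#' @return tibble with `primary_id` and `class`, a factor over
#'   `exposed_case`, `exposed_noncase`, `unexposed_case`,
#'   `unexposed_noncase`, `not_classifiable`; the five classes partition the
#'   dataset.
#' @export
classify_reports <- function(reports, exposure, event) {
  p <- classify_parts(reports, exposure)
  not_classifiable <- p$demo_missing | p$reg_missing
  exposed <- p$has_target & p$co_ok & p$reg_pass & p$demo_pass &
    !not_classifiable
  is_case <- p$ids %in% match_event(reports, event)
  n <- length(p$ids)
  ids <- p$ids

  cls <- dplyr::case_when(
    not_classifiable ~ "not_classifiable",
    exposed & is_case ~ "exposed_case",
    exposed & !is_case ~ "exposed_noncase",
    !exposed & is_case ~ "unexposed_case",
    TRUE ~ "unexposed_noncase"
  )
  tibble::tibble(
    primary_id = ids,
    class = factor(cls, levels = c("exposed_case", "exposed_noncase",
                                   "unexposed_case", "unexposed_noncase",
                                   "not_classifiable"))
  )
}
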