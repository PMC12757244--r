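#' FAERS report container
#'
#' A `faers_reports` object holds one spontaneous-report dataset in the
#' relational shape FAERS itself uses: a demographics table with one row per
#' report version, plus child tables for drugs, adverse events, and outcomes
#' keyed on the report-version identifier `primary_id`. All analysis
#' functions in the package take and return this container.
#'
#' @param demo tibble with columns `primary_id`, `case_id`, `fda_dt` (Date),
#'   `event_dt` (Date), `age_years`, `sex` (`"male"`/`"female"`/`NA`),
#'   `reporter` (`"healthcare_professional"`/`"non_healthcare_professional"`/
#'   `NA`), `country`.
#' @param drugs tibble with columns `primary_id`, `drug_seq`, `name_raw`,
#'   `name_std`, `role` (one of `PS`, `SS`, `C`, `I`), `dose_text`,
#'   `regimen`, `therapy_start` (Date).
#' @param events tibble with columns `primary_id`, `pt_name`, `pt_code`.
#' @param outcomes tibble with columns `primary_id`, `outcome` (one of
#'   `death`, `hospitalized`, `life_threatening`, `disability`,
#'   `required_intervention`, `other`).
#' @param meta optional list of provenance counters (orphans dropped on read,
#'   malformed rows skipped, ...).
#' @return an object of class `faers_reports`.
#' @export
faers_reports <- function(demo, drugs, events,
                          outcomes = empty_outcomes(), meta = list()) {
  demo <- tibble::as_tibble(demo)
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  outcomes <- tibble::as_tibble(outcomes)

  if (anyDuplicated(demo$primary_id)) {
    stop("primary_id must be unique within a dataset", call. = FALSE)
  }
  bad_age <- !is.na(demo$age_years) & (demo$age_years < 0 | demo$age_years > 130)
  if (any(bad_age)) {
    stop("age_years out of [0, 130]; harmonize ages before construction",
         call. = FALSE)
  }
  ok_role <- drugs$role %in% c("PS", "SS", "C", "I")
  if (!all(ok_role)) {
    stop("drug role codes must be one of PS/SS/C/I", call. = FALSE)
  }

  structure(
    list(demo = demo, drugs = drugs, events = events, outcomes = outcomes,
         meta = meta),
    class = "faers_reports"
  )
}

empty_demo <- function() {
  tibble::tibble(
    primary_id = integer(), case_id = integer(),
    fda_dt = as.Date(character()), event_dt = as.Date(character()),
    age_years = double(), sex = character(), reporter = character(),
    country = character()
  )
}

empty_drugs <- function() {
  tibble::tibble(
    primary_id = integer(), drug_seq = integer(), name_raw = character(),
    name_std = character(), role = character(), dose_text = character(),
    regimen = character(), therapy_start = as.Date(character())
  )
}

empty_events <- function() {
  tibble::tibble(primary_id = integer(), pt_name = character(),
                 pt_code = integer())
}

empty_outcomes <- function() {
  tibble::tibble(primary_id = integer(), outcome = character())
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf(
    "<faers_reports> %d reports (%d cases), %d drug rows, %d event rows, %d outcome rows\n",
    nrow(x$demo), length(unique(x$demo$case_id)), nrow(x$drugs),
    nrow(x$events), nrow(x$outcomes)
  ))
  invisible(x)
}

#' @export
length.faers_reports <- function(x) nrow(x$demo)

# Restrict every table to the given report versions; used by deduplication
# and cohort subsetting.
filter_reports <- function(reports, keep_ids) {
  faers_reports(
    demo = dplyr::filter(reports$demo, .data$primary_id %in% keep_ids),
    drugs = dplyr::filter(reports$drugs, .data$primary_id %in% keep_ids),
    events = dplyr::filter(reports$events, .data$primary_id %in% keep_ids),
    outcomes = dplyr::filter(reports$outcomes, .data$primary_id %in% keep_ids),
    meta = reports$meta
  )
}

#' Remove duplicate report versions
#'
#' Spontaneous-report databases carry multiple versions of the same case
#' (follow-up reports). One version per case is retained: the report with the
#' most recent FDA receipt date (`FDA_DT`) for each case identifier
#' (`CASEID`), breaking receipt-date ties by the higher primary identifier
#' (`PRIMARYID`). Output is ordered by `case_id` so the result is
#' deterministic regardless of input order.
#'
#' @param reports a [faers_reports] object.
#' @return a [faers_reports] object with at most one row per `case_id`;
#'   the number of versions dropped is recorded in `meta$dedup_removed`.
#' @export
deduplicate <- function(reports) {
  demo <- reports$demo
  if (anyDuplicated(demo$primary_id)) {
    stop("duplicate primary_id: identifier contract violated", call. = FALSE)
  }
  keep <- demo |>
    dplyr::group_by(.data$case_id) |>
    dplyr::arrange(dplyr::desc(.data$fda_dt), dplyr::desc(.data$primary_id),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$case_id)

  out <- filter_reports(reports, keep$primary_id)
  out$demo <- dplyr::arrange(out$demo, .data$case_id)
  out$meta$dedup_removed <- nrow(demo) - nrow(keep)
  out
}
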