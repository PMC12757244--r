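AGE_BANDS <- list(`0-17` = c(0, 18), `18-44` = c(18, 45),
                  `45-64` = c(45, 65), `>=65` = c(65, Inf))

# One outcome per report for descriptive tables, by severity priority, so
# percentages within the availability denominator sum to 100.
worst_outcome <- function(outcomes) {
  if (nrow(outcomes) == 0) return(outcomes)
  outcomes |>
    dplyr::mutate(rank = match(.data$outcome, OUTCOME_LEVELS)) |>
    dplyr::group_by(.data$primary_id) |>
    dplyr::summarise(outcome = OUTCOME_LEVELS[min(.data$rank)],
                     .groups = "drop")
}

#' Baseline characteristics of a cohort, split by case status
#'
#' Summarizes the cohort the way pharmacovigilance baseline tables do: for
#' each variable, a "data available" count and percentages computed within
#' that availability denominator, split into target-event cases and
#' non-cases. Covers reporter type, sex, age bands and median (IQR) age, the
#' top three reporting countries per group, and the outcome distribution
#' (one outcome per report, most severe first).
#'
#' @param reports a deduplicated [faers_reports] object.
#' @param cohort an [exposure_spec] (no demographic/regimen refinements).
#' @param event an [event_label].
#' @param top_countries number of countries to report per group.
#' @return tibble with columns `variable`, `level`, `n_case`, `pct_case`,
#'   `n_noncase`, `pct_noncase`. `data_available` rows carry the
#'   denominators; the `age_years` rows `median`/`q25`/`q75` carry values in
#'   the `n_*` columns.
#' @export
describe_cohort <- function(reports, cohort, event, top_countries = 3L) {
  cls <- classify_reports(reports, cohort, event)
  case_ids <- cls$primary_id[cls$class == "exposed_case"]
  noncase_ids <- cls$primary_id[cls$class == "exposed_noncase"]
  demo <- reports$demo
  d_case <- demo[demo$primary_id %in% case_ids, , drop = FALSE]
  d_non <- demo[demo$primary_id %in% noncase_ids, , drop = FALSE]

  lvl_row <- function(variable, level, nc, pc, nn, pn) {
    tibble::tibble(variable = variable, level = level, n_case = nc,
                   pct_case = pc, n_noncase = nn, pct_noncase = pn)
  }

  cat_block <- function(variable, values_case, values_non, levels) {
    avail_c <- sum(!is.na(values_case))
    avail_n <- sum(!is.na(values_non))
    rows <- list(lvl_row(variable, "data_available", avail_c, NA_real_,
                         avail_n, NA_real_))
    for (lv in levels) {
      nc <- sum(!is.na(values_case) & values_case == lv)
      nn <- sum(!is.na(values_non) & values_non == lv)
      rows <- c(rows, list(lvl_row(
        variable, lv, nc, share_pct(nc, avail_c), nn, share_pct(nn, avail_n)
      )))
    }
    dplyr::bind_rows(rows)
  }

  band_of <- function(age) {
    out <- rep(NA_character_, length(age))
    for (nm in names(AGE_BANDS)) {
      b <- AGE_BANDS[[nm]]
      out[!is.na(age) & age >= b[1] & age < b[2]] <- nm
    }
    out
  }

  occ <- cat_block("reporter", d_case$reporter, d_non$reporter,
                   c("healthcare_professional", "non_healthcare_professional"))
  sex <- cat_block("sex", d_case$sex, d_non$sex, c("male", "female"))
  age <- cat_block("age_band", band_of(d_case$age_years),
                   band_of(d_non$age_years), names(AGE_BANDS))
  qs <- function(x) {
    if (sum(!is.na(x)) == 0) return(c(NA_real_, NA_real_, NA_real_))
    quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  }
  qc <- qs(d_case$age_years); qn <- qs(d_non$age_years)
  age_sum <- dplyr::bind_rows(
    lvl_row("age_years", "median", qc[1], NA, qn[1], NA),
    lvl_row("age_years", "q25", qc[2], NA, qn[2], NA),
    lvl_row("age_years", "q75", qc[3], NA, qn[3], NA)
  )

  top_of <- function(x) {
    tab <- sort(table(x[!is.na(x)]), decreasing = TRUE)
    names(utils::head(tab, top_countries))
  }
  ctry_levels <- unique(c(top_of(d_case$country), top_of(d_non$country)))
  ctry <- cat_block("country", d_case$country, d_non$country, ctry_levels)

  wo <- worst_outcome(reports$outcomes)
  oc_case <- wo$outcome[match(d_case$primary_id, wo$primary_id)]
  oc_non <- wo$outcome[match(d_non$primary_id, wo$primary_id)]
  outc <- cat_block("outcome", oc_case, oc_non, OUTCOME_LEVELS)

  dplyr::bind_rows(
    lvl_row("cohort", "n", length(case_ids), NA, length(noncase_ids), NA),
    occ, sex, age, age_sum, ctry, outc
  )
}
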