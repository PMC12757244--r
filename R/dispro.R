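#' Construct a 2x2 disproportionality table
#'
#' The four counts of the case/non-case design: `a` target-drug reports with
#' the target event, `b` other-drug reports with the target event, `c`
#' target-drug reports with other events, `d` other-drug reports with other
#' events.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param n_not_classifiable reports excluded because a refinement referenced
#'   a missing field.
#' @param label display label.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, n_not_classifiable = 0L,
                              label = NULL) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
         d = as.integer(d),
         n_not_classifiable = as.integer(n_not_classifiable), label = label),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table>%s a=%d b=%d c=%d d=%d (not classifiable: %d)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$a, x$b, x$c, x$d, x$n_not_classifiable))
  invisible(x)
}

#' Tally the 2x2 table for an exposure and event
#'
#' Classifies every deduplicated report with [classify_reports] and counts
#' the four cells; classifiable reports are conserved
#' (`a + b + c + d + not classifiable = dataset size`). The comparator is
#' always all other reports in the cleaned dataset, never a restricted drug
#' class.
#'
#' @param reports a deduplicated [faers_reports] object.
#' @param exposure an [exposure_spec].
#' @param event an [event_label].
#' @return a [contingency_table].
#' @export
contingency <- function(reports, exposure, event) {
  cls <- classify_reports(reports, exposure, event)$class
  tab <- table(cls)
  contingency_table(
    a = tab[["exposed_case"]], b = tab[["unexposed_case"]],
    c = tab[["exposed_noncase"]], d = tab[["unexposed_noncase"]],
    n_not_classifiable = tab[["not_classifiable"]],
    label = exposure$label
  )
}

#' Reporting odds ratio with log-Wald confidence interval
#'
#' The ROR is the ratio of the odds of the target event among target-drug
#' reports to the same odds among all other reports,
#' \deqn{ROR = (a/c) / (b/d),}
#' with the 95% confidence interval
#' \deqn{\exp\{\ln ROR \pm z \sqrt{1/a + 1/b + 1/c + 1/d}\}.}
#' A safety signal is flagged when the lower CI bound exceeds 1 and there are
#' at least three exposed cases. Tables with any empty cell yield an explicit
#' undefined result (no continuity correction is applied): the estimate and
#' CI are `NA`, the table is carried along, and `is_signal` is `FALSE`.
#'
#' @param table a [contingency_table].
#' @param z normal critical value, default `1.96` for a 95% interval.
#' @param min_cases minimum exposed-case count in the signal rule, default 3.
#' @return an object of class `ror_result` with fields `ror`, `ci_low`,
#'   `ci_high`, `n_cases`, `is_signal`, `undefined`, `table`, `label`.
#' @export
ror <- function(table, z = 1.96, min_cases = 3L) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (min(a, b, c, d) == 0L) {
    res <- list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_cases = a, is_signal = FALSE, undefined = TRUE,
                table = table, label = table$label, z = z)
    return(structure(res, class = "ror_result"))
  }
  est <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(est) + c(-1, 1) * z * se)
  structure(
    list(ror = est, ci_low = ci[1], ci_high = ci[2], n_cases = a,
         is_signal = ci[1] > 1 && a >= min_cases, undefined = FALSE,
         table = table, label = table$label, z = z),
    class = "ror_result"
  )
}

#' @export
print.ror_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<ror_result>%s undefined (empty cell; a=%d b=%d c=%d d=%d)\n",
                if (is.null(x$label)) "" else paste0(" ", x$label),
                x$table$a, x$table$b, x$table$c, x$table$d))
  } else {
    cat(sprintf("<ror_result>%s ROR %.2f (95%% CI %.2f-%.2f), n=%d cases%s\n",
                if (is.null(x$label)) "" else paste0(" ", x$label),
                x$ror, x$ci_low, x$ci_high, x$n_cases,
                if (x$is_signal) " [signal]" else ""))
  }
  invisible(x)
}

ror_result_row <- function(x) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    n_cases = x$n_cases, ror = x$ror, ci_low = x$ci_low, ci_high = x$ci_high,
    is_signal = x$is_signal, undefined = x$undefined,
    n_not_classifiable = x$table$n_not_classifiable
  )
}

#' Refine an exposure definition for a stratified analysis
#'
#' Returns a copy of `base` with additional regimen, demographic or co-drug
#' restrictions, for use as one stratum in [stratified_rors].
#'
#' @param base an [exposure_spec].
#' @param co_drugs additional required co-drugs (appended).
#' @inheritParams exposure_spec
#' @return an [exposure_spec].
#' @export
refine_exposure <- function(base, co_drugs = character(), regimen = NULL,
                            sex = NULL, age_min = NULL, age_max = NULL,
                            label = NULL) {
  stopifnot(inherits(base, "exposure_spec"))
  exposure_spec(
    target_drug = base$target_drug, required_role = base$required_role,
    co_drugs = c(base$co_drugs, co_drugs),
    regimen = regimen %||% base$regimen, sex = sex %||% base$sex,
    age_min = age_min %||% base$age_min, age_max = age_max %||% base$age_max,
    label = label
  )
}

#' 2x2 table for one stratum of a stratified analysis
#'
#' Stratified disproportionality keeps the comparator "all other drugs":
#' the exposed cell holds reports matching the refined exposure, while the
#' comparator holds reports *without* the target drug (at the required
#' role). Target-drug reports that fail a drug-side refinement (other
#' regimen, missing co-drug) belong to a different stratum and are excluded
#' from this one — they are neither exposed nor "another drug".
#' Demographic refinements describe the patient, not the drug, so they
#' restrict both sides of the table; reports missing a referenced field are
#' excluded from the stratum only. Cell totals plus exclusions always sum
#' to the dataset size.
#'
#' @param reports a deduplicated [faers_reports] object.
#' @param base_exposure the unrefined [exposure_spec] defining the target
#'   drug and role.
#' @param stratum an [exposure_spec] refining `base_exposure` (see
#'   [refine_exposure]).
#' @param event an [event_label].
#' @return a [contingency_table]; `n_not_classifiable` counts all reports
#'   excluded from the stratum.
#' @export
stratum_contingency <- function(reports, base_exposure, stratum, event) {
  ps <- classify_parts(reports, stratum)
  pb <- classify_parts(reports, base_exposure)
  exposed <- ps$has_target & ps$co_ok & ps$reg_pass & ps$demo_pass &
    !(ps$reg_missing | ps$demo_missing)
  comparator <- !pb$has_target & ps$demo_pass & !ps$demo_missing
  is_case <- ps$ids %in% match_event(reports, event)
  n <- length(ps$ids)
  contingency_table(
    a = sum(exposed & is_case), b = sum(comparator & is_case),
    c = sum(exposed & !is_case), d = sum(comparator & !is_case),
    n_not_classifiable = n - sum(exposed) - sum(comparator),
    label = stratum$label
  )
}

#' Stratified reporting odds ratios
#'
#' Computes one ROR per stratum via [stratum_contingency]: each stratum's
#' exposed cell is the refined exposure, and each is compared against the
#' full "all other drugs" comparator (demographically restricted where the
#' stratum is demographic). Reports missing the field a stratum's refinement
#' references are excluded from that stratum only; strata with an empty cell
#' yield undefined rows, never an error.
#'
#' @param reports a deduplicated [faers_reports] object.
#' @param base_exposure the base [exposure_spec] (e.g. the target drug as
#'   primary suspect).
#' @param event an [event_label].
#' @param strata named list of [exposure_spec] refinements of
#'   `base_exposure`, e.g. from [refine_exposure]. The base exposure itself
#'   is reported first under its own label.
#' @param z normal critical value for the CIs.
#' @return tibble with one row per stratum: cells, ROR, CI, signal flag,
#'   undefined flag, and the not-classifiable count.
#' @export
stratified_rors <- function(reports, base_exposure, event, strata = list(),
                            z = 1.96) {
  specs <- c(list(base_exposure), unname(strata))
  rows <- lapply(specs, function(sp) {
    ror_result_row(ror(stratum_contingency(reports, base_exposure, sp, event),
                       z = z))
  })
  dplyr::bind_rows(rows)
}

#' Write ROR results as delimited and forest-plot-ready files
#'
#' @param ror_table tibble from [stratified_rors].
#' @param path output file for the full table (tab-separated).
#' @param forest_path optional output for a minimal forest-plot file with
#'   columns `label`, `estimate`, `ci_low`, `ci_high`.
#' @return invisibly, `path`.
#' @export
export_ror_table <- function(ror_table, path, forest_path = NULL) {
  readr::write_tsv(ror_table, path)
  if (!is.null(forest_path)) {
    readr::write_tsv(
      dplyr::select(ror_table, "label", estimate = "ror", "ci_low", "ci_high"),
      forest_path
    )
  }
  invisible(path)
}
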