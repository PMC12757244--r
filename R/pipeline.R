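#' Configuration for a full pipeline run
#'
#' Exactly one input mode must be given: `synth` (a [synth_config] for a
#' simulated study) or `tables` (named paths to FAERS-style files, as in
#' [read_faers_tables]). Standard strata for the disproportionality and
#' time-to-onset stages (sex, age band, regimen, one per co-drug) are
#' derived from the target drug and the co-drug list.
#'
#' @param target_drug standardized target drug name.
#' @param event_pt target event preferred term.
#' @param synth optional [synth_config].
#' @param tables optional named list of table paths.
#' @param synonym_map optional path to a synonym map file.
#' @param co_drugs standardized co-drug names used for stratification and as
#'   regression covariates.
#' @param screen_alpha univariate screening threshold.
#' @param force_include variables force-included in the multivariate model.
#' @param age_cut age threshold for the age indicator and strata.
#' @param seed seed for any run-level randomness (echoed in the manifest; in
#'   synthetic mode the generator's own seed governs the data).
#' @param out_dir output directory for the result bundle.
#' @return an object of class `run_config`.
#' @export
run_config <- function(target_drug, event_pt, synth = NULL, tables = NULL,
                       synonym_map = NULL, co_drugs = character(),
                       screen_alpha = 0.20, force_include = c("age_ge_65"),
                       age_cut = 65, seed = 1L, out_dir = "faersignal-out") {
  if (is.null(synth) == is.null(tables)) {
    stop("exactly one input mode: supply `synth` or `tables`", call. = FALSE)
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  structure(
    list(target_drug = normalize_drug_name(target_drug), event_pt = event_pt,
         synth = synth, tables = tables, synonym_map = synonym_map,
         co_drugs = normalize_drug_name(co_drugs),
         screen_alpha = screen_alpha, force_include = force_include,
         age_cut = age_cut, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

# Drug names in the config must be resolvable before any computation runs.
validate_run_config <- function(config) {
  if (!is.null(config$synth)) {
    known <- c(config$synth$target_drug, names(config$synth$co_drug_prev),
               normalize_drug_name(BG_DRUG_POOL))
    unknown <- setdiff(c(config$target_drug, config$co_drugs),
                       normalize_drug_name(known))
    if (length(unknown)) {
      stop("config references drug names unknown to the generator: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  } else if (!is.null(config$synonym_map)) {
    map <- read_synonym_map(config$synonym_map)
    known <- normalize_drug_name(unname(map))
    unknown <- setdiff(config$co_drugs, c(known, config$target_drug))
    if (length(unknown)) {
      stop("config references drug names absent from the synonym map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

standard_strata <- function(base, co_drugs, age_cut) {
  strata <- list(
    male = refine_exposure(base, sex = "male", label = "sex: male"),
    female = refine_exposure(base, sex = "female", label = "sex: female"),
    age_lt = refine_exposure(base, age_max = age_cut,
                             label = sprintf("age < %d", age_cut)),
    age_ge = refine_exposure(base, age_min = age_cut,
                             label = sprintf("age >= %d", age_cut)),
    dose_60 = refine_exposure(base, regimen = "q6m_60mg",
                              label = "60 mg Q6M"),
    dose_120 = refine_exposure(base, regimen = "q4w_120mg",
                               label = "120 mg Q4W")
  )
  for (cd in co_drugs) {
    strata[[paste0("co_", gsub("\\s+", "_", cd))]] <-
      refine_exposure(base, co_drugs = cd, label = paste0("+", cd))
  }
  strata
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes load -> deduplicate -> describe -> disproportionality ->
#' regression -> time-to-onset and writes every output table plus a
#' machine-readable JSON manifest (config echo, seed, stage counts, md5
#' checksums of outputs). The run is deterministic for fixed inputs and
#' seeds: two runs of the same config produce byte-identical manifests. On
#' any stage failure, partial outputs are removed and the error is re-raised
#' with a stage label.
#'
#' @param config a [run_config].
#' @return invisibly, a list with the in-memory results (`reports`,
#'   `describe`, `ror_table`, `regression`, `tto`, `manifest`) and the
#'   bundle directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    loaded <- stage("load", {
      if (!is.null(config$synth)) {
        synth_generate(config$synth)$reports
      } else {
        map <- if (!is.null(config$synonym_map)) {
          read_synonym_map(config$synonym_map)
        }
        read_faers_tables(config$tables, synonym_map = map)
      }
    })
    n_raw <- nrow(loaded$demo)
    reports <- stage("deduplicate", deduplicate(loaded))

    base <- exposure_spec(config$target_drug, required_role = "PS",
                          label = config$target_drug)
    event <- event_label(config$event_pt)
    strata <- standard_strata(base, config$co_drugs, config$age_cut)

    describe_tbl <- stage("describe", describe_cohort(reports, base, event))
    f_desc <- file.path(out_dir, "describe.tsv")
    readr::write_tsv(describe_tbl, f_desc)
    written <- c(written, f_desc)

    ror_tbl <- stage("dispro",
                     stratified_rors(reports, base, event, strata))
    f_ror <- file.path(out_dir, "ror.tsv")
    f_forest <- file.path(out_dir, "forest.tsv")
    export_ror_table(ror_tbl, f_ror, forest_path = f_forest)
    written <- c(written, f_ror, f_forest)

    regression <- stage("regression", {
      bf <- build_frame(reports, base, event, co_drugs = config$co_drugs,
                        age_cut = config$age_cut)
      screen <- univariate_screen(bf$frame,
                                  alpha_screen = config$screen_alpha,
                                  force_include = config$force_include)
      included <- screen$variable[screen$screen_included]
      fit <- if (length(included)) multivariate_fit(bf$frame, included)
      list(frame_meta = bf$exclusions, screen = screen, fit = fit,
           table = logistic_table(screen, fit))
    })
    f_reg <- file.path(out_dir, "regression.tsv")
    readr::write_tsv(regression$table, f_reg)
    written <- c(written, f_reg)

    tto_tbl <- stage("tto", tto_table(reports, base, event, strata))
    f_tto <- file.path(out_dir, "tto.tsv")
    readr::write_tsv(tto_tbl, f_tto)
    written <- c(written, f_tto)

    manifest <- stage("manifest", {
      files <- basename(written)
      md5 <- unname(tools::md5sum(written))
      list(
        package = "faersignal",
        config = list(
          target_drug = config$target_drug, event_pt = config$event_pt,
          mode = if (is.null(config$synth)) "tables" else "synth",
          co_drugs = config$co_drugs, screen_alpha = config$screen_alpha,
          force_include = config$force_include, age_cut = config$age_cut,
          seed = config$seed,
          synth_seed = if (!is.null(config$synth)) config$synth$seed,
          n_reports = if (!is.null(config$synth)) config$synth$n_reports
        ),
        counts = list(
          reports_raw = n_raw,
          dedup_removed = reports$meta$dedup_removed,
          reports_deduplicated = nrow(reports$demo),
          regression_cohort = unname(regression$frame_meta[["cohort"]]),
          regression_used = unname(regression$frame_meta[["used"]]),
          tto_usable = tto_tbl$n[1]
        ),
        outputs = stats::setNames(as.list(md5), files)
      )
    })
    f_manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, f_manifest)

    invisible(list(reports = reports, describe = describe_tbl,
                   ror_table = ror_tbl, regression = regression,
                   tto = tto_tbl, manifest = manifest, out_dir = out_dir,
                   files = written))
  }, error = on_fail)
}
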