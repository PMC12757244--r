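# Fixed vocabularies for the simulator: neutral background drugs and
# background adverse-event preferred terms. Chosen arbitrarily; analyses
# treat them as opaque labels.
BG_DRUG_POOL <- sprintf("backgrounddrug%02d", 1:20)
BG_PT_POOL <- c("Nausea", "Headache", "Dizziness", "Fatigue", "Arthralgia",
                "Pyrexia", "Rash", "Dyspnoea", "Diarrhoea", "Vomiting")
OUTCOME_LEVELS <- c("death", "hospitalized", "life_threatening", "disability",
                    "required_intervention", "other")

run_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic report generator
#'
#' Defines a FAERS-like study with known ground truth. The defaults emulate a
#' desk-scale denosumab/osteonecrosis-of-the-jaw study: a mostly female,
#' elderly reporting population; a rare target event in the background; a
#' strong planted drug-event association; regimen-dependent Weibull latencies
#' with scale/shape values matching published denosumab fits; heavy
#' structured missingness in age and dose; and injected duplicate report
#' versions for deduplication testing.
#'
#' The event indicator follows a logistic model on the log-odds scale:
#' `qlogis(background_event_rate) + log_or["exposure"]*exposed +
#' log_or["male"]*male + log_or["age_ge_65"]*(age >= 65) +
#' log_or["high_dose"]*high_dose + sum over co-drugs`. `high_dose` is defined
#' only for exposed reports (0 otherwise). With the other coefficients at
#' zero, `exp(log_or["exposure"])` is the planted reporting odds ratio;
#' under non-null covariates the marginal ROR differs slightly from it
#' (odds-ratio non-collapsibility), which [synth_generate] records.
#'
#' @param n_reports number of canonical (deduplicated) reports.
#' @param seed RNG seed; identical configs and seeds generate byte-identical
#'   table files.
#' @param target_drug standardized target drug name.
#' @param p_exposed marginal probability a report carries the target drug.
#' @param role_probs probabilities over FAERS roles `PS`/`SS`/`C`/`I` for the
#'   target drug entry.
#' @param background_event_rate target-event probability for a reference
#'   report (unexposed, female, age < 65, no co-drugs).
#' @param log_or named numeric vector of true log odds ratios:
#'   `exposure`, `male`, `age_ge_65`, `high_dose`, plus one entry per
#'   co-drug (named by drug).
#' @param co_drug_prev named numeric vector of marginal co-drug
#'   probabilities; names define the co-drug set.
#' @param p_male,age_mean,age_sd demographics; age is normal, truncated to
#'   \[1, 105\] years.
#' @param p_hcp probability the reporter is a healthcare professional.
#' @param country_probs named probability vector of reporting countries.
#' @param p_high_dose probability an exposed report is on the 120 mg Q4W
#'   regimen (otherwise 60 mg Q6M).
#' @param latency_params named list of `c(alpha, beta)` Weibull parameters
#'   (days, dimensionless) per regimen stratum (`q6m_60mg`, `q4w_120mg`,
#'   `other`); `other` is used when the regimen is not one of the two.
#' @param missing_rates named vector of masking probabilities for `age`,
#'   `sex`, `reporter`, `country`, `dose` (dose masking hides the regimen).
#' @param tto_missing fraction of exposed cases whose event date is masked,
#'   mirroring real databases where most onset dates are unusable.
#' @param duplicate_rate fraction of cases emitted as multiple report
#'   versions (the extra versions have an earlier or equal receipt date and
#'   a lower primary id than the canonical version).
#' @param calendar_window two Dates bounding therapy start dates; event
#'   dates are not clamped to the window, since clamping would bias the
#'   fitted Weibull shape.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(
    n_reports = 50000L,
    seed = 1L,
    target_drug = "denosumab",
    p_exposed = 0.15,
    role_probs = c(PS = 0.85, SS = 0.06, C = 0.07, I = 0.02),
    background_event_rate = 0.001,
    log_or = c(exposure = log(30), male = log(3), age_ge_65 = log(1.5),
               high_dose = log(7), `zoledronic acid` = log(10)),
    co_drug_prev = c(`zoledronic acid` = 0.04),
    p_male = 0.20, age_mean = 71, age_sd = 13,
    p_hcp = 0.75,
    country_probs = c(US = 0.55, JP = 0.12, DE = 0.08, CA = 0.07, FR = 0.05,
                      GB = 0.05, NL = 0.04, IT = 0.04),
    p_high_dose = 0.40,
    latency_params = list(
      q6m_60mg = c(alpha = 712.83, beta = 1.06),
      q4w_120mg = c(alpha = 576.47, beta = 1.33),
      other = c(alpha = 624.94, beta = 1.21)
    ),
    missing_rates = c(age = 0.40, sex = 0.12, reporter = 0.01,
                      country = 0.03, dose = 0.35),
    tto_missing = 1 - 1652 / 7689,
    duplicate_rate = 0.20,
    calendar_window = as.Date(c("2010-04-01", "2024-09-30"))) {

  probs <- c(p_exposed, background_event_rate, p_male, p_hcp, p_high_dose,
             missing_rates, tto_missing, duplicate_rate, co_drug_prev)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_reports < 1) stop("n_reports must be >= 1", call. = FALSE)
  for (lp in latency_params) {
    if (lp[["alpha"]] <= 0 || lp[["beta"]] <= 0) {
      stop("Weibull alpha and beta must be positive", call. = FALSE)
    }
  }
  needed <- c("exposure", "male", "age_ge_65", "high_dose", names(co_drug_prev))
  missing_lor <- setdiff(needed, names(log_or))
  if (length(missing_lor)) {
    stop("log_or lacks entries: ", paste(missing_lor, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(abs(sum(role_probs) - 1) < 1e-8, abs(sum(country_probs) - 1) < 1e-8)

  structure(
    list(n_reports = as.integer(n_reports), seed = as.integer(seed),
         target_drug = normalize_drug_name(target_drug),
         p_exposed = p_exposed, role_probs = role_probs,
         background_event_rate = background_event_rate, log_or = log_or,
         co_drug_prev = co_drug_prev, p_male = p_male, age_mean = age_mean,
         age_sd = age_sd, p_hcp = p_hcp, country_probs = country_probs,
         p_high_dose = p_high_dose, latency_params = latency_params,
         missing_rates = missing_rates, tto_missing = tto_missing,
         duplicate_rate = duplicate_rate, calendar_window = calendar_window),
    class = "synth_config"
  )
}

random_dates <- function(n, window) {
  span <- as.integer(window[2] - window[1])
  window[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic report set with recorded ground truth
#'
#' Draws demographics, exposure, co-drugs, and the event indicator from the
#' configured logistic model; draws case latencies from the regimen stratum's
#' Weibull and places therapy start dates inside the calendar window (event
#' dates are start + latency, unclamped); records all latent truth *before*
#' applying missingness masks; and finally injects duplicate report versions
#' whose receipt date/primary id are dominated by the canonical version, so
#' [deduplicate] must recover exactly the canonical set. Fully reproducible
#' for a fixed seed.
#'
#' @param config a [synth_config].
#' @return a list with elements `reports` (a [faers_reports] including
#'   duplicate versions) and `truth` (a `synth_truth` object: per-report
#'   latent assignments, canonical primary ids, planted parameter values).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  run_with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  n <- cfg$n_reports
  case_id <- seq_len(n)
  primary_id <- case_id * 10L + 9L

  age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 1), 105)
  male <- rbinom(n, 1, cfg$p_male)
  hcp <- rbinom(n, 1, cfg$p_hcp)
  country <- sample(names(cfg$country_probs), n, replace = TRUE,
                    prob = cfg$country_probs)
  exposed <- rbinom(n, 1, cfg$p_exposed)
  target_role <- sample(names(cfg$role_probs), n, replace = TRUE,
                        prob = cfg$role_probs)
  high_dose <- ifelse(exposed == 1, rbinom(n, 1, cfg$p_high_dose), 0L)
  regimen_true <- ifelse(exposed == 1,
                         ifelse(high_dose == 1, "q4w_120mg", "q6m_60mg"),
                         NA_character_)

  co_names <- names(cfg$co_drug_prev)
  co_mat <- vapply(co_names, function(cd) rbinom(n, 1, cfg$co_drug_prev[[cd]]),
                   integer(n))
  if (length(co_names) == 0) co_mat <- matrix(0L, n, 0)
  if (is.null(dim(co_mat))) co_mat <- matrix(co_mat, nrow = n)

  eta <- qlogis(cfg$background_event_rate) +
    cfg$log_or[["exposure"]] * exposed +
    cfg$log_or[["male"]] * male +
    cfg$log_or[["age_ge_65"]] * (age >= 65) +
    cfg$log_or[["high_dose"]] * high_dose
  for (j in seq_along(co_names)) {
    eta <- eta + cfg$log_or[[co_names[j]]] * co_mat[, j]
  }
  event <- rbinom(n, 1, plogis(eta))

  therapy_start <- random_dates(n, cfg$calendar_window)
  stratum <- ifelse(is.na(regimen_true), "other", regimen_true)
  latency <- rep(NA_integer_, n)
  gen_lat <- exposed == 1 & event == 1
  for (s in unique(stratum[gen_lat])) {
    pick <- gen_lat & stratum == s
    lp <- cfg$latency_params[[s]] %||% cfg$latency_params[["other"]]
    latency[pick] <- pmax(1L, as.integer(round(
      rweibull(sum(pick), shape = lp[["beta"]], scale = lp[["alpha"]])
    )))
  }
  event_dt <- as.Date(ifelse(is.na(latency), NA,
                             therapy_start + latency), origin = "1970-01-01")
  fda_dt <- random_dates(n, cfg$calendar_window)

  # masks, applied after truth is recorded below
  mask <- function(rate) rbinom(n, 1, rate) == 1
  m_age <- mask(cfg$missing_rates[["age"]])
  m_sex <- mask(cfg$missing_rates[["sex"]])
  m_rep <- mask(cfg$missing_rates[["reporter"]])
  m_cty <- mask(cfg$missing_rates[["country"]])
  m_dose <- mask(cfg$missing_rates[["dose"]])
  m_tto <- gen_lat & mask(cfg$tto_missing)

  truth <- tibble::tibble(
    case_id = case_id, primary_id = primary_id,
    exposed = exposed,
    target_role = ifelse(exposed == 1, target_role, NA_character_),
    male = male, age_years = age,
    age_ge_65 = as.integer(age >= 65), high_dose = as.integer(high_dose),
    regimen = regimen_true, event = event, latency_days = latency,
    therapy_start = therapy_start, event_dt = event_dt,
    masked_age = m_age, masked_sex = m_sex, masked_reporter = m_rep,
    masked_country = m_cty, masked_dose = m_dose, masked_tto = m_tto
  )
  for (j in seq_along(co_names)) {
    truth[[paste0("co_", gsub("\\s+", "_", co_names[j]))]] <- co_mat[, j]
  }

  demo <- tibble::tibble(
    primary_id = primary_id, case_id = case_id, fda_dt = fda_dt,
    event_dt = as.Date(ifelse(m_tto, NA, event_dt), origin = "1970-01-01"),
    age_years = ifelse(m_age, NA_real_, round(age, 1)),
    sex = ifelse(m_sex, NA_character_, ifelse(male == 1, "male", "female")),
    reporter = ifelse(m_rep, NA_character_,
                      ifelse(hcp == 1, "healthcare_professional",
                             "non_healthcare_professional")),
    country = ifelse(m_cty, NA_character_, country)
  )

  # drug rows: target entry for exposed reports; a PS background drug when
  # the target is absent or not itself PS; co-drug entries in role SS/C
  tgt_display <- toupper(cfg$target_drug)
  dose_text_true <- ifelse(high_dose == 1, "120 MG", "60 MG")
  idx_t <- which(exposed == 1)
  drug_target <- tibble::tibble(
    primary_id = primary_id[idx_t],
    name_raw = tgt_display,
    role = target_role[idx_t],
    dose_text = ifelse(m_dose[idx_t], NA_character_, dose_text_true[idx_t]),
    therapy_start = therapy_start[idx_t]
  )
  need_bg <- which(exposed == 0 | target_role != "PS")
  drug_bg <- tibble::tibble(
    primary_id = primary_id[need_bg],
    name_raw = sample(BG_DRUG_POOL, length(need_bg), replace = TRUE),
    role = "PS",
    dose_text = NA_character_,
    therapy_start = as.Date(ifelse(rbinom(length(need_bg), 1, 0.3) == 1,
                                   random_dates(length(need_bg),
                                                cfg$calendar_window), NA),
                            origin = "1970-01-01")
  )
  drug_co <- dplyr::bind_rows(lapply(seq_along(co_names), function(j) {
    idx <- which(co_mat[, j] == 1)
    tibble::tibble(
      primary_id = primary_id[idx],
      name_raw = toupper(co_names[j]),
      role = sample(c("SS", "C"), length(idx), replace = TRUE),
      dose_text = NA_character_,
      therapy_start = as.Date(ifelse(rbinom(length(idx), 1, 0.5) == 1,
                                     random_dates(length(idx),
                                                  cfg$calendar_window), NA),
                              origin = "1970-01-01")
    )
  }))
  drugs <- dplyr::bind_rows(drug_target, drug_bg, drug_co)
  ordd <- order(drugs$primary_id)
  drugs <- drugs[ordd, ]
  drugs$drug_seq <- sequence(rle(drugs$primary_id)$lengths)
  drugs$name_std <- normalize_drug_name(drugs$name_raw)
  drugs$regimen <- parse_regimen(drugs$dose_text)
  drugs <- drugs[, c("primary_id", "drug_seq", "name_raw", "name_std",
                     "role", "dose_text", "regimen", "therapy_start")]

  ev_bg <- tibble::tibble(
    primary_id = primary_id,
    pt_name = sample(BG_PT_POOL, n, replace = TRUE),
    pt_code = NA_integer_
  )
  ev_case <- tibble::tibble(
    primary_id = primary_id[event == 1],
    pt_name = "Osteonecrosis of jaw",
    pt_code = NA_integer_
  )
  events <- dplyr::arrange(dplyr::bind_rows(ev_case, ev_bg),
                           .data$primary_id)

  has_outc <- rbinom(n, 1, 0.6) == 1
  outcomes <- tibble::tibble(
    primary_id = primary_id[has_outc],
    outcome = sample(OUTCOME_LEVELS, sum(has_outc), replace = TRUE,
                     prob = c(0.10, 0.25, 0.02, 0.05, 0.01, 0.57))
  )

  # duplicate injection: earlier/equal receipt date, always lower primary id,
  # only mutable fields perturbed (reporter), drugs/events untouched
  n_dup <- as.integer(floor(cfg$duplicate_rate * n))
  if (n_dup > 0) {
    dup_case <- sort(sample.int(n, n_dup))
    dup_pid <- case_id[dup_case] * 10L + sample(0:8, n_dup, replace = TRUE)
    same_dt <- rbinom(n_dup, 1, 0.3) == 1
    dup_fda <- as.Date(ifelse(same_dt, fda_dt[dup_case],
                              fda_dt[dup_case] - sample(1:300, n_dup,
                                                        replace = TRUE)),
                       origin = "1970-01-01")
    flip_rep <- rbinom(n_dup, 1, 0.4) == 1
    dup_demo <- demo[dup_case, ]
    dup_demo$primary_id <- dup_pid
    dup_demo$fda_dt <- dup_fda
    dup_demo$reporter <- ifelse(
      flip_rep & !is.na(dup_demo$reporter),
      ifelse(dup_demo$reporter == "healthcare_professional",
             "non_healthcare_professional", "healthcare_professional"),
      dup_demo$reporter)
    remap <- function(tab) {
      idx <- match(tab$primary_id, primary_id[dup_case])
      extra <- tab[!is.na(idx), , drop = FALSE]
      extra$primary_id <- dup_pid[idx[!is.na(idx)]]
      extra
    }
    demo <- dplyr::bind_rows(demo, dup_demo)
    drugs <- dplyr::bind_rows(drugs, remap(drugs))
    events <- dplyr::bind_rows(events, remap(events))
    outcomes <- dplyr::bind_rows(outcomes, remap(outcomes))
  }

  ord <- order(demo$primary_id)
  demo <- demo[ord, ]
  drugs <- dplyr::arrange(drugs, .data$primary_id, .data$drug_seq)
  events <- dplyr::arrange(events, .data$primary_id, .data$pt_name)
  outcomes <- dplyr::arrange(outcomes, .data$primary_id, .data$outcome)

  true_medians <- lapply(cfg$latency_params, function(lp) {
    unname(lp[["alpha"]] * log(2)^(1 / lp[["beta"]]))
  })

  truth_obj <- structure(
    list(
      truth = truth,
      canonical_primary_ids = primary_id,
      true_ror = exp(cfg$log_or[["exposure"]]),
      true_or = exp(cfg$log_or[setdiff(names(cfg$log_or), "exposure")]),
      latency_params = cfg$latency_params,
      true_median_latency = true_medians,
      config = cfg
    ),
    class = "synth_truth"
  )

  list(
    reports = faers_reports(demo, drugs, events, outcomes,
                            meta = list(synthetic = TRUE, seed = cfg$seed)),
    truth = truth_obj
  )
}

#' Ground-truth 2x2 tallies for a synthetic dataset
#'
#' Counts the exposed/unexposed case/non-case cells directly from the
#' recorded latent assignments, before any missingness; the observed
#' [contingency] of the deduplicated dataset under an unrefined exposure must
#' match these exactly.
#'
#' @param truth a `synth_truth` object from [synth_generate].
#' @param required_role `"PS"` to count exposure only when the target drug
#'   was generated as primary suspect (matching the usual case definition),
#'   `"any"` for any role.
#' @return a [contingency_table].
#' @export
truth_contingency <- function(truth, required_role = c("PS", "any")) {
  stopifnot(inherits(truth, "synth_truth"))
  required_role <- match.arg(required_role)
  tt <- truth$truth
  exp_cls <- tt$exposed == 1
  if (required_role == "PS") {
    exp_cls <- exp_cls & !is.na(tt$target_role) & tt$target_role == "PS"
  }
  contingency_table(
    a = sum(exp_cls & tt$event == 1),
    b = sum(!exp_cls & tt$event == 1),
    c = sum(exp_cls & tt$event == 0),
    d = sum(!exp_cls & tt$event == 0),
    label = "ground truth"
  )
}

#' Serialize / load a generator configuration
#'
#' The configuration is stored as a flat YAML mapping so that simulated
#' studies are reproducible from a text file.
#'
#' @param config a [synth_config].
#' @param path file location.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns a [synth_config].
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  x <- unclass(config)
  x$calendar_window <- format(x$calendar_window, "%Y-%m-%d")
  x$latency_params <- lapply(x$latency_params, as.list)
  x$role_probs <- as.list(x$role_probs)
  x$country_probs <- as.list(x$country_probs)
  x$log_or <- as.list(x$log_or)
  x$co_drug_prev <- as.list(x$co_drug_prev)
  x$missing_rates <- as.list(x$missing_rates)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  synth_config(
    n_reports = x$n_reports, seed = x$seed, target_drug = x$target_drug,
    p_exposed = x$p_exposed, role_probs = unlist(x$role_probs),
    background_event_rate = x$background_event_rate,
    log_or = unlist(x$log_or), co_drug_prev = unlist(x$co_drug_prev),
    p_male = x$p_male, age_mean = x$age_mean, age_sd = x$age_sd,
    p_hcp = x$p_hcp, country_probs = unlist(x$country_probs),
    p_high_dose = x$p_high_dose,
    latency_params = lapply(x$latency_params, unlist),
    missing_rates = unlist(x$missing_rates), tto_missing = x$tto_missing,
    duplicate_rate = x$duplicate_rate,
    calendar_window = as.Date(unlist(x$calendar_window))
  )
}
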