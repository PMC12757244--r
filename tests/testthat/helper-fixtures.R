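# Builders for tiny in-code fixtures and independent brute-force oracles.

ONJ <- "Osteonecrosis of jaw"
onj_event <- event_label(ONJ)
deno_ps <- exposure_spec("denosumab")

# Build a small faers_reports from a compact per-report description.
# each report: list(pid, case, fda, age, sex, drugs = list(c(name, role)
# or c(name, role, dose)), events = chr, start = Date for first drug,
# event_dt = Date)
make_reports <- function(specs) {
  demo <- drugs <- events <- NULL
  drows <- list(); erows <- list(); dmrows <- list()
  for (s in specs) {
    dmrows[[length(dmrows) + 1]] <- tibble::tibble(
      primary_id = as.integer(s$pid), case_id = as.integer(s$case %||% s$pid),
      fda_dt = as.Date(s$fda %||% "2020-01-01"),
      event_dt = if (!is.null(s$event_dt)) as.Date(s$event_dt) else as.Date(NA),
      age_years = s$age %||% NA_real_, sex = s$sex %||% NA_character_,
      reporter = s$reporter %||% NA_character_,
      country = s$country %||% NA_character_
    )
    for (i in seq_along(s$drugs)) {
      d <- s$drugs[[i]]
      drows[[length(drows) + 1]] <- tibble::tibble(
        primary_id = as.integer(s$pid), drug_seq = i, name_raw = d[[1]],
        name_std = faersignal:::normalize_drug_name(d[[1]]), role = d[[2]],
        dose_text = if (length(d) >= 3) d[[3]] else NA_character_,
        regimen = parse_regimen(if (length(d) >= 3) d[[3]] else NA_character_),
        therapy_start = if (i == 1 && !is.null(s$start)) as.Date(s$start)
        else as.Date(NA)
      )
    }
    for (e in s$events %||% character()) {
      erows[[length(erows) + 1]] <- tibble::tibble(
        primary_id = as.integer(s$pid), pt_name = e, pt_code = NA_integer_
      )
    }
  }
  faers_reports(
    dplyr::bind_rows(dmrows),
    if (length(drows)) dplyr::bind_rows(drows) else
      faersignal:::empty_drugs(),
    if (length(erows)) dplyr::bind_rows(erows) else
      faersignal:::empty_events()
  )
}

# Brute-force deduplication oracle: group by case, argmax (fda_dt, pid).
dedup_oracle <- function(demo) {
  survivors <- vapply(split(demo, demo$case_id), function(g) {
    g <- g[order(g$fda_dt, g$primary_id, decreasing = TRUE), ]
    g$primary_id[1]
  }, integer(1))
  sort(unname(survivors))
}

# Independent ROR arithmetic, written directly from the estimator definition.
ror_oracle <- function(a, b, c, d, z = 1.96) {
  est <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = est, ci_low = exp(log(est) - z * se),
       ci_high = exp(log(est) + z * se))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  picks <- utils::combn(n1 + n2, n1)
  us <- apply(picks, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

faers_paths <- function(dir) {
  list(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
       reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"),
       outc = file.path(dir, "OUTC.txt"))
}

# Null-association generator config: all planted effects off.
null_config <- function(seed, n = 50000, bg = 0.01) {
  synth_config(
    n_reports = n, seed = seed, p_exposed = 0.15,
    role_probs = c(PS = 1, SS = 0, C = 0, I = 0),
    background_event_rate = bg,
    log_or = c(exposure = 0, male = 0, age_ge_65 = 0, high_dose = 0,
               `zoledronic acid` = 0),
    duplicate_rate = 0, tto_missing = 0,
    missing_rates = c(age = 0, sex = 0, reporter = 0, country = 0, dose = 0)
  )
}
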