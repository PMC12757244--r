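#' Read a drug-name synonym map
#'
#' FAERS drug names are verbatim reporter strings; analyses need them
#' collapsed to standard generic names. The map is a two-column delimited
#' text file (`raw_name<sep>standard_name`, header optional, `$`, `|`, tab
#' or comma separated). Lookup is case-insensitive on squished whitespace.
#'
#' @param path file location.
#' @return named character vector: normalized raw name -> standard name.
#' @export
read_synonym_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(character(), character()))
  sep <- detect_delim(lines[[1]], fallback = "\t")
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2
  parts <- parts[!bad]
  raw <- vapply(parts, `[[`, "", 1L)
  std <- vapply(parts, `[[`, "", 2L)
  drop <- normalize_drug_name(raw) %in% c("raw_name", "raw", "drugname")
  setNames(trimws(std[!drop]), normalize_drug_name(raw[!drop]))
}

apply_synonym_map <- function(raw_names, synonym_map) {
  key <- normalize_drug_name(raw_names)
  std <- unname(synonym_map[key])
  ifelse(is.na(std), key, normalize_drug_name(std))
}

# FAERS quarters switched delimiter over the years; detect from the header.
detect_delim <- function(header_line, fallback = "$") {
  for (d in c("$", "|", "\t", ",")) {
    if (grepl(d, header_line, fixed = TRUE)) return(d)
  }
  fallback
}

read_ascii_table <- function(path, required_cols) {
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- detect_delim(header)
  tab <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  names(tab) <- tolower(names(tab))
  missing_cols <- setdiff(required_cols, names(tab))
  for (mc in missing_cols) tab[[mc]] <- NA_character_
  tab
}

# Drop rows whose primaryid is absent/non-integer; returns table + count.
drop_malformed <- function(tab) {
  pid <- suppressWarnings(as.integer(tab$primaryid))
  bad <- is.na(pid)
  tab <- tab[!bad, , drop = FALSE]
  tab$primaryid <- pid[!bad]
  list(tab = tab, malformed = sum(bad))
}

occp_to_reporter <- function(occp_cod) {
  x <- toupper(trimws(ifelse(is.na(occp_cod), "", occp_cod)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("MD", "PH", "HP", "OT")] <- "healthcare_professional"
  out[x %in% c("CN", "LW")] <- "non_healthcare_professional"
  out
}

reporter_to_occp <- function(reporter) {
  out <- rep("", length(reporter))
  out[!is.na(reporter) & reporter == "healthcare_professional"] <- "MD"
  out[!is.na(reporter) & reporter == "non_healthcare_professional"] <- "CN"
  out
}

OUTC_CODES <- c(
  DE = "death", HO = "hospitalized", LT = "life_threatening",
  DS = "disability", RI = "required_intervention", OT = "other"
)

#' Read FAERS-style quarterly ASCII tables
#'
#' Reads the DEMO/DRUG/REAC and optional THER/OUTC tables of one FAERS-style
#' extract into a [faers_reports] container. Both the `$`- and `|`-delimited
#' dialects are accepted (auto-detected per file from the header row). Child
#' rows whose `primaryid` has no DEMO parent are dropped and counted as
#' orphans; rows with an unparseable `primaryid` are skipped and counted as
#' malformed; unparseable dates become missing. Counters are stored in the
#' result's `meta` field.
#'
#' @param paths named list/vector of file locations with names `demo`,
#'   `drug`, `reac`, and optionally `ther`, `outc`. DEMO is required.
#' @param synonym_map named character vector from [read_synonym_map], or
#'   `NULL` to standardize by case/whitespace normalization only.
#' @return a [faers_reports] object; `meta$load` holds the load report.
#' @export
read_faers_tables <- function(paths, synonym_map = NULL) {
  paths <- as.list(paths)
  if (is.null(paths$demo) || !file.exists(paths$demo)) {
    stop("DEMO table is required but missing", call. = FALSE)
  }
  synonym_map <- synonym_map %||% setNames(character(), character())

  malformed <- c(demo = 0L, drug = 0L, reac = 0L, ther = 0L, outc = 0L)
  orphans <- c(drug = 0L, reac = 0L, ther = 0L, outc = 0L)

  dm <- drop_malformed(read_ascii_table(
    paths$demo,
    c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod", "sex",
      "occp_cod", "reporter_country")
  ))
  malformed["demo"] <- dm$malformed
  d <- dm$tab
  sex <- toupper(trimws(ifelse(is.na(d$sex), "", d$sex)))
  demo <- tibble::tibble(
    primary_id = d$primaryid,
    case_id = suppressWarnings(as.integer(d$caseid)),
    fda_dt = parse_faers_date(d$fda_dt),
    event_dt = parse_faers_date(d$event_dt),
    age_years = harmonize_age(d$age, d$age_cod),
    sex = dplyr::case_match(sex, "M" ~ "male", "F" ~ "female",
                            .default = NA_character_),
    reporter = occp_to_reporter(d$occp_cod),
    country = ifelse(is.na(d$reporter_country) | trimws(d$reporter_country) == "",
                     NA_character_, toupper(trimws(d$reporter_country)))
  )
  known_ids <- demo$primary_id

  read_child <- function(name, cols) {
    if (is.null(paths[[name]]) || !file.exists(paths[[name]])) return(NULL)
    cm <- drop_malformed(read_ascii_table(paths[[name]], cols))
    malformed[name] <<- cm$malformed
    tab <- cm$tab
    orphan <- !(tab$primaryid %in% known_ids)
    orphans[name] <<- sum(orphan)
    tab[!orphan, , drop = FALSE]
  }

  dr <- read_child("drug", c("primaryid", "drug_seq", "role_cod", "drugname",
                             "dose_vbm"))
  if (is.null(dr)) stop("DRUG table is required but missing", call. = FALSE)
  dose_text <- ifelse(is.na(dr$dose_vbm) | trimws(dr$dose_vbm) == "",
                      NA_character_, dr$dose_vbm)
  drugs <- tibble::tibble(
    primary_id = dr$primaryid,
    drug_seq = suppressWarnings(as.integer(dr$drug_seq)),
    name_raw = ifelse(is.na(dr$drugname), "", dr$drugname),
    name_std = apply_synonym_map(ifelse(is.na(dr$drugname), "", dr$drugname),
                                 synonym_map),
    role = toupper(trimws(ifelse(is.na(dr$role_cod), "", dr$role_cod))),
    dose_text = dose_text,
    regimen = parse_regimen(dose_text),
    therapy_start = as.Date(rep(NA_character_, nrow(dr)))
  )
  bad_role <- !(drugs$role %in% c("PS", "SS", "C", "I"))
  malformed["drug"] <- malformed["drug"] + sum(bad_role)
  drugs <- drugs[!bad_role, , drop = FALSE]

  re <- read_child("reac", c("primaryid", "pt"))
  if (is.null(re)) stop("REAC table is required but missing", call. = FALSE)
  events <- tibble::tibble(
    primary_id = re$primaryid,
    pt_name = ifelse(is.na(re$pt), "", re$pt),
    pt_code = rep(NA_integer_, nrow(re))
  )

  th <- read_child("ther", c("primaryid", "dsg_drug_seq", "start_dt"))
  if (!is.null(th) && nrow(th) > 0) {
    ther <- tibble::tibble(
      primary_id = th$primaryid,
      drug_seq = suppressWarnings(as.integer(th$dsg_drug_seq)),
      start = parse_faers_date(th$start_dt)
    )
    drugs <- drugs |>
      dplyr::left_join(ther, by = c("primary_id", "drug_seq")) |>
      dplyr::mutate(therapy_start = .data$start) |>
      dplyr::select(-"start")
  }

  ou <- read_child("outc", c("primaryid", "outc_cod"))
  outcomes <- if (is.null(ou)) empty_outcomes() else {
    tibble::tibble(
      primary_id = ou$primaryid,
      outcome = unname(OUTC_CODES[toupper(trimws(ifelse(is.na(ou$outc_cod), "",
                                                        ou$outc_cod)))])
    ) |> dplyr::filter(!is.na(.data$outcome))
  }

  faers_reports(
    demo, drugs, events, outcomes,
    meta = list(load = list(malformed = malformed, orphans = orphans,
                            n_reports = nrow(demo)))
  )
}

#' Write a report set as FAERS-style ASCII tables
#'
#' Emits DEMO/DRUG/REAC/THER/OUTC files in the FAERS quarterly dialect such
#' that [read_faers_tables] round-trips the dataset field-equal. THER rows
#' are written only for drug entries with a therapy start date; outcome codes
#' use the FAERS two-letter vocabulary.
#'
#' @param reports a [faers_reports] object.
#' @param out_dir output directory, created if absent.
#' @param delim field delimiter, `"$"` (default) or `"|"`.
#' @return invisibly, a named vector of the files written.
#' @export
write_faers_tables <- function(reports, out_dir, delim = "$") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  stopifnot(delim %in% c("$", "|"))

  w <- function(df, file) {
    path <- file.path(out_dir, file)
    df[] <- lapply(df, function(col) {
      col <- as.character(col)
      ifelse(is.na(col), "", col)
    })
    lines <- c(paste(names(df), collapse = delim),
               do.call(paste, c(unname(as.list(df)), sep = delim)))
    writeLines(lines, path)
    path
  }

  d <- reports$demo
  demo_out <- data.frame(
    primaryid = d$primary_id, caseid = d$case_id,
    fda_dt = format_faers_date(d$fda_dt), event_dt = format_faers_date(d$event_dt),
    age = ifelse(is.na(d$age_years), "", format(d$age_years, trim = TRUE,
                                                scientific = FALSE)),
    age_cod = ifelse(is.na(d$age_years), "", "YR"),
    sex = dplyr::case_match(d$sex, "male" ~ "M", "female" ~ "F",
                            .default = ""),
    occp_cod = reporter_to_occp(d$reporter),
    reporter_country = ifelse(is.na(d$country), "", d$country)
  )

  dr <- reports$drugs
  drug_out <- data.frame(
    primaryid = dr$primary_id, drug_seq = dr$drug_seq, role_cod = dr$role,
    drugname = dr$name_raw,
    dose_vbm = ifelse(is.na(dr$dose_text), "", dr$dose_text)
  )

  ev <- reports$events
  reac_out <- data.frame(primaryid = ev$primary_id, pt = ev$pt_name)

  th <- dr[!is.na(dr$therapy_start), , drop = FALSE]
  ther_out <- data.frame(
    primaryid = th$primary_id, dsg_drug_seq = th$drug_seq,
    start_dt = format_faers_date(th$therapy_start)
  )

  oc <- reports$outcomes
  outc_out <- data.frame(
    primaryid = oc$primary_id,
    outc_cod = names(OUTC_CODES)[match(oc$outcome, OUTC_CODES)]
  )

  files <- c(
    demo = w(demo_out, "DEMO.txt"), drug = w(drug_out, "DRUG.txt"),
    reac = w(reac_out, "REAC.txt"), ther = w(ther_out, "THER.txt"),
    outc = w(outc_out, "OUTC.txt")
  )
  invisible(files)
}
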