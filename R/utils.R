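#' @importFrom rlang .data %||%
#' @importFrom stats median quantile qlogis plogis rbinom rnorm runif rweibull
#'   glm binomial coef vcov logLik pchisq pnorm pwilcox optim dweibull
#'   wilcox.test as.formula setNames qnorm
NULL

# FAERS dates are yyyymmdd integers; partial (yyyy or yyyymm) or garbled
# values parse to NA rather than erroring.
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[!grepl("^\\d{8}$", x %||% "")] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

format_faers_date <- function(d) {
  ifelse(is.na(d), "", format(d, "%Y%m%d"))
}

# PT comparison is case-insensitive on squished whitespace.
normalize_pt <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

normalize_drug_name <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

#' Convert FAERS age codes to years
#'
#' FAERS reports age as a number plus a unit code (`AGE_COD`): `YR` years,
#' `DEC` decades, `MON` months, `WK` weeks, `DY` days, `HR` hours. Values are
#' converted to years; results outside \[0, 130\] (implausible for a human
#' patient) are set to missing, as is any age with an unrecognized unit.
#'
#' @param age numeric vector of raw ages.
#' @param age_cod character vector of FAERS unit codes; empty or `NA` codes
#'   are treated as years, the FAERS default.
#' @return numeric vector of ages in years, `NA` where not interpretable.
#' @export
harmonize_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "", age_cod)))
  mult <- rep(NA_real_, length(age))
  mult[cod %in% c("", "YR")] <- 1
  mult[cod == "DEC"] <- 10
  mult[cod == "MON"] <- 1 / 12
  mult[cod == "WK"] <- 7 / 365.25
  mult[cod == "DY"] <- 1 / 365.25
  mult[cod == "HR"] <- 1 / (24 * 365.25)
  yrs <- age * mult
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 130)] <- NA_real_
  yrs
}

#' Derive a dosing regimen label from verbatim dose text
#'
#' Denosumab is marketed in two regimens tied to indication: 60 mg every six
#' months (osteoporosis) and 120 mg every four weeks (skeletal complications
#' of malignancy). The dose string is the only regimen information FAERS
#' carries, so the label is derived from it: text containing "120 mg" maps to
#' `q4w_120mg`, "60 mg" to `q6m_60mg`, any other non-empty text to `other`,
#' and missing text to `NA`. Text matching both doses is ambiguous and maps
#' to `other`.
#'
#' @param dose_text character vector of verbatim dose/regimen strings.
#' @return character vector over `q6m_60mg`, `q4w_120mg`, `other`, `NA`.
#' @export
parse_regimen <- function(dose_text) {
  out <- rep(NA_character_, length(dose_text))
  present <- !is.na(dose_text) & trimws(dose_text) != ""
  hi <- present & grepl("120\\s*mg", dose_text, ignore.case = TRUE)
  lo <- present & grepl("60\\s*mg", dose_text, ignore.case = TRUE)
  out[present] <- "other"
  out[hi & !lo] <- "q4w_120mg"
  out[lo & !hi] <- "q6m_60mg"
  out
}

# Percentage of a count within an availability denominator, as printed in
# descriptive tables (one decimal by default).
share_pct <- function(num, den, digits = 1) {
  round(100 * num / den, digits)
}
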