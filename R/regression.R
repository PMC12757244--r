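#' Build the complete-case analysis frame for the target-drug cohort
#'
#' Restricts the dataset to reports carrying the cohort drug (with the
#' cohort's required role, normally primary suspect), derives the binary
#' outcome (target event reported or not) and the binary covariates, and
#' applies complete-case filtering: a report missing any of sex, age, or
#' regimen is removed entirely, with a per-field tally of the exclusions.
#' Co-drug indicators are derived from drug-list presence and are never
#' missing. The dosage covariate `high_dose` is 1 for the 120 mg Q4W regimen,
#' 0 for 60 mg Q6M, and missing for any other or unparseable dose text.
#'
#' @param reports a deduplicated [faers_reports] object.
#' @param cohort an [exposure_spec] defining the cohort drug (demographic or
#'   regimen refinements are not allowed here: the frame carries them as
#'   covariates instead).
#' @param event an [event_label].
#' @param co_drugs character vector of standardized co-drug names, one 0/1
#'   column each.
#' @param age_cut age threshold in years for the `age_ge_65`-style indicator.
#' @return list with `frame` (tibble: `outcome`, `sex_male`, `age_ge_65`,
#'   `high_dose`, one column per co-drug) and `exclusions` (named counts:
#'   cohort size, per-field missing counts, rows retained).
#' @export
build_frame <- function(reports, cohort, event, co_drugs = character(),
                        age_cut = 65) {
  stopifnot(inherits(cohort, "exposure_spec"))
  if (!is.null(cohort$sex) || !is.null(cohort$age_min) ||
      !is.null(cohort$age_max) || !is.null(cohort$regimen)) {
    stop("cohort spec must not carry demographic/regimen refinements",
         call. = FALSE)
  }
  cls <- classify_reports(reports, cohort, event)
  in_cohort <- cls$primary_id[cls$class %in% c("exposed_case",
                                               "exposed_noncase")]
  demo <- dplyr::filter(reports$demo, .data$primary_id %in% in_cohort)
  drugs <- dplyr::filter(reports$drugs, .data$primary_id %in% in_cohort)
  case_ids <- match_event(reports, event)

  role_ok <- if (cohort$required_role == "PS") drugs$role == "PS" else TRUE
  trows <- drugs[drugs$name_std == cohort$target_drug & role_ok, ,
                 drop = FALSE]
  reg <- trows |>
    dplyr::group_by(.data$primary_id) |>
    dplyr::summarise(
      high_dose = if (any(!is.na(.data$regimen) &
                            .data$regimen == "q4w_120mg")) 1L
      else if (any(!is.na(.data$regimen) & .data$regimen == "q6m_60mg")) 0L
      else NA_integer_,
      .groups = "drop"
    )

  frame <- demo |>
    dplyr::left_join(reg, by = "primary_id") |>
    dplyr::mutate(
      outcome = as.integer(.data$primary_id %in% case_ids),
      sex_male = dplyr::case_match(.data$sex, "male" ~ 1L, "female" ~ 0L,
                                   .default = NA_integer_),
      age_ge_65 = ifelse(is.na(.data$age_years), NA_integer_,
                         as.integer(.data$age_years >= age_cut))
    )
  for (cd in co_drugs) {
    cd_std <- normalize_drug_name(cd)
    col <- gsub("\\s+", "_", cd_std)
    cd_ids <- unique(drugs$primary_id[drugs$name_std == cd_std])
    frame[[col]] <- as.integer(frame$primary_id %in% cd_ids)
  }

  exclusions <- c(
    cohort = nrow(frame),
    sex = sum(is.na(frame$sex_male)),
    age = sum(is.na(frame$age_ge_65)),
    dose = sum(is.na(frame$high_dose))
  )
  keep_cols <- c("outcome", "sex_male", "age_ge_65", "high_dose",
                 gsub("\\s+", "_", normalize_drug_name(co_drugs)))
  complete <- stats::complete.cases(frame[keep_cols])
  frame <- frame[complete, keep_cols]
  exclusions["used"] <- nrow(frame)

  if (nrow(frame) == 0 || length(unique(frame$outcome)) < 2) {
    stop("unfittable frame: empty or single-class outcome after ",
         "complete-case filtering", call. = FALSE)
  }
  list(frame = tibble::as_tibble(frame), exclusions = exclusions)
}

glm_ctrl <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

fit_logistic <- function(frame, vars) {
  f <- as.formula(paste("outcome ~", paste(vars, collapse = " + ")))
  fit <- glm(f, family = binomial(), data = frame, control = glm_ctrl())
  if (!fit$converged) {
    stop(sprintf("logistic fit did not converge in %d IRLS iterations (%s)",
                 glm_ctrl()$maxit, paste(vars, collapse = "+")),
         call. = FALSE)
  }
  fit
}

# |logit coefficient| above this is treated as (quasi-)complete separation;
# sparse co-drug indicators are the usual culprit.
SEPARATION_CUTOFF <- 15

#' Univariate screen with crude odds ratios
#'
#' Fits one single-covariate logistic model per variable. The crude OR is the
#' exponentiated coefficient with a Wald 95% CI; the p-value is the
#' likelihood-ratio test against the intercept-only model. Variables pass the
#' screen when p is below `alpha_screen` or they are force-included (the
#' default force list carries the age indicator, retained for baseline
#' confounding control regardless of univariate significance). Variables
#' whose fitted coefficient exceeds the separation cutoff are flagged and
#' never pass the screen.
#'
#' @param frame analysis frame from [build_frame] (the `frame` element).
#' @param alpha_screen screening threshold on the univariate p, default 0.20.
#' @param force_include variables included in the multivariate model
#'   irrespective of their univariate p.
#' @param z normal critical value for the Wald CI.
#' @return tibble: `variable`, `crude_or`, `ci_low`, `ci_high`, `p_crude`,
#'   `separation`, `screen_included`.
#' @export
univariate_screen <- function(frame, alpha_screen = 0.20,
                              force_include = c("age_ge_65"), z = 1.96) {
  vars <- setdiff(names(frame), "outcome")
  rows <- lapply(vars, function(v) {
    fit <- fit_logistic(frame, v)
    beta <- coef(fit)[[v]]
    se <- sqrt(vcov(fit)[v, v])
    p <- pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
    sep <- is.na(beta) || abs(beta) > SEPARATION_CUTOFF
    if (sep) {
      warning("separation detected for variable '", v,
              "'; excluded from the multivariate model", call. = FALSE)
    }
    tibble::tibble(
      variable = v, crude_or = exp(beta),
      ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
      p_crude = p, separation = sep,
      screen_included = !sep && (p < alpha_screen || v %in% force_include)
    )
  })
  dplyr::bind_rows(rows)
}

#' Multivariate logistic model with adjusted odds ratios
#'
#' One joint maximum-likelihood fit over the included variables. Adjusted ORs
#' are exponentiated coefficients with Wald 95% CIs; each variable's p-value
#' is the likelihood-ratio test comparing the full model to the model with
#' that variable removed. Aliased (collinear) variables are dropped with a
#' warning before testing.
#'
#' @param frame analysis frame from [build_frame].
#' @param included character vector of variables to fit (non-empty),
#'   normally the screen-passing set from [univariate_screen].
#' @param z normal critical value for the Wald CIs.
#' @return an object of class `logistic_fit`: tibble `estimates`
#'   (`variable`, `adjusted_or`, `ci_low`, `ci_high`, `p_lrt`), plus
#'   `log_lik`, `n`, `dropped` (aliased variables), and the `glm` object.
#' @export
multivariate_fit <- function(frame, included, z = 1.96) {
  stopifnot(length(included) >= 1, all(included %in% names(frame)))
  fit <- fit_logistic(frame, included)
  cf <- coef(fit)[included]
  dropped <- included[is.na(cf)]
  if (length(dropped)) {
    warning("collinear variables dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    included <- setdiff(included, dropped)
    fit <- fit_logistic(frame, included)
    cf <- coef(fit)[included]
  }
  vc <- vcov(fit)
  ll_full <- as.numeric(logLik(fit))
  rows <- lapply(included, function(v) {
    rest <- setdiff(included, v)
    red <- if (length(rest)) fit_logistic(frame, rest)
    else glm(outcome ~ 1, family = binomial(), data = frame,
             control = glm_ctrl())
    lrt <- 2 * (ll_full - as.numeric(logLik(red)))
    se <- sqrt(vc[v, v])
    tibble::tibble(
      variable = v, adjusted_or = exp(cf[[v]]),
      ci_low = exp(cf[[v]] - z * se), ci_high = exp(cf[[v]] + z * se),
      p_lrt = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
    )
  })
  structure(
    list(estimates = dplyr::bind_rows(rows), log_lik = ll_full,
         n = nrow(frame), dropped = dropped, model = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d, logLik=%.2f, %d variables\n",
              x$n, x$log_lik, nrow(x$estimates)))
  print(x$estimates)
  invisible(x)
}

#' Combine crude and adjusted results into one risk-factor table
#'
#' Produces the conventional two-column layout: every screened variable keeps
#' its crude OR row; variables that did not enter the multivariate model
#' (screened out, separated, or collinear) have empty adjusted fields.
#'
#' @param screen tibble from [univariate_screen].
#' @param fit a `logistic_fit` from [multivariate_fit], or `NULL`.
#' @return tibble with crude and adjusted OR columns and flags.
#' @export
logistic_table <- function(screen, fit = NULL) {
  adj <- if (is.null(fit)) {
    tibble::tibble(variable = character(), adjusted_or = double(),
                   adj_ci_low = double(), adj_ci_high = double(),
                   p_adjusted = double())
  } else {
    dplyr::rename(fit$estimates, adj_ci_low = "ci_low",
                  adj_ci_high = "ci_high", p_adjusted = "p_lrt")
  }
  screen |>
    dplyr::rename(crude_ci_low = "ci_low", crude_ci_high = "ci_high") |>
    dplyr::left_join(adj, by = "variable")
}
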