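# A generator config whose cohort is the whole dataset: everyone carries the
# target drug as PS with fully observed covariates, so the frame size equals
# n_reports and the planted coefficients are the within-cohort truth.
cohort_config <- function(seed, n = 8000,
                          lor = c(exposure = 0, male = log(3),
                                  age_ge_65 = 0, high_dose = log(7),
                                  `zoledronic acid` = log(10)),
                          bg = 0.02, co_prev = 0.04) {
  synth_config(
    n_reports = n, seed = seed, p_exposed = 1,
    role_probs = c(PS = 1, SS = 0, C = 0, I = 0),
    background_event_rate = bg, log_or = lor,
    co_drug_prev = c(`zoledronic acid` = co_prev),
    duplicate_rate = 0, tto_missing = 1,
    missing_rates = c(age = 0, sex = 0, reporter = 0, country = 0, dose = 0)
  )
}

test_that("complete-case filtering drops and tallies reports per field", {
  r <- make_reports(list(
    list(pid = 1, sex = "male", age = 70,
         drugs = list(c("denosumab", "PS", "60 MG")), events = ONJ),
    list(pid = 2, sex = "female", age = 50,
         drugs = list(c("denosumab", "PS", "120 MG"))),
    list(pid = 3, age = 70, drugs = list(c("denosumab", "PS", "60 MG"))),
    list(pid = 4, sex = "male", drugs = list(c("denosumab", "PS", "60 MG"))),
    list(pid = 5, sex = "male", age = 70, drugs = list(c("denosumab", "PS"))),
    list(pid = 6, sex = "male", age = 70, drugs = list(c("denosumab", "C", "60 MG"))),
    list(pid = 7, sex = "female", age = 40,
         drugs = list(c("denosumab", "PS", "120 MG")), events = ONJ)
  ))
  bf <- build_frame(r, deno_ps, onj_event)
  # pid 3 missing sex, pid 4 missing age, pid 5 missing dose, pid 6 not PS
  expect_equal(unname(bf$exclusions[c("cohort", "sex", "age", "dose", "used")]),
               c(6, 1, 1, 1, 3))
  expect_equal(nrow(bf$frame), 3)
  expect_equal(sort(bf$frame$outcome), c(0, 1, 1))
})

test_that("frame size matches the generator's fully observed cohort count", {
  cfg <- synth_config(n_reports = 4000, seed = 61, p_exposed = 1,
                      role_probs = c(PS = 1, SS = 0, C = 0, I = 0),
                      duplicate_rate = 0)
  gen <- synth_generate(cfg)
  bf <- build_frame(gen$reports, deno_ps, onj_event,
                    co_drugs = "zoledronic acid")
  tt <- gen$truth$truth
  fully_observed <- sum(!tt$masked_sex & !tt$masked_age & !tt$masked_dose)
  expect_equal(nrow(bf$frame), fully_observed)
})

test_that("single-class or empty frames are explicit errors", {
  r <- make_reports(list(
    list(pid = 1, sex = "male", age = 70,
         drugs = list(c("denosumab", "PS", "60 MG")))
  ))
  expect_error(build_frame(r, deno_ps, onj_event), "unfittable")
})

test_that("crude OR equals the classical 2x2 cross-product for binary covariates", {
  gen <- synth_generate(cohort_config(seed = 71, n = 6000))
  bf <- build_frame(gen$reports, deno_ps, onj_event,
                    co_drugs = "zoledronic acid")
  screen <- univariate_screen(bf$frame)
  for (v in screen$variable) {
    x <- bf$frame[[v]]; y <- bf$frame$outcome
    or_2x2 <- (sum(x == 1 & y == 1) * sum(x == 0 & y == 0)) /
      (sum(x == 1 & y == 0) * sum(x == 0 & y == 1))
    expect_equal(screen$crude_or[screen$variable == v], or_2x2,
                 tolerance = 1e-7)
  }
})

test_that("null covariates pass through the screen only via force-include", {
  gen <- synth_generate(cohort_config(
    seed = 81, n = 20000,
    lor = c(exposure = 0, male = 0, age_ge_65 = 0, high_dose = log(7),
            `zoledronic acid` = log(10))
  ))
  bf <- build_frame(gen$reports, deno_ps, onj_event,
                    co_drugs = "zoledronic acid")
  screen <- univariate_screen(bf$frame, force_include = "age_ge_65")
  male <- screen[screen$variable == "sex_male", ]
  expect_true(male$ci_low < 1 && 1 < male$ci_high)
  age <- screen[screen$variable == "age_ge_65", ]
  expect_true(age$screen_included)  # forced despite null effect
})

test_that("a planted strong effect is recovered by the crude estimate", {
  gen <- synth_generate(cohort_config(
    seed = 91, n = 40000,
    lor = c(exposure = 0, male = 0, age_ge_65 = 0, high_dose = log(8),
            `zoledronic acid` = 0)
  ))
  bf <- build_frame(gen$reports, deno_ps, onj_event)
  screen <- univariate_screen(bf$frame)
  hd <- screen[screen$variable == "high_dose", ]
  expect_true(hd$ci_low < 8 && 8 < hd$ci_high)
})

test_that("single-variable adjusted OR equals the crude OR", {
  gen <- synth_generate(cohort_config(seed = 101, n = 5000))
  bf <- build_frame(gen$reports, deno_ps, onj_event)
  screen <- univariate_screen(bf$frame)
  fit <- multivariate_fit(bf$frame, "high_dose")
  expect_equal(fit$estimates$adjusted_or,
               screen$crude_or[screen$variable == "high_dose"],
               tolerance = 1e-8)
})

test_that("LRT statistics are non-negative and order-invariant", {
  gen <- synth_generate(cohort_config(seed = 111, n = 5000))
  bf <- build_frame(gen$reports, deno_ps, onj_event,
                    co_drugs = "zoledronic acid")
  vars <- setdiff(names(bf$frame), "outcome")
  fit <- multivariate_fit(bf$frame, vars)
  expect_true(all(fit$estimates$p_lrt >= 0 & fit$estimates$p_lrt <= 1))

  shuffled <- bf$frame[sample(nrow(bf$frame)), ]
  fit2 <- multivariate_fit(shuffled, vars)
  expect_equal(fit$estimates$adjusted_or, fit2$estimates$adjusted_or,
               tolerance = 1e-10)
  expect_equal(fit$log_lik, fit2$log_lik, tolerance = 1e-8)
})

test_that("adjustment de-confounds a co-drug correlated with dose", {
  # plant confounding by hand: co-drug present mostly in high-dose reports,
  # with no effect of its own
  set.seed(121)
  n <- 30000
  high <- rbinom(n, 1, 0.4)
  co <- rbinom(n, 1, ifelse(high == 1, 0.30, 0.02))
  y <- rbinom(n, 1, plogis(qlogis(0.02) + log(6) * high + 0 * co))
  frame <- tibble::tibble(outcome = y, high_dose = high, co_drug = co)
  screen <- univariate_screen(frame, force_include = character())
  fit <- multivariate_fit(frame, c("high_dose", "co_drug"))
  crude_co <- screen$crude_or[screen$variable == "co_drug"]
  adj_co <- fit$estimates$adjusted_or[fit$estimates$variable == "co_drug"]
  expect_lt(abs(log(adj_co)), abs(log(crude_co)))  # closer to the null truth
  adj_hd <- fit$estimates$adjusted_or[fit$estimates$variable == "high_dose"]
  expect_true(abs(log(adj_hd) - log(6)) < abs(log(crude_co)))
})

test_that("separation is flagged and the variable excluded", {
  frame <- tibble::tibble(
    outcome = c(rep(1, 20), rep(0, 80)),
    sep_var = c(rep(1, 20), rep(0, 80)),
    ok_var = rbinom(100, 1, 0.5)
  )
  expect_warning(screen <- univariate_screen(frame), "separation")
  expect_true(screen$separation[screen$variable == "sep_var"])
  expect_false(screen$screen_included[screen$variable == "sep_var"])
})

test_that("collinear variables are dropped with a warning", {
  gen <- synth_generate(cohort_config(seed = 131, n = 4000))
  bf <- build_frame(gen$reports, deno_ps, onj_event)
  frame <- bf$frame
  frame$dup <- frame$high_dose
  expect_warning(fit <- multivariate_fit(frame, c("high_dose", "sex_male", "dup")),
                 "collinear")
  expect_false("dup" %in% fit$estimates$variable)
})

test_that("the combined table keeps crude-only rows for excluded variables", {
  gen <- synth_generate(cohort_config(seed = 141, n = 8000))
  bf <- build_frame(gen$reports, deno_ps, onj_event,
                    co_drugs = "zoledronic acid")
  screen <- univariate_screen(bf$frame, force_include = character())
  included <- screen$variable[screen$screen_included]
  fit <- multivariate_fit(bf$frame, included)
  tbl <- logistic_table(screen, fit)
  expect_equal(nrow(tbl), nrow(screen))
  out_vars <- setdiff(screen$variable, included)
  if (length(out_vars)) {
    expect_true(all(is.na(tbl$adjusted_or[tbl$variable %in% out_vars])))
  }
  expect_true(all(!is.na(tbl$crude_or)))
})
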