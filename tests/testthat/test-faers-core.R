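test_that("deduplication keeps the latest-dated, highest-id version per case", {
  r <- make_reports(list(
    list(pid = 5, case = 1, fda = "2020-01-01"),
    list(pid = 4, case = 1, fda = "2021-06-01")
  ))
  r$drugs <- tibble::add_row(faersignal:::empty_drugs(),
                             primary_id = c(4L, 5L), drug_seq = 1L,
                             name_raw = "x", name_std = "x", role = "PS")
  out <- deduplicate(r)
  expect_equal(out$demo$primary_id, 4L)

  # receipt-date tie broken by the higher primary id
  r2 <- make_reports(list(
    list(pid = 4, case = 1, fda = "2021-06-01", drugs = list(c("x", "PS"))),
    list(pid = 9, case = 1, fda = "2021-06-01", drugs = list(c("x", "PS")))
  ))
  expect_equal(deduplicate(r2)$demo$primary_id, 9L)

  # no duplicates: output equals input (sorted by case id)
  r3 <- make_reports(lapply(1:6, function(i) {
    list(pid = i, case = i, drugs = list(c("x", "PS")))
  }))
  expect_equal(deduplicate(r3)$demo, dplyr::arrange(r3$demo, case_id))
})

test_that("deduplication matches the brute-force oracle and is idempotent", {
  set.seed(11)
  for (rep in 1:20) {
    n_cases <- sample(3:20, 1)
    rows <- list()
    pid <- 0L
    for (cs in seq_len(n_cases)) {
      for (v in seq_len(sample(1:4, 1))) {
        pid <- pid + 1L
        rows[[pid]] <- list(
          pid = pid, case = cs,
          fda = as.character(as.Date("2018-01-01") + sample(0:1000, 1)),
          drugs = list(c("x", "PS"))
        )
      }
    }
    r <- make_reports(rows)
    got <- deduplicate(r)
    expect_equal(sort(got$demo$primary_id), dedup_oracle(r$demo))
    expect_equal(deduplicate(got)$demo, got$demo)
    # child tables restricted to survivors
    expect_true(all(got$drugs$primary_id %in% got$demo$primary_id))
  }
})

test_that("shared primary ids violate the identifier contract", {
  r <- make_reports(list(list(pid = 1, case = 1, drugs = list(c("x", "PS")))))
  r$demo <- dplyr::bind_rows(r$demo, r$demo)
  expect_error(deduplicate(r), "primary_id")
})

test_that("classification implements the exposure and event definitions", {
  r <- make_reports(list(
    list(pid = 1, drugs = list(c("Denosumab", "PS")), events = ONJ),
    list(pid = 2, drugs = list(c("DENOSUMAB", "C")), events = ONJ),
    list(pid = 3, drugs = list(c("denosumab", "PS"), c("zoledronic acid", "SS")),
         events = ONJ),
    list(pid = 4, drugs = list(c("otherdrug", "PS")), events = "Nausea")
  ))
  cls <- classify_reports(r, deno_ps, onj_event)
  expect_equal(as.character(cls$class[cls$primary_id == 1]), "exposed_case")
  # non-PS role fails the PS requirement -> comparator
  expect_equal(as.character(cls$class[cls$primary_id == 2]), "unexposed_case")
  expect_equal(as.character(cls$class[cls$primary_id == 4]),
               "unexposed_noncase")

  # required co-drug absent -> unexposed despite target drug as PS
  with_za <- refine_exposure(deno_ps, co_drugs = "zoledronic acid")
  cls2 <- classify_reports(r, with_za, onj_event)
  expect_equal(as.character(cls2$class[cls2$primary_id == 1]),
               "unexposed_case")
  expect_equal(as.character(cls2$class[cls2$primary_id == 3]), "exposed_case")
})

test_that("classification partitions the dataset for any refinement", {
  gen <- synth_generate(synth_config(n_reports = 2000, seed = 3))
  reports <- deduplicate(gen$reports)
  specs <- list(
    deno_ps,
    refine_exposure(deno_ps, sex = "male"),
    refine_exposure(deno_ps, regimen = "q4w_120mg"),
    refine_exposure(deno_ps, age_min = 65, regimen = "q6m_60mg"),
    refine_exposure(deno_ps, co_drugs = "zoledronic acid", sex = "female")
  )
  for (sp in specs) {
    cls <- classify_reports(reports, sp, onj_event)
    expect_equal(nrow(cls), nrow(reports$demo))
    expect_equal(sum(table(cls$class)), nrow(reports$demo))
  }
})

test_that("missing fields referenced by a refinement are not classifiable", {
  r <- make_reports(list(
    list(pid = 1, sex = "male", drugs = list(c("denosumab", "PS")),
         events = ONJ),
    list(pid = 2, drugs = list(c("denosumab", "PS")), events = ONJ),
    list(pid = 3, sex = "female", drugs = list(c("otherdrug", "PS")))
  ))
  cls <- classify_reports(r, refine_exposure(deno_ps, sex = "male"), onj_event)
  expect_equal(as.character(cls$class),
               c("exposed_case", "not_classifiable", "unexposed_noncase"))

  # regimen refinement: target-drug report with unknown dose is not
  # classifiable; non-target reports are untouched by the regimen filter
  r2 <- make_reports(list(
    list(pid = 1, drugs = list(c("denosumab", "PS", "120 MG")), events = ONJ),
    list(pid = 2, drugs = list(c("denosumab", "PS"))),
    list(pid = 3, drugs = list(c("otherdrug", "PS")))
  ))
  cls2 <- classify_reports(r2, refine_exposure(deno_ps, regimen = "q4w_120mg"),
                           onj_event)
  expect_equal(as.character(cls2$class),
               c("exposed_case", "not_classifiable", "unexposed_noncase"))
})

test_that("age harmonization converts FAERS unit codes and bounds the range", {
  expect_equal(harmonize_age(c(70, 7, 24, 730.5), c("YR", "DEC", "MON", "DY")),
               c(70, 70, 2, 2))
  expect_true(is.na(harmonize_age(140, "YR")))
  expect_true(is.na(harmonize_age(-1, "YR")))
  expect_equal(harmonize_age(55, NA), 55)  # missing unit defaults to years
  expect_true(is.na(harmonize_age(55, "XX")))
})

test_that("regimen parsing follows the dose-text rule", {
  expect_equal(
    parse_regimen(c("120 MG", "120mg, Q4W", "60 mg", "60MG Q6M",
                    "unknown", NA, "", "60 mg then 120 mg")),
    c("q4w_120mg", "q4w_120mg", "q6m_60mg", "q6m_60mg",
      "other", NA, NA, "other")
  )
})

test_that("reading joins child tables and counts orphans and malformed rows", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country",
               "101$1$20200101$$65$YR$F$MD$US",
               "102$2$20200102$$$$M$CN$JP",
               "103$3$20200103$$80$YR$$$"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname$dose_vbm",
               "101$1$PS$DENOSUMAB$60 MG",
               "101$2$SS$ZOLEDRONIC ACID$",
               "102$1$PS$OTHERDRUG$",
               "103$1$PS$DENOSUMAB$120 MG",
               "bad$1$PS$X$",
               "999$1$PS$ORPHANDRUG$"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt",
               "101$Osteonecrosis of jaw", "102$Nausea", "103$Headache",
               "998$Orphan event"),
             file.path(dir, "REAC.txt"))
  r <- read_faers_tables(faers_paths(dir))
  expect_equal(nrow(r$demo), 3)
  expect_equal(sum(vapply(split(r$drugs, r$drugs$primary_id), nrow, 1L)), 4)
  expect_equal(unname(r$meta$load$orphans[c("drug", "reac")]), c(1L, 1L))
  expect_equal(unname(r$meta$load$malformed[["drug"]]), 1L)
  expect_equal(r$demo$age_years, c(65, NA, 80))
  expect_equal(r$demo$sex, c("female", "male", NA))
  expect_equal(r$demo$reporter, c("healthcare_professional",
                                  "non_healthcare_professional", NA))
  expect_equal(r$drugs$regimen[r$drugs$primary_id == 103], "q4w_120mg")
  expect_error(read_faers_tables(list(demo = file.path(dir, "nope.txt"))),
               "DEMO")
})

test_that("both delimiter dialects are auto-detected and round-trip", {
  gen <- synth_generate(synth_config(n_reports = 150, seed = 9))
  reports <- deduplicate(gen$reports)
  for (delim in c("$", "|")) {
    dir <- withr::local_tempdir()
    write_faers_tables(reports, dir, delim = delim)
    back <- read_faers_tables(faers_paths(dir))
    expect_equal(as.data.frame(back$demo), as.data.frame(reports$demo))
    expect_equal(as.data.frame(back$drugs), as.data.frame(reports$drugs))
    expect_equal(as.data.frame(back$events), as.data.frame(reports$events))
    expect_equal(as.data.frame(back$outcomes),
                 as.data.frame(reports$outcomes))
  }
})

test_that("synonym map standardizes raw drug names case-insensitively", {
  dir <- withr::local_tempdir()
  map_file <- file.path(dir, "map.txt")
  writeLines(c("raw_name\tstandard_name",
               "PROLIA\tdenosumab", "Xgeva \tdenosumab"), map_file)
  map <- read_synonym_map(map_file)
  expect_equal(unname(map[c("prolia", "xgeva")]),
               c("denosumab", "denosumab"))
  r <- make_reports(list(list(pid = 1, drugs = list(c("ProLia", "PS")))))
  r$drugs$name_std <- faersignal:::apply_synonym_map(r$drugs$name_raw, map)
  expect_equal(r$drugs$name_std, "denosumab")
})
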