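test_that("cohort filters retain exactly the hand-derived set with each
          exclusion attributed to its first failing rule", {
  fx <- filter_fixture()
  res <- apply_cohort_filters(fx, as.Date("2018-09-27"))
  # visit 1: every vital and troponin exactly at its cutoff -> retained
  # visit 2: cellulitis at exactly 100.3 F -> retained (strict cutoffs)
  expect_identical(res$report$retained_ids, c("F1", "F2"))
  expect_identical(res$report$n_retained, 2L)
  expect_identical(res$report$exclusions,
                   c(disposition = 1L, acuity = 0L, tail_45d = 1L,
                     troponin = 1L, vitals = 2L, diagnosis_flags = 1L,
                     cellulitis_fever = 0L))
  expect_identical(res$report$n_input,
                   res$report$n_retained + sum(res$report$exclusions))
  # SNF discharge mapped to decision = discharge and kept
  expect_identical(res$data$decision[res$data$visit_id == "F2"],
                   "discharge")
})

test_that("each strict boundary crossing excludes while the boundary value
          is retained", {
  fx <- filter_fixture()[1, ]
  res0 <- apply_cohort_filters(fx, as.Date("2018-09-27"))
  expect_identical(res0$report$n_retained, 1L)
  for (mod in list(list("heart_rate", 121), list("systolic_bp", 79.9),
                   list("respiration_rate", 30.5),
                   list("pulse_oximetry", 87.9), list("troponin", 0.101))) {
    fx2 <- fx
    fx2[[mod[[1]]]] <- mod[[2]]
    res <- apply_cohort_filters(fx2, as.Date("2018-09-27"))
    expect_identical(res$report$n_retained, 0L)
    expect_identical(sum(res$report$exclusions[c("vitals", "troponin")]),
                     1L)
  }
  # out-of-range acuity and cellulitis fever just over the cutoff
  fx_ac <- fx; fx_ac$acuity <- 1L
  expect_identical(apply_cohort_filters(
    fx_ac, as.Date("2018-09-27"))$report$exclusions[["acuity"]], 1L)
  fx_cf <- filter_fixture()[2, ]; fx_cf$temperature <- 100.31
  expect_identical(apply_cohort_filters(
    fx_cf, as.Date("2018-09-27"))$report$exclusions[["cellulitis_fever"]],
    1L)
})

test_that("filtering is idempotent and missing vitals never exclude", {
  fx <- gen_prep(n = 1200, seed = 13)
  d <- inject_missingness(fx$cohort$data,
                          c(heart_rate = 0.3, respiration_rate = 0.3),
                          seed = 2)
  r1 <- apply_cohort_filters(d, fx$cfg$sample_period[2])
  r2 <- apply_cohort_filters(r1$data, fx$cfg$sample_period[2])
  expect_identical(r1$report$retained_ids, r2$report$retained_ids)
  expect_identical(r2$report$n_retained, r2$report$n_input)
  expect_error(apply_cohort_filters(transform(d, visit_date = NA),
                                    fx$cfg$sample_period[2]), "visit_date")
})

test_that("windowed outcome indicators use inclusive boundaries and nest", {
  d <- data.frame(revisit_days = c(NA, 9.0, 31), readmission_days =
                    c(2.0, NA, 0.5), mortality_days = c(NA, NA, 30.0))
  ym <- derive_outcome_matrix(d)
  expect_identical(ym$y_mortality_3, c(0L, 0L, 0L))
  expect_identical(ym$y_mortality_30, c(0L, 0L, 1L))
  expect_identical(ym$y_readmission_3, c(1L, 0L, 1L))
  expect_identical(ym$y_revisit_9, c(0L, 1L, 0L))
  expect_identical(ym$y_revisit_3, c(0L, 0L, 0L))
  expect_identical(ym$y_revisit_30, c(0L, 1L, 0L))
  expect_error(derive_outcome_matrix(
    data.frame(revisit_days = -1, readmission_days = NA_real_,
               mortality_days = NA_real_)), "negative")
})

test_that("imputation fills medians and modes deterministically and never
          alters observed values", {
  d <- data.frame(age = c(1, 2, 4, NA),
                  insurance = c("medicare", "medicare", "commercial", NA),
                  female = c(0, 0, 1, NA), stringsAsFactors = FALSE)
  res <- impute_missing(d, continuous = "age",
                        categorical = c("insurance", "female"))
  expect_identical(res$data$age, c(1, 2, 4, 2))
  expect_identical(res$data$insurance[4], "medicare")
  expect_identical(res$data$female[4], 0)
  expect_identical(res$log$age$fill, 2)
  expect_identical(res$log$insurance$n_filled, 1L)

  # bimodal tie: lexicographically smallest category wins
  d2 <- data.frame(insurance = c("b", "b", "a", "a", NA),
                   stringsAsFactors = FALSE)
  expect_identical(
    impute_missing(d2, continuous = character(0),
                   categorical = "insurance")$data$insurance[5], "a")
  expect_error(impute_missing(data.frame(age = c(NA_real_, NA_real_)),
                              continuous = "age",
                              categorical = character(0)), "age")
})

test_that("standardization is an invertible affine map with exact
          two-point values", {
  d <- data.frame(age = c(2, 4))
  res <- standardize_continuous(d, "age")
  expect_equal(res$data$age, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  fx <- gen_prep(n = 500, seed = 19, with_missingness = FALSE)
  raw <- fx$cohort$data
  std <- standardize_continuous(raw)
  for (nm in std$scaling$column) {
    expect_lt(abs(mean(std$data[[nm]])), 1e-12)
    expect_lt(abs(sd(std$data[[nm]]) - 1), 1e-12)
  }
  back <- apply_scaling(std$data, std$scaling, inverse = TRUE)
  expect_equal(back$heart_rate, raw$heart_rate, tolerance = 1e-10)
  expect_error(standardize_continuous(data.frame(age = rep(3, 5)), "age"),
               "zero standard deviation")
})

test_that("design encoding uses medicare and ESI 3 as reference levels", {
  d <- data.frame(
    visit_id = c("a", "b"), presentation = c("falls", "uti"),
    age = c(0.5, -0.5), female = c(1, 0),
    insurance = c("medicare", "commercial"), diabetes = c(0, 1),
    chf = c(1, 0), hypertension = c(0, 1), hcc = c(0.2, -0.2),
    acuity = c(2L, 3L), temperature = c(0.1, -0.1),
    blood_pressure = c(0.3, -0.3), respiration_rate = c(0, 0),
    heart_rate = c(1, -1), decision = c("admit", "discharge"),
    treatment_time = c(1, 2), revisit_days = c(NA, 2),
    readmission_days = c(NA, NA), mortality_days = c(NA, NA),
    stringsAsFactors = FALSE)
  des <- encode_design(d)
  expect_identical(unname(des$baseline[1, ]),
                   c(0.5, 1, 0, 0, 0, 0, 1, 0, 0.2))
  expect_identical(unname(des$baseline[2, "ins_commercial"]), 1)
  expect_identical(unname(des$proxies[, "acuity2"]), c(1, 0))
  expect_identical(des$admitted, c(1, 0))
  expect_identical(unname(des$outcomes[, "y_revisit_3"]), c(0L, 1L))
  expect_error(encode_design(transform(d, insurance = "hmo")),
               "unknown insurance")
})
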