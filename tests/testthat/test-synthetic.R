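test_that("invalid generator configurations are rejected", {
  expect_error(validate_generator_config(
    generator_config(outcome_spec = list(
      revisit = c(b0 = 0.9, bH = 0.2, bA = 0.05, bHA = 0),
      readmission = c(b0 = 0.02, bH = 0.1, bA = 0.058, bHA = 0),
      mortality = c(b0 = 0.005, bH = 0.06, bA = 0.01, bHA = 0)))),
    "outside \\[0, 1\\]")
  expect_error(validate_generator_config(
    generator_config(threshold_spec = modifyList(
      generator_config()$threshold_spec, list(boundary_a = -1)))),
    "boundary_a")
  expect_error(validate_generator_config(
    generator_config(presentation_mix = c(falls = 0.5, weakness = 0.2,
                                          syncope = 0.1, uti = 0.1,
                                          pneumonia = 0.05,
                                          cellulitis = 0.1))),
    "sum to 1")
  expect_error(generate_cohort(generator_config(n_visits = 0)), "n_visits")
})

test_that("without a latent-admission interaction the true ATE is the
          admission coefficient exactly", {
  cfg <- generator_config(
    n_visits = 400, seed = 3,
    outcome_spec = list(revisit = c(b0 = 0.10, bH = 0.20, bA = 0.05,
                                    bHA = 0),
                        readmission = c(b0 = 0.02, bH = 0.1, bA = 0.058,
                                        bHA = 0),
                        mortality = c(b0 = 0.005, bH = 0.06, bA = 0.01,
                                      bHA = 0)))
  truth <- generate_cohort(cfg)$truth
  expect_identical(unname(truth$true_ate[["y_revisit_30"]]), 0.05)
  expect_equal(unname(truth$true_ate[["y_revisit_9"]]), 0.05 * 9 / 30)
})

test_that("cohort generation is deterministic given config and seed", {
  cfg <- generator_config(n_visits = 300, seed = 17)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$true_ate, b$truth$true_ate)
})

test_that("generated cohorts satisfy the structural invariants", {
  cfg <- generator_config(
    n_visits = 2000, seed = 5,
    disposition_spec = modifyList(generator_config()$disposition_spec,
                                  list(missing_decision_rate = 0)))
  coh <- generate_cohort(cfg)
  expect_true(all(coh$data$decision %in% c("admit", "discharge")))
  expect_true(all(coh$data$treatment_time > 0))
  ym <- derive_outcome_matrix(coh$data)
  for (fam in c("revisit", "readmission", "mortality")) {
    expect_true(all(ym[[paste0("y_", fam, "_3")]] <=
                      ym[[paste0("y_", fam, "_9")]]))
    expect_true(all(ym[[paste0("y_", fam, "_9")]] <=
                      ym[[paste0("y_", fam, "_30")]]))
  }
  expect_true(all(coh$truth$true_ate >= -1 & coh$truth$true_ate <= 1))
})

test_that("empirical admitted fraction matches the averaged closed-form
          hit probability", {
  fx <- gen_prep(n = 20000, seed = 1, with_missingness = FALSE)
  p <- upper_hit_probability(fx$cohort$truth$drifts,
                             fx$cfg$threshold_spec$boundary_a,
                             fx$cfg$threshold_spec$start_w0)
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(fx$cohort$truth$admitted_fraction - mean(p)), 3 * se)
})

test_that("severing every path from the latent state to disposition
          removes their association", {
  cfg <- generator_config(
    n_visits = 50000, seed = 9,
    proxy_spec = modifyList(generator_config()$proxy_spec, list(
      continuous = lapply(generator_config()$proxy_spec$continuous,
                          function(p) { p$lambda <- 0; p }),
      acuity = c("(Intercept)" = -1.5, latent = 0, age = 0.2, hcc = 0.2))),
    threshold_spec = modifyList(generator_config()$threshold_spec,
                                list(delta = replace(
                                  generator_config()$threshold_spec$delta,
                                  "latent", 0))))
  coh <- generate_cohort(cfg)
  ok <- !is.na(coh$data$decision)
  h <- coh$truth$latent_states[ok]
  adm <- as.numeric(coh$data$decision[ok] == "admit")
  X <- edlatent:::gen_baseline_design(coh$data[ok, ], cfg)
  # partial correlation given baseline: the latent state reaches the
  # decision only through baseline once the proxy and drift links are cut
  r <- cor(resid(lm(h ~ X)), resid(lm(adm ~ X)))
  expect_lt(abs(r), 0.02)
})

test_that("missingness injection masks at the configured rates and never
          touches the admission process", {
  fx <- gen_prep(n = 5000, seed = 21, with_missingness = FALSE)
  d0 <- fx$cohort$data
  expect_identical(inject_missingness(d0, c(temperature = 0), seed = 1),
                   d0)
  d1 <- inject_missingness(d0, c(temperature = 1), seed = 1)
  expect_true(all(is.na(d1$temperature)))
  d2 <- inject_missingness(d0, c(heart_rate = 0.2), seed = 2)
  expect_lt(abs(sum(is.na(d2$heart_rate)) - 1000),
            3 * sqrt(5000 * 0.2 * 0.8))
  expect_error(inject_missingness(d0, c(decision = 0.1)), "decision")
  expect_error(inject_missingness(d0, c(temperature = 1.4)), "\\[0, 1\\]")
})

test_that("analytic ground-truth effects agree with the forward
          Monte-Carlo oracle", {
  cfg <- generator_config(n_visits = 1000, seed = 2)
  mc <- true_ate_monte_carlo(cfg, n_mc = 40000, seed = 4)
  truth <- generate_cohort(cfg)$truth
  for (oc in c("y_revisit_30", "y_readmission_30", "y_mortality_30",
               "y_revisit_9")) {
    row <- mc[mc$outcome == oc, ]
    # population-level check: both target the same expectation
    expect_lt(abs(row$estimate - truth$true_ate[[oc]]),
              3 * row$se + 0.01)
  }

  # with an interaction, the MC oracle must match beta_A + beta_HA P(H=1)
  cfg2 <- generator_config(
    n_visits = 1000, seed = 2,
    outcome_spec = list(revisit = c(b0 = 0.1, bH = 0.1, bA = 0.05,
                                    bHA = 0.10),
                        readmission = c(b0 = 0.02, bH = 0.1, bA = 0.058,
                                        bHA = 0),
                        mortality = c(b0 = 0.005, bH = 0.06, bA = 0.01,
                                      bHA = 0)))
  mc2 <- true_ate_monte_carlo(cfg2, n_mc = 60000, seed = 5)
  big <- generate_cohort(generator_config(n_visits = 50000, seed = 8))
  p_h <- mean(big$truth$latent_states)  # large-sample P(H = 1)
  row <- mc2[mc2$outcome == "y_revisit_30", ]
  expect_lt(abs(row$estimate - (0.05 + 0.10 * p_h)), 3 * row$se + 0.005)
  expect_error(true_ate_monte_carlo(cfg, n_mc = 10), "n_mc")
})

test_that("ground-truth parameters mapped to the model scale reproduce
          regressions on the standardized data with known latent states", {
  fx <- gen_prep(n = 20000, seed = 1, with_missingness = FALSE)
  truth <- model_scale_truth(fx$cfg, fx$prep$scaling)
  des <- fx$prep$design
  h <- fx$cohort$truth$latent_states[fx$truth_idx]

  # temperature measurement model refitted with the true latent states
  lmfit <- lm(des$proxies[, "temperature"] ~ h + des$baseline)
  tr <- truth$proxies$continuous$temperature
  se <- summary(lmfit)$coefficients[, 2]
  expect_lt(abs(coef(lmfit)[["h"]] - tr$lambda), 3 * se[["h"]])
  expect_lt(abs(coef(lmfit)[[1]] - tr$alpha), 3 * se[[1]])
  expect_lt(abs(coef(lmfit)[["des$baselinehcc"]] - tr$kappa[["hcc"]]),
            3 * se[["des$baselinehcc"]])

  # latent prior refitted on the model-scale baseline
  gfit <- glm(h ~ des$baseline, family = binomial())
  gse <- summary(gfit)$coefficients[, 2]
  expect_lt(abs(coef(gfit)[[1]] - truth$eta[["(Intercept)"]]),
            3 * gse[[1]])
  expect_lt(abs(coef(gfit)[["des$baselineage"]] - truth$eta[["age"]]),
            3 * gse[["des$baselineage"]])
})

test_that("cohorts round-trip through CSV with their ground-truth sidecar", {
  cfg <- generator_config(n_visits = 120, seed = 31)
  coh <- generate_cohort(cfg)
  path <- file.path(tempdir(), "cohort_test.csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$data$treatment_time, coh$data$treatment_time)
  expect_identical(back$data$decision, coh$data$decision)
  expect_equal(back$truth$true_ate, coh$truth$true_ate)
  expect_equal(back$truth$latent_states, coh$truth$latent_states)
  unlink(c(path, paste0(path, ".truth.json")))
})
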