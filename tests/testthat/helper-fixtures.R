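# Shared fixtures: all built in code at test time.

# generate + preprocess a default-scenario cohort (cached per size/seed so
# several tests in a file can share one)
.fixture_cache <- new.env(parent = emptyenv())

gen_prep <- function(n = 1500, seed = 7, with_missingness = TRUE, ...) {
  key <- paste0("n", n, "_s", seed, "_m", with_missingness,
                if (...length()) paste0("_", rlang_hashish(list(...))))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- generator_config(n_visits = n, seed = seed, ...)
  coh <- generate_cohort(cfg)
  d <- if (with_missingness)
    inject_missingness(coh$data, cfg$missingness_rates, seed = seed + 1)
  else coh$data
  prep <- preprocess_cohort(d, cfg$sample_period[2])
  out <- list(cfg = cfg, cohort = coh, prep = prep,
              truth_idx = match(prep$design$visit_id, coh$data$visit_id))
  .fixture_cache[[key]] <- out
  out
}

rlang_hashish <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  substr(unname(tools::md5sum(f)), 1, 8)
}

# small shared EM fit on a default-scenario cohort
fit_small <- function() {
  if (!is.null(.fixture_cache$fit_small)) return(.fixture_cache$fit_small)
  fx <- gen_prep(n = 1200, seed = 42)
  fit <- fit_em(fx$prep$design,
                em_control(n_restarts = 1, max_iter = 50, rel_tol = 1e-7,
                           seed = 1, cov_method = "opg"))
  out <- list(fx = fx, fit = fit)
  .fixture_cache$fit_small <- out
  out
}

# a tiny fully hand-specified design (no generator) for enumeration oracles
toy_design <- function() {
  baseline <- cbind(age = c(0.5, -1.2), female = c(1, 0),
                    ins_medicaid = c(0, 0), ins_commercial = c(1, 0),
                    ins_selfpay = c(0, 0), diabetes = c(0, 1),
                    chf = c(0, 0), hypertension = c(1, 0),
                    hcc = c(0.3, -0.4))
  proxies <- cbind(acuity2 = c(1, 0), temperature = c(0.8, -0.3),
                   blood_pressure = c(-0.5, 1.1),
                   respiration_rate = c(0.2, -0.9),
                   heart_rate = c(1.4, 0.1))
  outcomes <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2,
                     dimnames = list(NULL, c("y_revisit_30",
                                             "y_readmission_30",
                                             "y_mortality_30")))
  outcomes <- cbind(outcomes, y_revisit_3 = c(0, 0), y_revisit_9 = c(1, 0),
                    y_readmission_3 = c(0, 0), y_readmission_9 = c(0, 1),
                    y_mortality_3 = c(1, 0), y_mortality_9 = c(1, 0))
  structure(list(baseline = baseline, proxies = proxies,
                 admitted = c(1, 0), time = c(0.8, 2.1),
                 outcomes = outcomes, presentation = c("falls", "uti"),
                 visit_id = c("T1", "T2"), n = 2L),
            class = "ed_design")
}

toy_params <- function() {
  xcols <- colnames(toy_design()$baseline)
  kappa0 <- setNames(numeric(9), xcols)
  model_params(
    eta = setNames(c(-0.4, 0.3, -0.1, 0, 0.2, 0, 0.1, 0.25, 0.05, 0.4),
                   c("(Intercept)", xcols)),
    proxies = list(
      continuous = list(
        temperature = list(alpha = -0.2, lambda = 0.9,
                           kappa = replace(kappa0, "hcc", 0.1),
                           sigma = 0.8),
        blood_pressure = list(alpha = 0.1, lambda = -0.5,
                              kappa = replace(kappa0, "age", -0.2),
                              sigma = 1.1),
        respiration_rate = list(alpha = 0, lambda = 0.6, kappa = kappa0,
                                sigma = 0.9),
        heart_rate = list(alpha = -0.1, lambda = 0.5,
                          kappa = replace(kappa0, "diabetes", 0.15),
                          sigma = 1.0)),
      acuity = setNames(c(-1.2, 1.1, 0.2, 0, 0, 0, 0, 0, 0, 0, 0.3),
                        c("(Intercept)", "latent", xcols))),
    threshold = threshold_params(
      2.2, 0.4,
      setNames(c(-0.3, 1.0, 0.1, 0, 0, 0, 0, 0, 0.1, 0, 0.1,
                 0.3, 0.1, -0.1, 0.05, 0.1),
               c("(Intercept)", "latent", xcols,
                 colnames(toy_design()$proxies)))),
    outcomes = list(
      y_revisit_30 = c(b0 = 0.2, bH = 0.05, bA = -0.06, bHA = 0.01),
      y_readmission_30 = c(b0 = 0.02, bH = 0.1, bA = 0.06, bHA = 0),
      y_mortality_30 = c(b0 = 0.01, bH = 0.05, bA = 0.01, bHA = 0.02)))
}

# independent single-visit log-likelihood: plain-R re-derivation used as the
# enumeration oracle for the vectorized implementation
oracle_row_loglik <- function(params, design, i, h,
                              outcomes = c("y_revisit_30",
                                           "y_readmission_30",
                                           "y_mortality_30")) {
  x <- design$baseline[i, ]
  w <- design$proxies[i, ]
  p_h1 <- plogis(sum(params$eta * c(1, x)))
  ll <- log(if (h == 1) p_h1 else 1 - p_h1)
  for (nm in names(params$proxies$continuous)) {
    pr <- params$proxies$continuous[[nm]]
    mu <- pr$alpha + pr$lambda * h + sum(pr$kappa[names(x)] * x)
    ll <- ll + dnorm(w[[nm]], mu, pr$sigma, log = TRUE)
  }
  ac <- params$proxies$acuity
  p_ac <- plogis(ac[["(Intercept)"]] + ac[["latent"]] * h +
                   sum(ac[names(x)] * x))
  ll <- ll + dbinom(w[["acuity2"]], 1, p_ac, log = TRUE)
  d <- params$threshold$delta
  drift <- d[["(Intercept)"]] + d[["latent"]] * h +
    sum(d[names(x)] * x) + sum(d[names(w)] * w)
  ll <- ll + fpt_density(design$time[i], drift, params$threshold$boundary_a,
                         params$threshold$start_w0,
                         if (design$admitted[i] == 1) "upper" else "lower",
                         log = TRUE)
  for (nm in outcomes) {
    b <- params$outcomes[[nm]]
    p <- min(max(b[["b0"]] + b[["bH"]] * h + b[["bA"]] * design$admitted[i] +
                   b[["bHA"]] * h * design$admitted[i], 1e-6), 1 - 1e-6)
    ll <- ll + dbinom(design$outcomes[i, nm], 1, p, log = TRUE)
  }
  unname(ll)
}

# minimal design stub for the comparator estimators
design_stub <- function(y, a, X = NULL, W = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(0, n, 1, dimnames = list(NULL, "x1"))
  if (is.null(W)) W <- matrix(0, n, 1, dimnames = list(NULL, "w1"))
  structure(list(baseline = X, proxies = W, admitted = a,
                 time = rep(1, n),
                 outcomes = matrix(y, ncol = 1,
                                   dimnames = list(NULL, "y_revisit_30")),
                 presentation = rep("falls", n),
                 visit_id = as.character(seq_len(n)), n = n),
            class = "ed_design")
}

# hand-written 8-visit fixture: two clean visits and one violation of each
# exclusion rule, with every cutoff's boundary case kept on a clean visit
filter_fixture <- function() {
  base <- data.frame(
    visit_id = sprintf("F%d", 1:8),
    presentation = c("falls", "cellulitis", "uti", "falls", "syncope",
                     "weakness", "pneumonia", "cellulitis"),
    age = 80, female = 1, insurance = "medicare", diabetes = 0, chf = 0,
    hypertension = 1, hcc = 1.2,
    acuity = c(3L, 2L, 3L, 3L, 2L, 3L, 2L, 3L),
    temperature = c(98, 100.3, 98, 98, 98, 98, 98, 101.0),
    blood_pressure = 75, respiration_rate = c(30, 18, 18, 18, 18, 18, 31,
                                              18),
    heart_rate = c(120, 80, 80, 80, 80, 121, 80, 80),
    troponin = c(0.10, NA, NA, NA, 0.11, NA, NA, NA),
    pulse_oximetry = c(88, 95, 95, 95, 95, 95, 95, 95),
    systolic_bp = c(80, 130, 130, 130, 130, 130, 79, 130),
    flag_stroke = FALSE, flag_mi = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                     FALSE, FALSE, FALSE),
    flag_femur_fracture = FALSE,
    visit_date = as.Date("2018-01-01") + c(0, 0, 0, 0, 0, 0, 0, 230),
    decision = c("admit", "discharge", "discharge", "admit", "discharge",
                 "admit", "discharge", "admit"),
    disposition_destination = c("hospital", "snf", "other", "hospital",
                                "home", "hospital", "home", "hospital"),
    treatment_time = 1.5,
    revisit_days = NA_real_, readmission_days = NA_real_,
    mortality_days = NA_real_, stringsAsFactors = FALSE)
  base
}

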