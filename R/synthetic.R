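# Synthetic ED-visit cohort generator.
#
# The generator realizes, forward, exactly the statistical structure the
# analysis model assumes: a binary latent health state drawn from a logistic
# prior on baseline characteristics; Gaussian vital-sign proxies and a
# logistic acuity proxy conditional on that state; a two-boundary Wiener
# first-passage process for the disposition decision and treatment time; and
# identity-link Bernoulli outcomes in (latent state x admission). Ground
# truth (latent states, per-visit effects, true average treatment effects)
# is recorded so downstream estimators can be tested for recovery.

ed_presentations <- c("falls", "weakness", "syncope", "uti",
                      "pneumonia", "cellulitis")
ed_baseline_cols <- c("age", "female", "ins_medicaid", "ins_commercial",
                      "ins_selfpay", "diabetes", "chf", "hypertension", "hcc")
ed_proxy_cols <- c("acuity2", "temperature", "blood_pressure",
                   "respiration_rate", "heart_rate")
ed_cont_proxy_cols <- c("temperature", "blood_pressure",
                        "respiration_rate", "heart_rate")
ed_outcome_families <- c("revisit", "readmission", "mortality")
ed_windows <- c(3, 9, 30)
ed_outcome_cols <- as.vector(outer(ed_outcome_families, ed_windows,
                                   function(f, w) paste0("y_", f, "_", w)))

#' Configuration for the synthetic ED cohort generator
#'
#' Returns the default generative scenario: marginals chosen to resemble an
#' older-adult gray-area ED population (mean age ~79, predominantly Medicare,
#' ~39% admitted), moderate latent-state effects on vitals and on the
#' admission drift, and 30-day outcome probabilities in line with observed
#' revisit/readmission/mortality rates. Any component can be overridden.
#'
#' Linear predictors in the generator (`eta`, proxy `kappa`s, the drift
#' `delta`) act on covariates standardized by the fixed locations and scales
#' in `$standardization`, so coefficients are per-SD effects; the continuous
#' proxies themselves are generated on their raw clinical scales.
#'
#' @param n_visits Number of visits to generate.
#' @param seed Integer seed used by [generate_cohort()].
#' @param ... Named components to override (e.g. `eta`, `threshold_spec`,
#'   `outcome_spec`, `missingness_rates`), merged into the defaults.
#' @return An object of class `ed_generator_config`.
#' @export
generator_config <- function(n_visits = 5000, seed = 1, ...) {
  cfg <- list(
    n_visits = as.integer(n_visits),
    seed = as.integer(seed),
    presentation_mix = c(falls = 0.44, weakness = 0.16, syncope = 0.13,
                         uti = 0.13, pneumonia = 0.08, cellulitis = 0.06),
    baseline_spec = list(
      age = list(mean = 79.2, sd = 8.9, min = 65, max = 105),
      female = 0.585,
      insurance = c(medicare = 0.919, medicaid = 0.004,
                    commercial = 0.076, selfpay = 0.001),
      diabetes = 0.207, chf = 0.115, hypertension = 0.580,
      hcc = list(shape = 1.37, scale = 1.205)),
    # fixed locations/scales for the generator's standardized covariates
    standardization = list(
      age = c(79.2, 8.9), hcc = c(1.65, 1.41),
      temperature = c(97.6, 1.4), blood_pressure = c(74.2, 13.7),
      respiration_rate = c(18.1, 3.2), heart_rate = c(78.1, 14.7)),
    eta = c("(Intercept)" = -0.8, age = 0.4, female = -0.1,
            ins_medicaid = 0.2, ins_commercial = -0.2, ins_selfpay = 0,
            diabetes = 0.3, chf = 0.5, hypertension = 0.2, hcc = 0.5),
    proxy_spec = list(
      continuous = list(
        temperature = list(alpha = 97.35, lambda = 1.0,
                           kappa = c(hcc = 0.10), sigma = 1.0),
        blood_pressure = list(alpha = 76.0, lambda = -6.0,
                              kappa = c(age = -1.5), sigma = 12.5),
        respiration_rate = list(alpha = 17.6, lambda = 2.0,
                                kappa = c(hcc = 0.30), sigma = 2.8),
        heart_rate = list(alpha = 76.0, lambda = 7.0,
                          kappa = c(diabetes = 1.0), sigma = 13.5)),
      acuity = c("(Intercept)" = -1.5, latent = 1.4, age = 0.2, hcc = 0.2)),
    # probability the recorded ESI falls outside {2, 3} (filtered later)
    acuity_outside = list(rate = 0.02, levels = c(`1` = 0.3, `4` = 0.5,
                                                  `5` = 0.2)),
    threshold_spec = list(
      boundary_a = 2.5, start_w0 = 0.35,
      delta = c("(Intercept)" = -0.55, latent = 1.3,
                age = 0.10, female = 0, ins_medicaid = 0, ins_commercial = 0,
                ins_selfpay = 0, diabetes = 0, chf = 0.15, hypertension = 0,
                hcc = 0.15,
                acuity2 = 0.40, temperature = 0.10, blood_pressure = -0.15,
                respiration_rate = 0.10, heart_rate = 0.15)),
    outcome_spec = list(
      revisit = c(b0 = 0.200, bH = 0.050, bA = -0.064, bHA = 0),
      readmission = c(b0 = 0.020, bH = 0.100, bA = 0.058, bHA = 0),
      mortality = c(b0 = 0.005, bH = 0.060, bA = 0.010, bHA = 0)),
    missingness_rates = c(temperature = 0.05, blood_pressure = 0.02,
                          respiration_rate = 0.03, heart_rate = 0.02,
                          hcc = 0.04, insurance = 0.01),
    screening_spec = list(
      troponin_observed = 0.30, troponin = c(meanlog = -3.5, sdlog = 1.0),
      pulse_oximetry = c(mean = 96.5, sd = 2.8),
      systolic_bp = c(mean = 132, sd = 22),
      flag_rates = c(stroke = 0.004, mi = 0.004, femur_fracture = 0.004)),
    disposition_spec = list(
      discharge_destination = c(home = 0.87, snf = 0.10, irf = 0.03),
      other_destination_rate = 0.02,   # AMA / eloped / transfer (excluded)
      missing_decision_rate = 0.005),
    sample_period = as.Date(c("2014-01-01", "2018-09-27")),
    censor_after_death = FALSE,
    fpt_step_factor = 1e-4)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config components: ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = "ed_generator_config")
}

outcome_cells <- function(beta) {
  c(beta[["b0"]],
    beta[["b0"]] + beta[["bH"]],
    beta[["b0"]] + beta[["bA"]],
    beta[["b0"]] + beta[["bH"]] + beta[["bA"]] + beta[["bHA"]])
}

#' Validate a generator configuration
#'
#' Checks probability ranges, positive scales, boundary validity, and that
#' every outcome specification yields probabilities inside \[0, 1\] for all
#' four (latent state, admission) combinations.
#'
#' @param config An `ed_generator_config`.
#' @return Invisibly `TRUE`; otherwise an error naming the violation.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "ed_generator_config"))
  if (config$n_visits < 1) stop("n_visits must be >= 1")
  probsum <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(what, ": probabilities outside [0, 1]")
    if (abs(sum(p) - 1) > 1e-12) stop(what, ": probabilities must sum to 1")
  }
  probsum(config$presentation_mix, "presentation_mix")
  probsum(config$baseline_spec$insurance, "insurance")
  probsum(config$disposition_spec$discharge_destination,
          "discharge_destination")
  scalars <- c(config$baseline_spec$female, config$baseline_spec$diabetes,
               config$baseline_spec$chf, config$baseline_spec$hypertension,
               config$missingness_rates, config$acuity_outside$rate,
               config$disposition_spec$other_destination_rate,
               config$disposition_spec$missing_decision_rate)
  if (any(scalars < 0 | scalars > 1))
    stop("a probability component lies outside [0, 1]")
  for (nm in names(config$proxy_spec$continuous)) {
    if (config$proxy_spec$continuous[[nm]]$sigma <= 0)
      stop("sigma for proxy ", nm, " must be > 0")
  }
  check_boundary(config$threshold_spec$boundary_a,
                 config$threshold_spec$start_w0)
  for (nm in names(config$outcome_spec)) {
    cells <- outcome_cells(config$outcome_spec[[nm]])
    if (any(cells < 0 | cells > 1))
      stop("outcome ", nm, ": probabilities outside [0, 1] for some ",
           "(latent, admission) combination")
  }
  invisible(TRUE)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# generator-scale standardized value of a continuous variable
gen_std <- function(x, config, name) {
  cs <- config$standardization[[name]]
  (x - cs[1]) / cs[2]
}

# baseline design on the generator's standardized scale, columns in
# ed_baseline_cols order
gen_baseline_design <- function(df, config) {
  cbind(age = gen_std(df$age, config, "age"),
        female = df$female,
        ins_medicaid = as.numeric(df$insurance == "medicaid"),
        ins_commercial = as.numeric(df$insurance == "commercial"),
        ins_selfpay = as.numeric(df$insurance == "selfpay"),
        diabetes = df$diabetes, chf = df$chf,
        hypertension = df$hypertension,
        hcc = gen_std(df$hcc, config, "hcc"))
}

#' Generate a synthetic ED-visit cohort with known ground truth
#'
#' Draws `config$n_visits` complete visit records from the generative model
#' described in [generator_config()] and records the ground truth needed for
#' recovery testing: the latent states, realized drifts, per-visit effects
#' of admission, and the true average treatment effect of each of the nine
#' outcome indicators. Missingness is *not* injected here; see
#' [inject_missingness()].
#'
#' Each outcome family is generated as a single 30-day Bernoulli event with
#' probability `b0 + bH*H + bA*A + bHA*H*A`; an event that occurs is given a
#' day-of-event uniform on (0, 30], so the 3- and 9-day indicators are
#' deterministic truncations and nesting holds by construction.
#'
#' @param config An [generator_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with `data` (one row per visit) and `truth`
#'   (class `ed_ground_truth`: `latent_states`, `drifts`, `ite` matrix of
#'   per-visit 30-day admission effects, and `true_ate` for all nine
#'   outcome indicators).
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_generator_config(config)
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_visits
  bs <- config$baseline_spec

  df <- data.frame(
    visit_id = sprintf("V%06d", seq_len(n)),
    presentation = sample(ed_presentations, n, replace = TRUE,
                          prob = config$presentation_mix[ed_presentations]),
    age = rtruncnorm1(n, bs$age$mean, bs$age$sd, bs$age$min, bs$age$max),
    female = rbinom(n, 1, bs$female),
    insurance = sample(names(bs$insurance), n, replace = TRUE,
                       prob = bs$insurance),
    diabetes = rbinom(n, 1, bs$diabetes),
    chf = rbinom(n, 1, bs$chf),
    hypertension = rbinom(n, 1, bs$hypertension),
    hcc = rgamma(n, shape = bs$hcc$shape, scale = bs$hcc$scale),
    stringsAsFactors = FALSE)

  xb <- gen_baseline_design(df, config)

  # latent adverse health state
  p_h <- expit_capped(config$eta[1] +
                        as.numeric(xb %*% config$eta[ed_baseline_cols]))
  h <- rbinom(n, 1, p_h)

  # continuous proxies on raw clinical scales
  for (nm in names(config$proxy_spec$continuous)) {
    ps <- config$proxy_spec$continuous[[nm]]
    mu <- ps$alpha + ps$lambda * h
    if (length(ps$kappa)) mu <- mu +
        as.numeric(xb[, names(ps$kappa), drop = FALSE] %*% ps$kappa)
    df[[nm]] <- mu + ps$sigma * rnorm(n)
  }

  # acuity: ESI 2-vs-3 from the logistic proxy model, with a small rate of
  # out-of-range levels (1, 4, 5) that cohort filtering removes
  ac <- config$proxy_spec$acuity
  lp2 <- ac[["(Intercept)"]] + ac[["latent"]] * h
  kap <- ac[setdiff(names(ac), c("(Intercept)", "latent"))]
  if (length(kap)) lp2 <- lp2 +
      as.numeric(xb[, names(kap), drop = FALSE] %*% kap)
  esi <- ifelse(rbinom(n, 1, expit_capped(lp2)) == 1, 2L, 3L)
  out_idx <- which(runif(n) < config$acuity_outside$rate)
  if (length(out_idx)) {
    lv <- config$acuity_outside$levels
    esi[out_idx] <- as.integer(sample(names(lv), length(out_idx),
                                      replace = TRUE, prob = lv))
  }
  df$acuity <- esi

  # admission process: drift linear in latent state, baseline and proxies
  ts <- config$threshold_spec
  wstd <- cbind(acuity2 = as.numeric(df$acuity == 2),
                temperature = gen_std(df$temperature, config, "temperature"),
                blood_pressure = gen_std(df$blood_pressure, config,
                                         "blood_pressure"),
                respiration_rate = gen_std(df$respiration_rate, config,
                                           "respiration_rate"),
                heart_rate = gen_std(df$heart_rate, config, "heart_rate"))
  drift <- ts$delta[["(Intercept)"]] + ts$delta[["latent"]] * h +
    as.numeric(xb %*% ts$delta[ed_baseline_cols]) +
    as.numeric(wstd %*% ts$delta[ed_proxy_cols])
  fp <- simulate_first_passage(drift, ts$boundary_a, ts$start_w0, n = n,
                               dt = config$fpt_step_factor * ts$boundary_a^2,
                               seed = sample.int(.Machine$integer.max, 1))
  admitted <- fp$admit
  df$treatment_time <- fp$time
  df$decision <- ifelse(admitted == 1, "admit", "discharge")

  dsp <- config$disposition_spec
  dest <- ifelse(admitted == 1, "hospital",
                 sample(names(dsp$discharge_destination), n, replace = TRUE,
                        prob = dsp$discharge_destination))
  oth <- runif(n) < dsp$other_destination_rate
  dest[oth] <- "other"
  df$disposition_destination <- dest
  df$decision[runif(n) < dsp$missing_decision_rate] <- NA_character_

  # screening fields used only by the cohort filters
  sc <- config$screening_spec
  df$troponin <- ifelse(runif(n) < sc$troponin_observed,
                        rlnorm_named(n, sc$troponin), NA_real_)
  df$pulse_oximetry <- pmin(rnorm(n, sc$pulse_oximetry[["mean"]],
                                  sc$pulse_oximetry[["sd"]]), 100)
  df$systolic_bp <- rnorm(n, sc$systolic_bp[["mean"]], sc$systolic_bp[["sd"]])
  df$flag_stroke <- runif(n) < sc$flag_rates[["stroke"]]
  df$flag_mi <- runif(n) < sc$flag_rates[["mi"]]
  df$flag_femur_fracture <- runif(n) < sc$flag_rates[["femur_fracture"]]
  period <- config$sample_period
  df$visit_date <- period[1] +
    floor(runif(n, 0, as.numeric(period[2] - period[1]) + 1))

  # outcomes: one 30-day Bernoulli per family, day uniform on (0, 30]
  ite <- matrix(NA_real_, n, length(ed_outcome_families),
                dimnames = list(NULL, ed_outcome_families))
  for (fam in ed_outcome_families) {
    beta <- config$outcome_spec[[fam]]
    p30 <- beta[["b0"]] + beta[["bH"]] * h + beta[["bA"]] * admitted +
      beta[["bHA"]] * h * admitted
    ev <- rbinom(n, 1, p30)
    day <- ifelse(ev == 1, runif(n, 0, 30), NA_real_)
    df[[paste0(fam, "_days")]] <- day
    ite[, fam] <- beta[["bA"]] + beta[["bHA"]] * h
  }
  if (isTRUE(config$censor_after_death)) {
    dd <- df$mortality_days
    for (fam in c("revisit", "readmission")) {
      col <- paste0(fam, "_days")
      df[[col]][!is.na(dd) & !is.na(df[[col]]) & df[[col]] > dd] <- NA_real_
    }
  }

  true_ate <- setNames(numeric(length(ed_outcome_cols)), ed_outcome_cols)
  for (fam in ed_outcome_families) for (w in ed_windows)
    true_ate[paste0("y_", fam, "_", w)] <- mean(ite[, fam]) * w / 30

  truth <- structure(list(latent_states = h, drifts = drift, ite = ite,
                          true_ate = true_ate,
                          admitted_fraction = mean(admitted)),
                     class = "ed_ground_truth")
  list(data = df, truth = truth)
}

rlnorm_named <- function(n, p) {
  exp(rnorm(n, p[["meanlog"]], p[["sdlog"]]))
}

#' Inject missingness into a generated cohort
#'
#' Masks each maskable field independently, completely at random, with its
#' configured rate. The disposition decision and treatment time are never
#' masked.
#'
#' @param data Cohort table from [generate_cohort()].
#' @param rates Named per-field probabilities in \[0, 1\]; names must be
#'   columns of `data` other than `decision` / `treatment_time`.
#' @param seed Optional seed.
#' @return A copy of `data` with masked values set to `NA`.
#' @export
inject_missingness <- function(data, rates, seed = NULL) {
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  if (any(names(rates) %in% c("decision", "treatment_time")))
    stop("decision and treatment_time cannot be masked")
  bad <- setdiff(names(rates), names(data))
  if (length(bad)) stop("unknown fields: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- data
  for (nm in names(rates)) {
    if (rates[[nm]] == 0) next
    out[[nm]][runif(nrow(out)) < rates[[nm]]] <- NA
  }
  out
}

#' Monte-Carlo oracle for the true average treatment effect
#'
#' Independent check on the analytic `true_ate`: simulates baseline
#' covariates and latent states forward, draws *both* potential outcomes for
#' every replicate, and averages their difference.
#'
#' @param config An [generator_config()] object.
#' @param n_mc Number of Monte-Carlo replicates (at least 1000).
#' @param seed Seed for the oracle stream.
#' @return A data.frame with one row per outcome indicator: `estimate` and
#'   its Monte-Carlo `se`.
#' @export
true_ate_monte_carlo <- function(config, n_mc = 1e5, seed = 1) {
  validate_generator_config(config)
  if (n_mc < 1000) stop("n_mc must be at least 1000")
  set.seed(seed)
  bs <- config$baseline_spec
  df <- data.frame(
    age = rtruncnorm1(n_mc, bs$age$mean, bs$age$sd, bs$age$min, bs$age$max),
    female = rbinom(n_mc, 1, bs$female),
    insurance = sample(names(bs$insurance), n_mc, replace = TRUE,
                       prob = bs$insurance),
    diabetes = rbinom(n_mc, 1, bs$diabetes),
    chf = rbinom(n_mc, 1, bs$chf),
    hypertension = rbinom(n_mc, 1, bs$hypertension),
    hcc = rgamma(n_mc, shape = bs$hcc$shape, scale = bs$hcc$scale))
  xb <- gen_baseline_design(df, config)
  p_h <- expit_capped(config$eta[1] +
                        as.numeric(xb %*% config$eta[ed_baseline_cols]))
  h <- rbinom(n_mc, 1, p_h)
  out <- data.frame(outcome = ed_outcome_cols, estimate = NA_real_,
                    se = NA_real_)
  for (fam in ed_outcome_families) {
    beta <- config$outcome_spec[[fam]]
    p1 <- beta[["b0"]] + beta[["bH"]] * h + beta[["bA"]] + beta[["bHA"]] * h
    p0 <- beta[["b0"]] + beta[["bH"]] * h
    y1 <- rbinom(n_mc, 1, p1)
    y0 <- rbinom(n_mc, 1, p0)
    day1 <- runif(n_mc, 0, 30)
    day0 <- runif(n_mc, 0, 30)
    for (w in ed_windows) {
      d <- y1 * (day1 <= w) - y0 * (day0 <= w)
      i <- out$outcome == paste0("y_", fam, "_", w)
      out$estimate[i] <- mean(d)
      out$se[i] <- sd(d) / sqrt(n_mc)
    }
  }
  out
}

#' Write / read a synthetic cohort as CSV with a ground-truth sidecar
#'
#' The cohort is written as plain CSV; the ground truth is written next to
#' it as JSON (`<path>.truth.json`).
#'
#' @param cohort A list with `data` and `truth` as from [generate_cohort()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$data
  df$visit_date <- as.character(df$visit_date)
  write.csv(df, path, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(latent_states = truth$latent_states, drifts = truth$drifts,
         ite = as.data.frame(truth$ite), true_ate = as.list(truth$true_ate),
         admitted_fraction = truth$admitted_fraction),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$visit_date <- as.Date(df$visit_date)
  truth_path <- paste0(path, ".truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- structure(list(latent_states = tj$latent_states,
                            drifts = tj$drifts, ite = as.matrix(tj$ite),
                            true_ate = unlist(tj$true_ate),
                            admitted_fraction = tj$admitted_fraction),
                       class = "ed_ground_truth")
  }
  list(data = df, truth = truth)
}

#' Ground-truth parameters on the fitted model's scale
#'
#' The generator draws covariates and proxies on raw clinical scales while
#' the model is fitted to sample-standardized variables. This helper maps
#' the generative coefficients onto the scale of a fitted model given the
#' scaling table actually used, so fitted parameters can be compared to
#' truth coefficient-by-coefficient.
#'
#' @param config The [generator_config()] the data came from.
#' @param scaling Scaling table from [standardize_continuous()] for the
#'   analysis sample.
#' @return An `ed_model_params` object on the fitted scale.
#' @export
model_scale_truth <- function(config, scaling) {
  sc <- function(nm) {
    i <- match(nm, scaling$column)
    if (is.na(i)) stop("no scaling entry for ", nm)
    c(m = scaling$center[i], s = scaling$scale[i])
  }
  cont_baseline <- c("age", "hcc")

  # linear predictor over generator-standardized baseline -> model scale
  conv_baseline <- function(intercept, coefs) {
    full <- setNames(numeric(length(ed_baseline_cols)), ed_baseline_cols)
    full[names(coefs)] <- coefs
    for (nm in cont_baseline) {
      cg <- config$standardization[[nm]]
      s <- sc(nm)
      intercept <- intercept + full[[nm]] * (s[["m"]] - cg[1]) / cg[2]
      full[[nm]] <- full[[nm]] * s[["s"]] / cg[2]
    }
    list(intercept = intercept, coefs = full)
  }

  cb <- conv_baseline(config$eta[["(Intercept)"]],
                      config$eta[intersect(names(config$eta),
                                           ed_baseline_cols)])
  eta <- c("(Intercept)" = unname(cb$intercept), cb$coefs)

  proxies <- list(continuous = list())
  for (nm in ed_cont_proxy_cols) {
    ps <- config$proxy_spec$continuous[[nm]]
    cb <- conv_baseline(ps$alpha, ps$kappa)
    s_y <- sc(nm)
    proxies$continuous[[nm]] <- list(
      alpha = unname((cb$intercept - s_y[["m"]]) / s_y[["s"]]),
      lambda = ps$lambda / s_y[["s"]],
      kappa = cb$coefs / s_y[["s"]],
      sigma = ps$sigma / s_y[["s"]])
  }
  ac <- config$proxy_spec$acuity
  cb <- conv_baseline(ac[["(Intercept)"]],
                      ac[intersect(names(ac), ed_baseline_cols)])
  proxies$acuity <- c("(Intercept)" = unname(cb$intercept),
                      latent = ac[["latent"]], cb$coefs)

  ts <- config$threshold_spec
  cb <- conv_baseline(ts$delta[["(Intercept)"]], ts$delta[ed_baseline_cols])
  dprox <- ts$delta[ed_proxy_cols]
  intercept <- cb$intercept
  for (nm in ed_cont_proxy_cols) {
    cg <- config$standardization[[nm]]
    s <- sc(nm)
    intercept <- intercept + dprox[[nm]] * (s[["m"]] - cg[1]) / cg[2]
    dprox[[nm]] <- dprox[[nm]] * s[["s"]] / cg[2]
  }
  delta <- c("(Intercept)" = unname(intercept), latent = ts$delta[["latent"]],
             cb$coefs, dprox)
  threshold <- threshold_params(ts$boundary_a, ts$start_w0, delta)

  outcomes <- list()
  for (fam in ed_outcome_families) {
    beta <- config$outcome_spec[[fam]]
    for (w in ed_windows)
      outcomes[[paste0("y_", fam, "_", w)]] <-
        c(b0 = unname(beta[["b0"]]) * w / 30,
          bH = unname(beta[["bH"]]) * w / 30,
          bA = unname(beta[["bA"]]) * w / 30,
          bHA = unname(beta[["bHA"]]) * w / 30)
  }
  model_params(eta, proxies, threshold, outcomes)
}
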