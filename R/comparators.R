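# Comparator estimators of the same risk differences that do not use the
# latent health state: the unadjusted contrast, inverse probability
# weighting (Hajek form), and parametric g-computation.

#' Unadjusted risk difference between admitted and discharged visits
#'
#' `rd = mean(Y | admitted) - mean(Y | discharged)` with the two-proportion
#' standard error `sqrt(p1 (1 - p1) / n1 + p0 (1 - p0) / n0)`.
#'
#' @param design An `ed_design`.
#' @param outcome Outcome column name.
#' @param level Confidence level.
#' @param population Label recorded in the estimate.
#' @return One-row `ed_effect` data.frame, `estimator = "unadjusted"`.
#' @export
unadjusted_rd <- function(design, outcome, level = 0.95,
                          population = "overall") {
  y <- design$outcomes[, outcome]
  a <- design$admitted
  n1 <- sum(a == 1); n0 <- sum(a == 0)
  if (n1 == 0 || n0 == 0) stop("both arms must be nonempty")
  p1 <- mean(y[a == 1]); p0 <- mean(y[a == 0])
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  effect_row(outcome, population, "unadjusted", design$n, p1 - p0, se, level)
}

#' Fit the admission propensity model
#'
#' Logistic regression of the admission indicator on the measured variables
#' (baseline characteristics and proxies). Scores are trimmed to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param design An `ed_design`.
#' @param covariates `"both"` (baseline + proxies, default), `"baseline"`
#'   only, or `"proxies"` only.
#' @return Object of class `ed_propensity`: `coefficients`, per-visit
#'   `scores`, `diagnostics` (min/max score, effective sample size per arm),
#'   `separation` flag.
#' @export
fit_propensity <- function(design,
                           covariates = c("both", "baseline", "proxies")) {
  covariates <- match.arg(covariates)
  Z <- propensity_design(design, covariates)
  fit <- fit_weighted_logistic(Z, design$admitted, rep(1, design$n))
  scores <- pmin(pmax(expit_capped(as.numeric(Z %*% fit$coefs)), 1e-6),
                 1 - 1e-6)
  a <- design$admitted
  w1 <- a / scores; w0 <- (1 - a) / (1 - scores)
  ess <- function(w) sum(w)^2 / sum(w^2)
  structure(list(coefficients = fit$coefs, scores = scores,
                 covariates = covariates,
                 diagnostics = list(min_score = min(scores),
                                    max_score = max(scores),
                                    ess_admit = ess(w1[a == 1]),
                                    ess_discharge = ess(w0[a == 0])),
                 separation = fit$separation),
            class = "ed_propensity")
}

propensity_design <- function(design, covariates) {
  switch(covariates,
         both = cbind("(Intercept)" = 1, design$baseline, design$proxies),
         baseline = cbind("(Intercept)" = 1, design$baseline),
         proxies = cbind("(Intercept)" = 1, design$proxies))
}

#' Inverse-probability-weighted risk difference (Hajek estimator)
#'
#' Normalized weighted contrast
#' `sum(w1 y)/sum(w1) - sum(w0 y)/sum(w0)` with `w1 = A/score`,
#' `w0 = (1 - A)/(1 - score)`. The standard error is a seeded nonparametric
#' bootstrap over the whole procedure, including the propensity refit.
#'
#' @inheritParams unadjusted_rd
#' @param propensity Optional [fit_propensity()] result on the same rows.
#' @param covariates Passed to [fit_propensity()] when refitting.
#' @param boot_B Bootstrap resamples for the standard error (0 skips it).
#' @param seed Bootstrap seed.
#' @return One-row `ed_effect` data.frame, `estimator = "ipw"`.
#' @export
ipw_rd <- function(design, outcome, propensity = NULL,
                   covariates = "both", boot_B = 500, seed = 1,
                   level = 0.95, population = "overall") {
  if (is.null(propensity)) propensity <- fit_propensity(design, covariates)
  if (min(propensity$diagnostics$ess_admit,
          propensity$diagnostics$ess_discharge) < 30)
    warning("effective sample size below 30 in one arm")
  rd <- ipw_point(design, outcome, propensity$scores)
  se <- NA_real_
  if (boot_B > 0) {
    est_fun <- function(d) ipw_point(d, outcome,
                                     fit_propensity(d, covariates)$scores)
    se <- bootstrap_se(design, est_fun, boot_B, seed)
  }
  effect_row(outcome, population, "ipw", design$n, rd, se, level)
}

ipw_point <- function(design, outcome, scores) {
  y <- design$outcomes[, outcome]
  a <- design$admitted
  w1 <- a / scores
  w0 <- (1 - a) / (1 - scores)
  sum(w1 * y) / sum(w1) - sum(w0 * y) / sum(w0)
}

#' Parametric g-computation (outcome-model standardization)
#'
#' Fits a logistic outcome model on admission plus the measured variables,
#' predicts every visit's outcome with admission forced to 1 and to 0, and
#' averages the difference over the empirical covariate distribution.
#'
#' @inheritParams ipw_rd
#' @return One-row `ed_effect` data.frame, `estimator = "gcomp"`.
#' @export
g_computation_rd <- function(design, outcome, covariates = "both",
                             boot_B = 500, seed = 1, level = 0.95,
                             population = "overall") {
  rd <- gcomp_point(design, outcome, covariates)
  se <- NA_real_
  if (boot_B > 0)
    se <- bootstrap_se(design,
                       function(d) gcomp_point(d, outcome, covariates),
                       boot_B, seed)
  effect_row(outcome, population, "gcomp", design$n, rd, se, level)
}

gcomp_point <- function(design, outcome, covariates = "both") {
  Zx <- propensity_design(design, covariates)
  Z <- cbind(admitted = design$admitted, Zx)
  fit <- fit_weighted_logistic(Z, design$outcomes[, outcome],
                               rep(1, design$n))
  lp_x <- as.numeric(Zx %*% fit$coefs[-1])
  mean(expit_capped(fit$coefs[1] + lp_x) - expit_capped(lp_x))
}

bootstrap_se <- function(design, est_fun, B, seed) {
  set.seed(seed)
  n <- design$n
  est <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(est_fun(subset_design(design, idx)), error = function(e)
      NA_real_)
  }, numeric(1))
  sd(est, na.rm = TRUE)
}
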