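# Counterfactual effect estimation from a fitted latent-variable model:
# per-visit potential-outcome predictions, overall and subgroup average
# treatment effects (risk differences) with Wald intervals.

#' Wald confidence interval and 2-tailed test
#'
#' @param estimate Point estimate.
#' @param se Positive standard error.
#' @param level Confidence level in (0, 1).
#' @return List with `low`, `high`, `p_value`.
#' @export
wald_interval <- function(estimate, se, level = 0.95) {
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- qnorm((1 + level) / 2)
  list(low = estimate - z * se, high = estimate + z * se,
       p_value = 2 * pnorm(-abs(estimate) / se))
}

#' Predicted potential outcome probability under forced admission status
#'
#' Integrates the clamped identity-link outcome mean over each visit's
#' posterior latent-state distribution:
#' `gamma * p(h = 1, a) + (1 - gamma) * p(h = 0, a)`. Setting
#' `use_prior = TRUE` replaces the posterior by the latent prior (a
#' sensitivity option).
#'
#' @param params An `ed_model_params`.
#' @param gamma Posterior weights (final E-step), one per visit.
#' @param a Forced admission status, 0 or 1.
#' @param outcome Outcome column name.
#' @return Vector of predicted probabilities.
#' @export
predict_potential_outcome <- function(params, gamma, a, outcome) {
  beta <- params$outcomes[[outcome]]
  if (is.null(beta)) stop("unknown outcome: ", outcome)
  gamma * outcome_cell_prob(beta, 1, a) +
    (1 - gamma) * outcome_cell_prob(beta, 0, a)
}

# risk difference as a function of the packed parameter vector: recompute
# the posterior, re-estimate the outcome cells for indicators outside the
# likelihood, and average the per-visit counterfactual contrast
rd_from_theta <- function(theta, fit, design, outcome, subset = NULL) {
  params <- params_unpack(theta, fit$params, fit$likelihood_outcomes)
  gamma <- e_step(params, design, fit$likelihood_outcomes)
  if (!outcome %in% fit$likelihood_outcomes) {
    params <- refresh_derived_outcome(params, design, gamma, outcome)
  }
  g <- if (is.null(subset)) gamma else gamma[subset]
  mean(predict_potential_outcome(params, g, 1, outcome) -
         predict_potential_outcome(params, g, 0, outcome))
}

# weighted cell-mean estimate of an outcome model given responsibilities
refresh_derived_outcome <- function(params, design, gamma, outcome) {
  y <- design$outcomes[, outcome]
  A <- design$admitted
  cells <- matrix(NA_real_, 2, 2)
  for (hh in 0:1) for (aa in 0:1) {
    wh <- if (hh == 1) gamma else 1 - gamma
    sel <- A == aa
    denom <- sum(wh[sel])
    cells[hh + 1, aa + 1] <- if (denom > 0)
      clamp_prob(sum(wh[sel] * y[sel]) / denom) else clamp_prob(mean(y))
  }
  params$outcomes[[outcome]] <- c(
    b0 = cells[1, 1], bH = cells[2, 1] - cells[1, 1],
    bA = cells[1, 2] - cells[1, 1],
    bHA = cells[2, 2] - cells[2, 1] - cells[1, 2] + cells[1, 1])
  params
}

effect_row <- function(outcome, population, estimator, n, rd, se, level) {
  if (is.finite(se) && se > 0) {
    wi <- wald_interval(rd, se, level)
  } else {
    wi <- list(low = NA_real_, high = NA_real_, p_value = NA_real_)
  }
  parts <- strsplit(outcome, "_")[[1]]
  structure(data.frame(
    population = population, outcome = outcome,
    family = parts[2], window = as.integer(parts[3]),
    estimator = estimator, n = n, rd = rd, se = se,
    ci_low = wi$low, ci_high = wi$high, p_value = wi$p_value,
    stringsAsFactors = FALSE), class = c("ed_effect", "data.frame"))
}

#' Average treatment effect of admission from a fitted model
#'
#' The risk difference is the mean over visits of the difference between
#' the predicted outcome under forced admission and forced discharge, each
#' integrated over the visit's posterior latent-state weight. The standard
#' error propagates the parameter covariance through a central-difference
#' gradient (delta method).
#'
#' @param fit An `ed_fit` from [fit_em()].
#' @param design The `ed_design` the model was fitted to.
#' @param outcome Outcome column name (any of the nine indicators).
#' @param level Confidence level.
#' @param population Label recorded in the estimate.
#' @param se_method `"delta"` (default) or `"none"`.
#' @return A one-row `ed_effect` data.frame: `rd`, `se`, Wald `ci_low`,
#'   `ci_high`, `p_value`, `n`, `estimator = "latent"`.
#' @export
estimate_ate <- function(fit, design, outcome, level = 0.95,
                         population = "overall",
                         se_method = c("delta", "none")) {
  se_method <- match.arg(se_method)
  est <- estimate_rd_core(fit, design, outcome, subset = NULL, se_method)
  effect_row(outcome, population, "latent", design$n, est$rd, est$se, level)
}

estimate_rd_core <- function(fit, design, outcome, subset, se_method) {
  theta <- params_pack(fit$params, fit$likelihood_outcomes)
  rd <- rd_from_theta(theta, fit, design, outcome, subset)
  se <- NA_real_
  if (se_method == "delta") {
    if (is.null(fit$covariance))
      stop("fit has no covariance; refit with cov_method != 'none'")
    grad <- numeric(length(theta))
    for (j in seq_along(theta)) {
      hstep <- 1e-5 * (1 + abs(theta[j]))
      tp <- theta; tp[j] <- theta[j] + hstep
      tm <- theta; tm[j] <- theta[j] - hstep
      grad[j] <- (rd_from_theta(tp, fit, design, outcome, subset) -
                    rd_from_theta(tm, fit, design, outcome, subset)) /
        (2 * hstep)
    }
    v <- as.numeric(t(grad) %*% fit$covariance %*% grad)
    se <- sqrt(max(v, 0))
  }
  list(rd = rd, se = se)
}

#' Subgroup average treatment effect
#'
#' As [estimate_ate()], averaging the per-visit counterfactual contrast
#' over the visits selected by `subset` only.
#'
#' @inheritParams estimate_ate
#' @param subset Logical vector over visits (or a predicate function of the
#'   design returning one).
#' @param label Population label for the estimate.
#' @param floor Minimum subgroup size below which a warning is issued.
#' @return A one-row `ed_effect` data.frame.
#' @export
estimate_subgroup_ate <- function(fit, design, outcome, subset,
                                  label = "subgroup", level = 0.95,
                                  floor = 30,
                                  se_method = c("delta", "none")) {
  se_method <- match.arg(se_method)
  if (is.function(subset)) subset <- subset(design)
  subset <- as.logical(subset)
  n_sub <- sum(subset)
  if (n_sub == 0) stop("empty subgroup: ", label)
  if (n_sub < floor)
    warning("subgroup ", label, " has only ", n_sub, " visits")
  est <- estimate_rd_core(fit, design, outcome, subset, se_method)
  effect_row(outcome, label, "latent", n_sub, est$rd, est$se, level)
}

#' Standard subgroup axes
#'
#' The subgroup predicates used in reporting: age at or below versus above
#' the sample mean, sex, Medicare versus other insurance, diabetes,
#' congestive heart failure, hypertension, and HCC score at or below versus
#' above the sample mean. Continuous covariates are standardized in the
#' design, so "sample mean" is zero on the model scale.
#'
#' @param design An `ed_design`.
#' @return Named list of logical vectors.
#' @export
default_subgroups <- function(design) {
  X <- design$baseline
  medicare <- X[, "ins_medicaid"] + X[, "ins_commercial"] +
    X[, "ins_selfpay"] == 0
  list(
    "age<=mean" = X[, "age"] <= 0, "age>mean" = X[, "age"] > 0,
    "male" = X[, "female"] == 0, "female" = X[, "female"] == 1,
    "medicare" = medicare, "other insurance" = !medicare,
    "no diabetes" = X[, "diabetes"] == 0, "diabetes" = X[, "diabetes"] == 1,
    "no chf" = X[, "chf"] == 0, "chf" = X[, "chf"] == 1,
    "no hypertension" = X[, "hypertension"] == 0,
    "hypertension" = X[, "hypertension"] == 1,
    "hcc<=mean" = X[, "hcc"] <= 0, "hcc>mean" = X[, "hcc"] > 0)
}
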