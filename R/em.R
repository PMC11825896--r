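# Joint latent-variable model and its expectation-maximization fit.
#
# Components: a logistic prior for the binary latent health state given
# baseline characteristics; Gaussian measurement models for the continuous
# vital-sign proxies and a logistic model for the acuity indicator, each
# conditional on the latent state and baseline; the Wiener first-passage
# likelihood for (decision, treatment time); and identity-link Bernoulli
# models for the outcome indicators in (latent state x admission).

OUTCOME_EPS <- 1e-6
ed_primary_outcomes <- c("y_revisit_30", "y_readmission_30", "y_mortality_30")

#' Construct a full model parameter set
#'
#' @param eta Named logistic coefficients of the latent-state prior
#'   (`(Intercept)` plus the nine encoded baseline columns).
#' @param proxies List with `continuous` (per proxy: `alpha`, `lambda`,
#'   `kappa` over baseline columns, `sigma > 0`) and `acuity` (logistic
#'   coefficients: `(Intercept)`, `latent`, baseline columns).
#' @param threshold A [threshold_params] object whose `delta` is ordered
#'   `(Intercept)`, `latent`, baseline columns, proxy columns.
#' @param outcomes Named list, per outcome indicator, of identity-link
#'   coefficients `c(b0, bH, bA, bHA)`.
#' @return Object of class `ed_model_params`.
#' @export
model_params <- function(eta, proxies, threshold, outcomes) {
  for (nm in names(proxies$continuous))
    if (proxies$continuous[[nm]]$sigma <= 0)
      stop("sigma for proxy ", nm, " must be > 0")
  stopifnot(inherits(threshold, "threshold_params"))
  structure(list(eta = eta, proxies = proxies, threshold = threshold,
                 outcomes = outcomes),
            class = "ed_model_params")
}

#' Latent-state prior probability
#'
#' `P(H = 1 | baseline) = expit(eta . [1, baseline])`, with the linear
#' predictor capped at +/- 30.
#'
#' @param eta Named coefficient vector (intercept first).
#' @param baseline Numeric vector or matrix of encoded baseline covariates.
#' @return Prior probability vector.
#' @export
latent_prior <- function(eta, baseline) {
  x <- if (is.matrix(baseline)) baseline else matrix(baseline, nrow = 1)
  expit_capped(eta[1] + as.numeric(x %*% eta[-1]))
}

clamp_prob <- function(p, eps = OUTCOME_EPS) pmin(pmax(p, eps), 1 - eps)

outcome_cell_prob <- function(beta, h, a) {
  unname(clamp_prob(beta[1] + beta[2] * h + beta[3] * a + beta[4] * h * a))
}

#' Per-visit complete-data log-likelihood at a fixed latent state
#'
#' Sums, for each visit, the log prior of the latent state, the Gaussian
#' log-densities of the continuous proxies, the Bernoulli log-likelihood of
#' the acuity indicator, the first-passage log-likelihood of the
#' (decision, time) pair, and the Bernoulli log-likelihoods of the included
#' outcome indicators under the clamped identity link.
#'
#' @param params An `ed_model_params` object.
#' @param design An `ed_design` object (see [encode_design()]).
#' @param h Latent state, 0 or 1 (scalar).
#' @param outcomes Character vector of outcome columns included in the
#'   likelihood (default: the three 30-day indicators).
#' @return Numeric vector, one value per visit.
#' @export
component_loglik <- function(params, design, h,
                             outcomes = ed_primary_outcomes) {
  stopifnot(h %in% c(0, 1))
  X <- design$baseline
  lp_prior <- pmin(pmax(params$eta[1] +
                          as.numeric(X %*% params$eta[-1]), -30), 30)
  ll <- if (h == 1) plogis(lp_prior, log.p = TRUE) else
    plogis(-lp_prior, log.p = TRUE)

  for (nm in names(params$proxies$continuous)) {
    pr <- params$proxies$continuous[[nm]]
    mu <- pr$alpha + pr$lambda * h +
      as.numeric(X %*% pr$kappa[colnames(X)])
    ll <- ll + dnorm(design$proxies[, nm], mu, pr$sigma, log = TRUE)
  }

  ac <- params$proxies$acuity
  lp_ac <- pmin(pmax(ac[["(Intercept)"]] + ac[["latent"]] * h +
                       as.numeric(X %*% ac[colnames(X)]), -30), 30)
  y_ac <- design$proxies[, "acuity2"]
  ll <- ll + y_ac * plogis(lp_ac, log.p = TRUE) +
    (1 - y_ac) * plogis(-lp_ac, log.p = TRUE)

  th <- params$threshold
  d <- th$delta
  drift <- d[["(Intercept)"]] + d[["latent"]] * h +
    as.numeric(X %*% d[colnames(X)]) +
    as.numeric(design$proxies %*% d[colnames(design$proxies)])
  ll <- ll + wfpt_logdens(design$time, drift, th$boundary_a, th$start_w0,
                          design$admitted == 1)

  for (nm in outcomes) {
    beta <- params$outcomes[[nm]]
    p <- outcome_cell_prob(beta, h, design$admitted)
    y <- design$outcomes[, nm]
    ll <- ll + y * log(p) + (1 - y) * log1p(-p)
  }
  ll
}

#' Posterior probability of the adverse latent state (E-step)
#'
#' @inheritParams component_loglik
#' @return Vector `gamma` of per-visit posterior probabilities
#'   `P(H = 1 | data)`, computed in the log domain.
#' @export
e_step <- function(params, design, outcomes = ed_primary_outcomes) {
  ll0 <- component_loglik(params, design, 0, outcomes)
  ll1 <- component_loglik(params, design, 1, outcomes)
  exp(ll1 - logsumexp2(ll0, ll1))
}

#' Observed-data log-likelihood
#'
#' Sum over visits of `log(exp(ll_0) + exp(ll_1))`, evaluated stably in the
#' log domain.
#'
#' @inheritParams component_loglik
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(params, design, outcomes = ed_primary_outcomes) {
  sum(visit_loglik(params, design, outcomes))
}

visit_loglik <- function(params, design, outcomes = ed_primary_outcomes) {
  logsumexp2(component_loglik(params, design, 0, outcomes),
             component_loglik(params, design, 1, outcomes))
}

# ---- M-step -----------------------------------------------------------

# expected Bernoulli log-likelihood of a logistic component, used to
# safeguard the EM ascent when an inner IRLS fit misbehaves
logistic_q <- function(coefs, Z, y, w) {
  lp <- pmin(pmax(as.numeric(Z %*% coefs), -30), 30)
  sum(w * (y * plogis(lp, log.p = TRUE) + (1 - y) * plogis(-lp, log.p = TRUE)))
}

fit_weighted_logistic <- function(Z, y, w, start = NULL) {
  fit <- suppressWarnings(glm.fit(Z, y, weights = w,
                                  family = quasibinomial(),
                                  start = start))
  coefs <- fit$coefficients
  coefs[!is.finite(coefs)] <- 0
  lp <- as.numeric(Z %*% coefs)
  list(coefs = coefs, separation = any(abs(lp) > 30))
}

threshold_objective <- function(par, Z, t2, up2, w2) {
  a <- exp(par[1]); w0 <- plogis(par[2])
  drift <- as.numeric(Z %*% par[-(1:2)])
  -sum(w2 * wfpt_logdens(t2, drift, a, w0, up2))
}

threshold_gradient <- function(par, Z, t2, up2, w2) {
  a <- exp(par[1]); w0 <- plogis(par[2])
  z <- w0 * a
  drift <- as.numeric(Z %*% par[-(1:2)])
  # d(-log f)/d drift is closed-form: the series factor does not involve it
  gv <- ifelse(up2, -(a - z) + drift * t2, z + drift * t2)
  g_delta <- as.numeric(t(Z) %*% (w2 * gv))
  # boundary and start point: central differences on the transformed scale
  g_aw <- numeric(2)
  for (j in 1:2) {
    hstep <- 1e-5 * (1 + abs(par[j]))
    pp <- par; pp[j] <- par[j] + hstep
    pm <- par; pm[j] <- par[j] - hstep
    g_aw[j] <- (threshold_objective(pp, Z, t2, up2, w2) -
                  threshold_objective(pm, Z, t2, up2, w2)) / (2 * hstep)
  }
  c(g_aw, g_delta)
}

#' One M-step: maximize each component against posterior-weighted data
#'
#' Every visit contributes with weight `gamma_i` as latent state 1 and
#' `1 - gamma_i` as latent state 0. The latent prior and the acuity proxy
#' are refitted by weighted logistic regression; continuous proxies by
#' weighted least squares with a weighted residual SD; the threshold
#' component by quasi-Newton maximization warm-started at the previous
#' values; the outcome components by weighted cell means in
#' (latent state x admission), clamped to the valid probability range (the
#' exact constrained maximizer under the identity link). Any component whose
#' refit would lower its expected log-likelihood is kept at its previous
#' value and flagged.
#'
#' @param design An `ed_design`.
#' @param gamma Posterior weights from [e_step()].
#' @param prev Previous `ed_model_params` (warm starts and fallbacks).
#' @param outcomes Outcome columns included in the likelihood.
#' @param inner_maxit Iteration cap for the threshold quasi-Newton step.
#' @return Updated `ed_model_params` with a `flags` attribute.
#' @export
m_step <- function(design, gamma, prev, outcomes = ed_primary_outcomes,
                   inner_maxit = 25) {
  X <- design$baseline
  n <- design$n
  flags <- character(0)
  Z1 <- cbind("(Intercept)" = 1, X)

  # latent prior
  eta_fit <- fit_weighted_logistic(Z1, gamma, rep(1, n), start = prev$eta)
  eta <- eta_fit$coefs
  if (eta_fit$separation) flags <- c(flags, "eta_separation")
  if (logistic_q(eta, Z1, gamma, rep(1, n)) <
      logistic_q(prev$eta, Z1, gamma, rep(1, n))) {
    eta <- prev$eta; flags <- c(flags, "eta_kept_previous")
  }
  names(eta) <- colnames(Z1)

  # stacked fractional representation: each visit once per latent state
  h2 <- c(rep(0, n), rep(1, n))
  w2 <- c(1 - gamma, gamma)
  Z2 <- cbind("(Intercept)" = 1, latent = h2, rbind(X, X))

  proxies <- prev$proxies
  for (nm in names(prev$proxies$continuous)) {
    y2 <- rep(design$proxies[, nm], 2)
    wls <- lm.wfit(Z2, y2, w2)
    cf <- wls$coefficients
    cf[is.na(cf)] <- 0
    sig <- sqrt(max(sum(w2 * wls$residuals^2) / sum(w2), 1e-12))
    proxies$continuous[[nm]] <- list(
      alpha = cf[["(Intercept)"]], lambda = cf[["latent"]],
      kappa = cf[colnames(X)], sigma = sig)
  }

  y_ac2 <- rep(design$proxies[, "acuity2"], 2)
  ac_fit <- fit_weighted_logistic(Z2, y_ac2, w2, start = prev$proxies$acuity)
  ac <- ac_fit$coefs
  if (ac_fit$separation) flags <- c(flags, "acuity_separation")
  if (logistic_q(ac, Z2, y_ac2, w2) <
      logistic_q(prev$proxies$acuity, Z2, y_ac2, w2)) {
    ac <- prev$proxies$acuity; flags <- c(flags, "acuity_kept_previous")
  }
  names(ac) <- colnames(Z2)
  proxies$acuity <- ac

  # threshold component (warm start, transformed to an unconstrained scale)
  th <- prev$threshold
  Zt <- cbind(Z2, rbind(design$proxies, design$proxies))
  t2 <- rep(design$time, 2)
  up2 <- rep(design$admitted == 1, 2)
  par0 <- c(log(th$boundary_a), qlogis(th$start_w0), th$delta)
  opt <- tryCatch(
    optim(par0, threshold_objective, threshold_gradient, Z = Zt, t2 = t2,
          up2 = up2, w2 = w2, method = "BFGS",
          control = list(maxit = inner_maxit)),
    error = function(e) NULL)
  if (is.null(opt) ||
      opt$value > threshold_objective(par0, Zt, t2, up2, w2) + 1e-10) {
    flags <- c(flags, "threshold_kept_previous")
    threshold <- th
  } else {
    delta <- opt$par[-(1:2)]
    names(delta) <- colnames(Zt)
    threshold <- threshold_params(exp(opt$par[1]), plogis(opt$par[2]), delta)
  }

  # outcome components: exact weighted cell means per (latent, admission)
  A <- design$admitted
  out_params <- prev$outcomes
  for (nm in colnames(design$outcomes)) {
    y <- design$outcomes[, nm]
    cells <- matrix(NA_real_, 2, 2)  # [h + 1, a + 1]
    for (hh in 0:1) for (aa in 0:1) {
      wh <- if (hh == 1) gamma else 1 - gamma
      sel <- A == aa
      denom <- sum(wh[sel])
      cells[hh + 1, aa + 1] <- if (denom > 0)
        clamp_prob(sum(wh[sel] * y[sel]) / denom) else clamp_prob(mean(y))
    }
    out_params[[nm]] <- c(
      b0 = cells[1, 1], bH = cells[2, 1] - cells[1, 1],
      bA = cells[1, 2] - cells[1, 1],
      bHA = cells[2, 2] - cells[2, 1] - cells[1, 2] + cells[1, 1])
  }

  res <- model_params(eta, proxies, threshold, out_params)
  attr(res, "flags") <- flags
  res
}

# ---- initialization, canonicalization ---------------------------------

# starting responsibilities from a split along the first principal
# component of the continuous proxies, oriented toward higher temperature
initial_gamma <- function(design, perturb_sd = 0) {
  W <- design$proxies[, ed_cont_proxy_cols, drop = FALSE]
  pc <- prcomp(W, scale. = TRUE)
  s <- pc$x[, 1]
  if (cor(s, W[, 1]) < 0) s <- -s
  lp <- 1.5 * s / max(sd(s), 1e-12)
  if (perturb_sd > 0) lp <- lp + rnorm(length(lp), 0, perturb_sd)
  plogis(lp)
}

initial_params <- function(design) {
  X <- design$baseline
  pbar <- mean(design$admitted)
  w0 <- min(max(pbar, 0.05), 0.95)
  a <- sqrt(max(mean(design$time), 1e-3) / (w0 * (1 - w0)))
  delta <- setNames(numeric(2 + ncol(X) + ncol(design$proxies)),
                    c("(Intercept)", "latent", colnames(X),
                      colnames(design$proxies)))
  proxies <- list(continuous = list(), acuity = setNames(
    numeric(2 + ncol(X)), c("(Intercept)", "latent", colnames(X))))
  for (nm in ed_cont_proxy_cols)
    proxies$continuous[[nm]] <- list(
      alpha = mean(design$proxies[, nm]), lambda = 0,
      kappa = setNames(numeric(ncol(X)), colnames(X)),
      sigma = max(sd(design$proxies[, nm]), 1e-6))
  outcomes <- lapply(seq_len(ncol(design$outcomes)), function(j)
    c(b0 = clamp_prob(mean(design$outcomes[, j])), bH = 0, bA = 0, bHA = 0))
  names(outcomes) <- colnames(design$outcomes)
  model_params(eta = setNames(numeric(1 + ncol(X)),
                              c("(Intercept)", colnames(X))),
               proxies = proxies,
               threshold = threshold_params(a, w0, delta),
               outcomes = outcomes)
}

# resolve the mixture label-swap ambiguity: the adverse state is oriented
# so that the latent effect on the first continuous proxy is >= 0
canonicalize_params <- function(params) {
  first <- ed_cont_proxy_cols[1]
  if (params$proxies$continuous[[first]]$lambda >= 0)
    return(list(params = params, flipped = FALSE))
  p <- params
  p$eta <- -params$eta
  for (nm in names(params$proxies$continuous)) {
    pr <- params$proxies$continuous[[nm]]
    p$proxies$continuous[[nm]]$alpha <- pr$alpha + pr$lambda
    p$proxies$continuous[[nm]]$lambda <- -pr$lambda
  }
  ac <- params$proxies$acuity
  ac[["(Intercept)"]] <- ac[["(Intercept)"]] + ac[["latent"]]
  ac[["latent"]] <- -ac[["latent"]]
  p$proxies$acuity <- ac
  d <- params$threshold$delta
  d[["(Intercept)"]] <- d[["(Intercept)"]] + d[["latent"]]
  d[["latent"]] <- -d[["latent"]]
  p$threshold$delta <- d
  for (nm in names(params$outcomes)) {
    b <- params$outcomes[[nm]]
    p$outcomes[[nm]] <- c(b0 = b[["b0"]] + b[["bH"]], bH = -b[["bH"]],
                          bA = b[["bA"]] + b[["bHA"]], bHA = -b[["bHA"]])
  }
  list(params = p, flipped = TRUE)
}

#' EM fitting control settings
#'
#' @param n_restarts Number of EM chains from perturbed initializations.
#' @param max_iter Maximum EM iterations per chain.
#' @param rel_tol Convergence tolerance on the relative change of the
#'   observed-data log-likelihood.
#' @param seed Seed governing restarts and initialization noise.
#' @param likelihood_outcomes Outcome indicators entering the joint
#'   likelihood (the remaining indicators are estimated from the final
#'   posterior weights).
#' @param cov_method `"opg"` (outer product of per-visit scores, default),
#'   `"hessian"` (numerically differentiated observed-information), or
#'   `"none"`.
#' @return List of class `em_control`.
#' @export
em_control <- function(n_restarts = 10, max_iter = 500, rel_tol = 1e-8,
                       seed = 1, likelihood_outcomes = ed_primary_outcomes,
                       cov_method = c("opg", "hessian", "none")) {
  structure(list(n_restarts = n_restarts, max_iter = max_iter,
                 rel_tol = rel_tol, seed = seed,
                 likelihood_outcomes = likelihood_outcomes,
                 cov_method = match.arg(cov_method)),
            class = "em_control")
}

#' Fit the latent-variable model by expectation-maximization
#'
#' Runs `n_restarts` EM chains (the first from a deterministic principal
#' component split of the continuous proxies, the rest from perturbed
#' responsibilities), keeps the chain with the highest observed-data
#' log-likelihood, resolves the label-swap ambiguity so the latent effect
#' on the first continuous proxy is nonnegative, and estimates a parameter
#' covariance.
#'
#' @param design An `ed_design` from [encode_design()].
#' @param control An [em_control()] list.
#' @return Object of class `ed_fit`: `params`, final posterior `gamma`,
#'   `loglik`, `loglik_trace`, `converged`, `n_iterations`, `covariance`
#'   (with packed parameter names), `best_of_restarts`, `flags`.
#' @export
fit_em <- function(design, control = em_control()) {
  set.seed(control$seed)
  outcomes <- control$likelihood_outcomes
  best <- NULL
  traces <- list()
  for (r in seq_len(control$n_restarts)) {
    gamma <- initial_gamma(design, perturb_sd = if (r == 1) 0 else 0.75)
    params <- m_step(design, gamma, initial_params(design), outcomes)
    trace <- numeric(0)
    converged <- FALSE
    flags <- character(0)
    ll_prev <- -Inf
    for (it in seq_len(control$max_iter)) {
      gamma <- e_step(params, design, outcomes)
      params <- m_step(design, gamma, params, outcomes)
      flags <- union(flags, attr(params, "flags"))
      ll <- observed_loglik(params, design, outcomes)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < control$rel_tol * (abs(ll) + 1)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    traces[[r]] <- trace
    cand <- list(params = params, loglik = trace[length(trace)],
                 converged = converged, n_iterations = length(trace),
                 restart = r, flags = flags)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (is.null(best)) stop("all EM restarts failed")

  canon <- canonicalize_params(best$params)
  params <- canon$params
  gamma <- e_step(params, design, outcomes)

  cov <- NULL
  if (control$cov_method != "none")
    cov <- em_covariance(params, design, outcomes, control$cov_method)

  structure(list(params = params, gamma = gamma, loglik = best$loglik,
                 loglik_trace = traces[[best$restart]],
                 all_traces = traces, converged = best$converged,
                 n_iterations = best$n_iterations,
                 covariance = cov$covariance, cov_flags = cov$flags,
                 best_of_restarts = best$restart,
                 likelihood_outcomes = outcomes,
                 n = design$n, flags = best$flags,
                 label_flipped = canon$flipped),
            class = "ed_fit")
}

#' @export
print.ed_fit <- function(x, ...) {
  cat("Latent-variable disposition model fit\n")
  cat("  n =", x$n, " log-likelihood =", format(x$loglik), "\n")
  cat("  converged:", x$converged, "after", x$n_iterations,
      "iterations (best of restarts:", x$best_of_restarts, ")\n")
  ate <- vapply(x$likelihood_outcomes, function(nm) {
    b <- x$params$outcomes[[nm]]
    b[["bA"]] + b[["bHA"]] * mean(x$gamma)
  }, numeric(1))
  cat("  posterior mean of adverse state:", round(mean(x$gamma), 3), "\n")
  cat("  risk differences (admit - discharge):\n")
  for (nm in names(ate)) cat(sprintf("    %-18s %+0.4f\n", nm, ate[[nm]]))
  invisible(x)
}

# ---- parameter packing and covariance ---------------------------------

params_pack <- function(params, outcomes = ed_primary_outcomes) {
  v <- c(setNames(params$eta, paste0("eta.", names(params$eta))))
  for (nm in names(params$proxies$continuous)) {
    pr <- params$proxies$continuous[[nm]]
    v <- c(v,
           setNames(c(pr$alpha, pr$lambda),
                    paste0("proxy.", nm, c(".alpha", ".lambda"))),
           setNames(pr$kappa, paste0("proxy.", nm, ".kappa.",
                                     names(pr$kappa))),
           setNames(pr$sigma, paste0("proxy.", nm, ".sigma")))
  }
  v <- c(v, setNames(params$proxies$acuity,
                     paste0("acuity.", names(params$proxies$acuity))))
  th <- params$threshold
  v <- c(v, threshold.boundary_a = th$boundary_a,
         threshold.start_w0 = th$start_w0,
         setNames(th$delta, paste0("threshold.delta.", names(th$delta))))
  for (nm in outcomes)
    v <- c(v, setNames(params$outcomes[[nm]],
                       paste0("outcome.", nm, ".", c("b0", "bH", "bA",
                                                     "bHA"))))
  v
}

params_unpack <- function(v, template, outcomes = ed_primary_outcomes) {
  p <- template
  k <- length(p$eta)
  p$eta[] <- v[1:k]; i <- k
  for (nm in names(p$proxies$continuous)) {
    pr <- p$proxies$continuous[[nm]]
    nk <- length(pr$kappa)
    pr$alpha <- v[i + 1]; pr$lambda <- v[i + 2]
    pr$kappa[] <- v[i + 2 + seq_len(nk)]
    pr$sigma <- max(v[i + 3 + nk], 1e-8)
    p$proxies$continuous[[nm]] <- pr
    i <- i + 3 + nk
  }
  k <- length(p$proxies$acuity)
  p$proxies$acuity[] <- v[i + seq_len(k)]; i <- i + k
  a <- max(v[i + 1], 1e-8)
  w0 <- min(max(v[i + 2], 1e-8), 1 - 1e-8)
  k <- length(p$threshold$delta)
  delta <- p$threshold$delta
  delta[] <- v[i + 2 + seq_len(k)]
  p$threshold <- threshold_params(a, w0, delta)
  i <- i + 2 + k
  for (nm in outcomes) {
    p$outcomes[[nm]][] <- v[i + 1:4]; i <- i + 4
  }
  p
}

# parameter covariance: inverse information, with the information estimated
# either from the outer product of per-visit scores (central differences on
# the per-visit observed log-likelihood) or from a numerically
# differentiated Hessian of the total observed log-likelihood
em_covariance <- function(params, design, outcomes, method = "opg") {
  theta <- params_pack(params, outcomes)
  p <- length(theta)
  flags <- character(0)
  if (method == "opg") {
    S <- matrix(0, design$n, p, dimnames = list(NULL, names(theta)))
    for (j in seq_len(p)) {
      hstep <- 1e-5 * (1 + abs(theta[j]))
      tp <- theta; tp[j] <- theta[j] + hstep
      tm <- theta; tm[j] <- theta[j] - hstep
      S[, j] <- (visit_loglik(params_unpack(tp, params, outcomes), design,
                              outcomes) -
                   visit_loglik(params_unpack(tm, params, outcomes), design,
                                outcomes)) / (2 * hstep)
    }
    info <- crossprod(S)
  } else {
    f <- function(v) observed_loglik(params_unpack(v, params, outcomes),
                                     design, outcomes)
    info <- -numeric_hessian(f, theta)
    dimnames(info) <- list(names(theta), names(theta))
  }
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(cov)) {
    flags <- c(flags, "information_not_pd")
    eig <- eigen(info, symmetric = TRUE)
    vals <- pmax(eig$values, max(eig$values) * 1e-10)
    cov <- eig$vectors %*% diag(1 / vals) %*% t(eig$vectors)
  }
  dimnames(cov) <- list(names(theta), names(theta))
  list(covariance = cov, flags = flags)
}

numeric_hessian <- function(f, x, rel_step = 1e-5) {
  p <- length(x)
  h <- rel_step * (1 + abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}
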