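test_that("latent prior is the capped-expit of the baseline linear
          predictor", {
  x <- c(0.5, 1, 0, 0, 0, 0, 1, 0, 0.3)
  expect_equal(latent_prior(rep(0, 10), x), 0.5)
  expect_equal(latent_prior(c(qlogis(0.3), rep(0, 9)), x), 0.3)
  eta <- c(0, 1, rep(0, 8))
  x2 <- x; x2[1] <- x[1] + 1
  expect_gt(latent_prior(eta, x2), latent_prior(eta, x))
})

test_that("component log-likelihood matches an independent per-row
          enumeration to 1e-10", {
  des <- toy_design()
  par <- toy_params()
  for (h in 0:1) {
    got <- component_loglik(par, des, h)
    for (i in 1:2)
      expect_equal(got[i], oracle_row_loglik(par, des, i, h),
                   tolerance = 1e-10)
  }
})

test_that("the two latent branches sum to the observed-data likelihood
          and the E-step equals brute-force enumeration", {
  des <- toy_design()
  par <- toy_params()
  ll0 <- component_loglik(par, des, 0)
  ll1 <- component_loglik(par, des, 1)
  expect_equal(sum(log(exp(ll0) + exp(ll1))), observed_loglik(par, des),
               tolerance = 1e-12)
  gamma <- e_step(par, des)
  brute <- exp(ll1) / (exp(ll0) + exp(ll1))
  expect_equal(gamma, brute, tolerance = 1e-12)
  expect_true(all(gamma >= 0 & gamma <= 1))
})

test_that("with all latent effects removed the posterior equals the
          prior", {
  des <- toy_design()
  par <- toy_params()
  for (nm in names(par$proxies$continuous))
    par$proxies$continuous[[nm]]$lambda <- 0
  par$proxies$acuity[["latent"]] <- 0
  par$threshold$delta[["latent"]] <- 0
  for (nm in names(par$outcomes)) {
    par$outcomes[[nm]][["bH"]] <- 0
    par$outcomes[[nm]][["bHA"]] <- 0
  }
  expect_equal(e_step(par, des), latent_prior(par$eta, des$baseline),
               tolerance = 1e-12)
})

test_that("weighted-least-squares proxy update solves the weighted normal
          equations", {
  fx <- gen_prep(n = 400, seed = 23)
  des <- fx$prep$design
  set.seed(1)
  gamma <- runif(des$n)
  prev <- edlatent:::initial_params(des)
  new <- m_step(des, gamma, prev)
  Z <- cbind(1, c(rep(0, des$n), rep(1, des$n)),
             rbind(des$baseline, des$baseline))
  w <- c(1 - gamma, gamma)
  y <- rep(des$proxies[, "temperature"], 2)
  beta_hat <- solve(t(Z) %*% (w * Z), t(Z) %*% (w * y))
  pr <- new$proxies$continuous$temperature
  expect_equal(unname(c(pr$alpha, pr$lambda, pr$kappa)),
               unname(as.numeric(beta_hat)), tolerance = 1e-10)
  r <- y - as.numeric(Z %*% beta_hat)
  expect_equal(pr$sigma, sqrt(sum(w * r^2) / sum(w)), tolerance = 1e-10)
})

test_that("degenerate responsibilities drive the prior toward certainty
          with the linear predictor capped", {
  fx <- gen_prep(n = 300, seed = 29)
  des <- fx$prep$design
  prev <- edlatent:::initial_params(des)
  up <- m_step(des, rep(1, des$n), prev)
  p1 <- latent_prior(up$eta, des$baseline)
  expect_true(all(p1 > 0.95))
  expect_true(all(is.finite(component_loglik(up, des, 1))))
  down <- m_step(des, rep(0, des$n), prev)
  expect_true(all(latent_prior(down$eta, des$baseline) < 0.05))
})

test_that("observed log-likelihood is additive and permutation
          invariant", {
  des <- toy_design()
  par <- toy_params()
  ll <- observed_loglik(par, des)
  dup <- edlatent:::subset_design(des, c(1, 2, 1))
  expect_equal(observed_loglik(par, dup),
               ll + edlatent:::visit_loglik(par, des)[1],
               tolerance = 1e-10)
  perm <- edlatent:::subset_design(des, c(2, 1))
  expect_equal(observed_loglik(par, perm), ll, tolerance = 1e-12)
})

test_that("label flipping leaves the observed likelihood unchanged and
          canonicalization orients the first proxy's latent effect", {
  des <- toy_design()
  par <- toy_params()
  par$proxies$continuous$temperature$lambda <- -0.9
  flipped <- edlatent:::canonicalize_params(par)
  expect_true(flipped$flipped)
  expect_gte(flipped$params$proxies$continuous$temperature$lambda, 0)
  expect_equal(observed_loglik(flipped$params, des),
               observed_loglik(par, des), tolerance = 1e-8)
  expect_equal(e_step(flipped$params, des), 1 - e_step(par, des),
               tolerance = 1e-8)
})

test_that("EM increases the observed log-likelihood and the fit is
          deterministic given a seed", {
  fx <- fit_small()
  fit <- fx$fit
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(fit$gamma >= 0 & fit$gamma <= 1))
  expect_gte(fit$params$proxies$continuous$temperature$lambda, 0)
  # covariance is symmetric positive semidefinite
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-10)
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(ev)))
  refit <- fit_em(fx$fx$prep$design,
                  em_control(n_restarts = 1, max_iter = 50,
                             rel_tol = 1e-7, seed = 1,
                             cov_method = "none"))
  expect_equal(refit$params$eta, fit$params$eta, tolerance = 1e-12)
})

test_that("packing and unpacking the parameter vector round-trips", {
  par <- toy_params()
  v <- edlatent:::params_pack(par)
  back <- edlatent:::params_unpack(v, par)
  expect_equal(edlatent:::params_pack(back), v, tolerance = 1e-15)
  expect_equal(back$threshold$boundary_a, par$threshold$boundary_a)
  expect_equal(back$outcomes$y_mortality_30, par$outcomes$y_mortality_30)
})
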