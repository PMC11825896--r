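#' Threshold-regression (Wiener first-passage) admission process
#'
#' The admission process is modelled as a latent evidence process: a Wiener
#' process with unit diffusion, started at `w0 * a` between an absorbing
#' discharge boundary at 0 and an admit boundary at `a > 0`, with drift
#' linear in latent health, baseline characteristics and proxy observations.
#' The boundary first crossed determines the disposition decision and the
#' crossing time is the treatment time, giving a joint likelihood for the
#' decision/timing pair.
#'
#' @param boundary_a Positive boundary separation (latent-evidence units).
#' @param start_w0 Relative start point in (0, 1); the absolute start is
#'   `w0 * a`.
#' @param delta Named numeric vector of drift coefficients: `"(Intercept)"`,
#'   `"latent"`, then one entry per baseline and proxy column.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(boundary_a, start_w0, delta) {
  if (!is.numeric(boundary_a) || length(boundary_a) != 1 || boundary_a <= 0)
    stop("boundary_a must be a positive scalar")
  if (!is.numeric(start_w0) || length(start_w0) != 1 ||
      start_w0 <= 0 || start_w0 >= 1)
    stop("start_w0 must lie strictly inside (0, 1)")
  structure(list(boundary_a = boundary_a, start_w0 = start_w0,
                 delta = delta),
            class = "threshold_params")
}

check_boundary <- function(boundary_a, start_w0) {
  if (!is.finite(boundary_a) || boundary_a <= 0)
    stop("boundary_a must be a positive number")
  if (!is.finite(start_w0) || start_w0 <= 0 || start_w0 >= 1)
    stop("start_w0 must lie strictly inside (0, 1)")
  invisible(TRUE)
}

#' Probability that the admit (upper) boundary is hit first
#'
#' Closed form for a unit-diffusion Wiener process with drift between
#' absorbing boundaries at 0 and `a`, started at `w0 * a`:
#' `P(admit) = (1 - exp(-2 v w0 a)) / (1 - exp(-2 v a))` for drift `v != 0`
#' and `w0` at zero drift. Near zero drift a first-order expansion is used so
#' the ratio stays numerically stable.
#'
#' @param drift Numeric vector of drift values.
#' @inheritParams threshold_params
#' @return Vector of admit probabilities.
#' @export
upper_hit_probability <- function(drift, boundary_a, start_w0) {
  check_boundary(boundary_a, start_w0)
  va <- drift * boundary_a
  z <- start_w0 * boundary_a
  p <- ifelse(abs(va) < 1e-5,
              # expm1 ratio ~ w0 * (1 - v a (1 - w0)) + O((va)^2)
              start_w0 * (1 - va * (1 - start_w0)),
              expm1(-2 * drift * z) / expm1(-2 * va))
  pmin(pmax(p, 0), 1)
}

#' Defective first-passage-time density
#'
#' Density (per unit time) of absorption at the named boundary at time `t`.
#' The density is defective: integrating over all `t > 0` gives the
#' probability of exiting through that boundary. Evaluation uses the
#' standard dual series: an image expansion accurate at small scaled time
#' and an eigenfunction expansion accurate at large scaled time, with terms
#' accumulated until they fall below 1e-9.
#'
#' @param t Positive first-passage times.
#' @param drift Drift value(s), length 1 or `length(t)`.
#' @inheritParams threshold_params
#' @param boundary `"upper"` (admit) or `"lower"` (discharge); recycled.
#' @param log Return the log density?
#' @param method Series choice: `"auto"` (default), `"small"` or `"large"`
#'   time representation (mainly for numerical checks).
#' @return Vector of (log) densities.
#' @export
fpt_density <- function(t, drift, boundary_a, start_w0,
                        boundary = c("upper", "lower"), log = FALSE,
                        method = c("auto", "small", "large")) {
  check_boundary(boundary_a, start_w0)
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be positive and finite")
  boundary <- match.arg(boundary, several.ok = FALSE)
  method <- match.arg(method)
  upper <- rep(boundary == "upper", length(t))
  ld <- wfpt_logdens_cpp(as.numeric(t), as.numeric(drift),
                         boundary_a, start_w0, upper,
                         match(method, c("auto", "small", "large")) - 1L)
  if (log) ld else exp(ld)
}

# vectorized log density with per-row boundary indicator; workhorse for the
# likelihood (no arg checking beyond t > 0, done in C++)
wfpt_logdens <- function(t, drift, boundary_a, start_w0, upper) {
  wfpt_logdens_cpp(as.numeric(t), as.numeric(drift), boundary_a, start_w0,
                   as.logical(upper), 0L)
}

#' Joint log-likelihood of a disposition decision and treatment time
#'
#' Composes the drift from the linear predictor
#' `delta0 + deltaH * h + delta_X' x + delta_W' w` and evaluates the log
#' first-passage density at the boundary matching the decision (admit =
#' upper, discharge = lower) at the observed treatment time.
#'
#' @param theta A [threshold_params] object. `theta$delta` must be ordered
#'   `(Intercept, latent, covariates...)` to match `covariates`.
#' @param covariates Numeric vector (or matrix, rows = visits) of baseline
#'   and proxy values in the order of `theta$delta[-(1:2)]`.
#' @param latent_h Latent state 0/1 (scalar or per-row).
#' @param decision `"admit"`/`"discharge"` (or 1/0), scalar or per-row.
#' @param treatment_time Positive time(s) to decision.
#' @return Log-likelihood value(s); underflowing densities come back as a
#'   large negative number rather than `-Inf`.
#' @export
admission_loglik <- function(theta, covariates, latent_h, decision,
                             treatment_time) {
  stopifnot(inherits(theta, "threshold_params"))
  if (any(treatment_time <= 0)) stop("treatment_time must be > 0")
  x <- if (is.matrix(covariates)) covariates else matrix(covariates, nrow = 1)
  adm <- if (is.character(decision) || is.factor(decision)) {
    as.character(decision) == "admit"
  } else as.logical(decision)
  d <- theta$delta
  drift <- d[1] + d[2] * latent_h + as.numeric(x %*% d[-(1:2)])
  wfpt_logdens(treatment_time, drift, theta$boundary_a, theta$start_w0, adm)
}

#' Simulate a first-passage decision and time
#'
#' Euler scheme with a Brownian-bridge crossing correction inside every step,
#' so boundary excursions between grid points are detected; the default step
#' is `1e-4 * boundary_a^2`.
#'
#' @inheritParams upper_hit_probability
#' @param n Number of draws; `drift` must have length 1 or `n`.
#' @param dt Euler step.
#' @param seed Integer seed for the simulation stream. Defaults to a value
#'   drawn from R's RNG, so `set.seed()` governs reproducibility.
#' @return `data.frame(admit = 0/1, time > 0)`.
#' @export
simulate_first_passage <- function(drift, boundary_a, start_w0, n = length(drift),
                                   dt = 1e-4 * boundary_a^2, seed = NULL) {
  check_boundary(boundary_a, start_w0)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  sim <- wfpt_sim_cpp(as.numeric(drift), as.integer(n), boundary_a, start_w0,
                      dt, as.integer(seed))
  data.frame(admit = sim$admit, time = sim$time)
}
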