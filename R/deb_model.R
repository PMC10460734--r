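#' Fixed host constants of the tumor-in-host model
#'
#' The host maintenance-growth rate ratio `m` (1/day) and growth
#' energy-investment ratio `g` (dimensionless) are fixed during model
#' identification on xenograft data and enter the secondary metrics only
#' through their product `m*g`. The defaults shipped here are SYNTHETIC
#' stand-ins: the product is calibrated so that the tumor volume doubling
#' time evaluated at the typical tumor parameters equals the reference value
#' of 1.3 days, and the split between `m` and `g` is arbitrary (g = 1).
#' Supply study-specific values when they are available.
#'
#' @param m host maintenance-growth rate ratio, 1/day.
#' @param g host growth energy-investment ratio, dimensionless.
#' @return a list of class `host_constants` with elements `m`, `g` and a
#'   `calibrated` flag marking the synthetic defaults.
#' @export
host_constants <- function(m = 0.4361763, g = 1) {
  stopifnot(m > 0, g > 0)
  structure(list(m = m, g = g,
                 calibrated = missing(m) && missing(g)),
            class = "host_constants")
}

#' Exponential tumor growth rate
#'
#' The rate governing the initial (exponential) phase of tumor growth,
#' `lambda = m*g*mu_u/g_u - m_u`: the host maintenance and growth costs
#' (m, g) scaled by the tumor gluttony `mu_u` relative to the tumor growth
#' cost `g_u`, net of the tumor maintenance cost `m_u`. May be non-positive
#' for extreme parameter draws (a non-growing tumor); that is a legitimate
#' value, not an error.
#'
#' @param mu_u tumor gluttony (dimensionless), vectorised.
#' @param g_u tumor growth energy-investment ratio (> 0).
#' @param m_u tumor maintenance-growth rate ratio, 1/day.
#' @param host a [host_constants()] object.
#' @return lambda, 1/day.
#' @export
lambda_rate <- function(mu_u, g_u, m_u, host = host_constants()) {
  if (any(g_u <= 0)) stop("g_u must be strictly positive")
  host$m * host$g * mu_u / g_u - m_u
}

#' Tumor volume doubling time
#'
#' `TVDT = ln(2) / lambda` for a growing tumor. Draws with `lambda <= 0`
#' (non-growing tumor) yield `NA` — the undefined marker that downstream
#' delta estimation drops, with a reported count, rather than clamping.
#'
#' @param lambda exponential tumor growth rate, 1/day (vectorised).
#' @return doubling time in days, `NA` where `lambda <= 0`.
#' @export
tvdt <- function(lambda) {
  ifelse(lambda > 0, log(2) / lambda, NA_real_)
}

#' Concentration threshold for tumor eradication
#'
#' The minimal constant drug concentration beyond which tumor eradication is
#' asymptotically reached: `C_T = lambda / k2`, with `k2` the anticancer
#' drug potency. `NA` where `lambda <= 0`.
#'
#' @param lambda exponential tumor growth rate, 1/day.
#' @param k2 drug potency, ml/(ng day); strictly positive.
#' @return threshold concentration, ng/ml.
#' @export
c_threshold <- function(lambda, k2) {
  if (any(k2 <= 0)) stop("k2 must be strictly positive")
  ifelse(lambda > 0, lambda / k2, NA_real_)
}

#' Basal food-supply coefficient from its estimation parametrization
#'
#' During model identification the food-supply coefficient is parametrized
#' as `rho_b = 1 / (1 + R_b)`, which maps any non-negative `R_b` into (0, 1].
#'
#' @param Rb non-negative reparametrization value (vectorised).
#' @return `rho_b` in (0, 1].
#' @export
rho_b <- function(Rb) {
  if (any(Rb < 0)) stop("Rb must be non-negative")
  1 / (1 + Rb)
}

#' Structural-biomass degradation trajectory
#'
#' A time grid with the corresponding structural-biomass degradation rate,
#' as exported from a simulator of the full tumor-in-host dynamics (the ODE
#' system itself is outside this package). A 0.1-day export grid is the
#' recommended resolution; extraction operates on the supplied grid without
#' interpolation.
#'
#' @param times strictly increasing time vector (days).
#' @param degradation_rate degradation rate at each time (cm^3/day).
#' @return an object of class `body_trajectory`.
#' @export
body_trajectory <- function(times, degradation_rate) {
  stopifnot(length(times) == length(degradation_rate), length(times) > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 degradation_rate = as.numeric(degradation_rate)),
            class = "body_trajectory")
}

#' Read a trajectory CSV (columns `time,degradation_rate`)
#' @param path CSV path.
#' @return a [body_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  body_trajectory(d$time, d$degradation_rate)
}

#' Time at which the maximum degradation rate is first reached
#'
#' Returns the earliest time at which the degradation rate comes within
#' `tolerance` of its maximum over the trajectory. The default tolerance of
#' zero means the trajectory's own maximum; a positive tolerance instead
#' detects attainment of the asymptotic plateau.
#'
#' @param traj a [body_trajectory()].
#' @param tolerance non-negative attainment tolerance (same units as the
#'   rate).
#' @return the first-attainment time, days.
#' @export
time_of_max_degradation <- function(traj, tolerance = 0) {
  stopifnot(inherits(traj, "body_trajectory"), tolerance >= 0)
  peak <- max(traj$degradation_rate)
  traj$times[which(traj$degradation_rate >= peak - tolerance)[1]]
}

#' Control-vs-treated delay in reaching maximum degradation
#'
#' The toxicity/efficacy trade-off metric `T_max,control - T_max,treated`:
#' positive when the treated arm reaches its maximum structural-biomass
#' degradation rate earlier than the control arm (drug toxicity dominates),
#' negative when treatment delays it (net benefit to the host).
#'
#' @param control,treated [body_trajectory()] objects for the untreated and
#'   treated arms.
#' @param tolerance passed to [time_of_max_degradation()].
#' @return the delay in days.
#' @export
delta_t_dvmax <- function(control, treated, tolerance = 0) {
  time_of_max_degradation(control, tolerance) -
    time_of_max_degradation(treated, tolerance)
}

#' Built-in row-wise model functions for the secondary metrics
#'
#' `ct_model` and `tvdt_model` map a sample matrix of tumor-in-host
#' parameters (columns named as in the packaged parameter table, at minimum
#' `mu_u`, `g_u`, `m_u` and, for `ct_model`, `k2`) to the eradication
#' threshold and the doubling time respectively. Rows whose growth rate is
#' non-positive yield `NA`. Use these as the `model` argument of
#' [run_two_stage()] or [monte_carlo_summary()].
#'
#' @param host a [host_constants()] object; bind it with `ct_model(host = )`
#'   via an anonymous function if non-default values are needed.
#' @return a function `matrix -> numeric vector`.
#' @export
ct_model <- function(host = host_constants()) {
  function(X) {
    lam <- lambda_rate(X[, "mu_u"], X[, "g_u"], X[, "m_u"], host)
    c_threshold(lam, X[, "k2"])
  }
}

#' @rdname ct_model
#' @export
tvdt_model <- function(host = host_constants()) {
  function(X) {
    tvdt(lambda_rate(X[, "mu_u"], X[, "g_u"], X[, "m_u"], host))
  }
}

#' Evaluate all closed-form secondary metrics on a sample matrix
#'
#' @param X sample matrix with columns `mu_u`, `g_u`, `m_u`, `k2`, `Rb`.
#' @param host a [host_constants()] object.
#' @return data.frame with columns `lambda`, `tvdt`, `c_t`, `rho_b`.
#' @export
derived_metrics <- function(X, host = host_constants()) {
  lam <- lambda_rate(X[, "mu_u"], X[, "g_u"], X[, "m_u"], host)
  data.frame(lambda = lam, tvdt = tvdt(lam),
             c_t = c_threshold(lam, X[, "k2"]),
             rho_b = rho_b(X[, "Rb"]))
}
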