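#' PD parameters for the tumor-growth-inhibition model
#'
#' Parameters of the Simeoni unperturbed-growth model (smooth transition
#' from exponential growth at rate lambda0 to linear growth at rate lambda1,
#' with shape factor phi fixed at 20 by convention) and of the drug-effect
#' extension: exposure-proportional transfer of proliferating cells into a
#' chain of three transit death compartments emptying at rate k1. In the
#' combination arm the potency k_aft is scaled by (1 + alpha_syn), the
#' synergy factor.
#'
#' @param lambda0 Exponential growth rate (1/day).
#' @param lambda1 Linear growth rate (mm^3/day).
#' @param phi Shape factor of the smooth exponential-to-linear switch
#'   (dimensionless, conventionally fixed at 20).
#' @param v0 Tumor volume at inoculation (mm^3).
#' @param k1 Transit death rate (1/day).
#' @param k_aft Drug potency (mL/ng/day).
#' @param alpha_syn Synergy factor (dimensionless, > -1); the kill term is
#'   multiplied by (1 + alpha_syn * hadb1_flag).
#' @param hadb1_flag 0 for control/monotherapy dynamics, 1 for the
#'   combination arm.
#' @param sigma_prop Proportional residual error (fraction).
#' @return Object of class `pd_params`.
#' @export
pd_params <- function(lambda0, lambda1, phi = 20, v0,
                      k1 = 0, k_aft = 0, alpha_syn = 0, hadb1_flag = 0,
                      sigma_prop = 0) {
  if (lambda0 <= 0 || lambda1 <= 0 || v0 <= 0 || phi <= 0)
    stopf("lambda0, lambda1, v0 and phi must be positive")
  if (k1 < 0 || k_aft < 0) stopf("k1 and k_aft must be non-negative")
  if (alpha_syn <= -1) stopf("alpha_syn must be greater than -1")
  if (!hadb1_flag %in% c(0, 1)) stopf("hadb1_flag must be 0 or 1")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, phi = phi, v0 = v0,
                 k1 = k1, k_aft = k_aft, alpha_syn = alpha_syn,
                 hadb1_flag = hadb1_flag, sigma_prop = sigma_prop),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf("Tumor growth: lambda0 %.4g 1/day, lambda1 %.4g mm3/day, phi %g, V0 %.4g mm3\n",
              x$lambda0, x$lambda1, x$phi, x$v0))
  if (x$k_aft > 0)
    cat(sprintf("  Drug effect: K %.4g mL/ng/day, k1 %.3g 1/day, alpha_syn %.3g (flag %d)\n",
                x$k_aft, x$k1, x$alpha_syn, x$hadb1_flag))
  invisible(x)
}

#' Unperturbed tumor growth rate
#'
#' Smooth Simeoni growth function
#' f(X1) = lambda0 * X1 / (1 + (lambda0 * X1 / lambda1)^phi)^(1/phi):
#' exponential (rate lambda0) well below the switching threshold, linear
#' (rate lambda1) well above it. The denominator is evaluated on the log
#' scale (log-sum-exp) so phi = 20 cannot overflow even for volumes of
#' 1e6 mm^3.
#'
#' @param x1 Proliferating tumor volume (mm^3); vectorized.
#' @param p [pd_params()].
#' @return Growth rate (mm^3/day).
#' @export
natural_growth_rate <- function(x1, p) {
  if (any(x1 < 0)) stopf("tumor volume must be non-negative")
  out <- numeric(length(x1))
  pos <- x1 > 0
  if (any(pos)) {
    lr <- log(p$lambda0 * x1[pos] / p$lambda1)
    denom <- exp(logaddexp(0, p$phi * lr) / p$phi)
    out[pos] <- p$lambda0 * x1[pos] / denom
  }
  out
}

#' Exponential-to-linear switching threshold
#'
#' The tumor volume W_th = lambda1 / lambda0 at which the exponential growth
#' rate equals the linear one (continuity of the piecewise model).
#'
#' @param p [pd_params()].
#' @return W_th (mm^3).
#' @export
switching_threshold <- function(p) {
  if (p$lambda0 <= 0) stopf("lambda0 must be positive")
  p$lambda1 / p$lambda0
}

#' Tumor-stasis/eradication threshold concentration
#'
#' C_T = lambda0 / K: the steady-state drug concentration above which the
#' model predicts eventual tumor eradication, and below which the tumor
#' approaches a stable size. For the combination arm the effective potency
#' K * (1 + alpha_syn) is used, lowering the threshold.
#'
#' @param p [pd_params()] with `k_aft > 0` (otherwise `Inf` is returned as a
#'   documented sentinel: a drug with no potency never eradicates).
#' @param combination If `TRUE`, use the synergy-scaled potency.
#' @return C_T (ng/mL).
#' @export
threshold_concentration <- function(p, combination = FALSE) {
  k <- p$k_aft * (if (combination) 1 + p$alpha_syn else 1)
  if (k == 0) return(Inf)
  p$lambda0 / k
}

#' Derivatives of the tumor-growth-inhibition system
#'
#' State X1 is the proliferating volume; X2-X4 are transit death
#' compartments. The drug moves cells out of X1 at rate
#' K * (1 + alpha_syn * flag) * C(t) and damaged cells progress through the
#' chain at rate k1. The observed volume is V = X1 + X2 + X3 + X4 (computed,
#' never integrated, so the identity is exact).
#'
#' @param state Named numeric vector `c(x1=, x2=, x3=, x4=)` (mm^3).
#' @param t Time (days since inoculation).
#' @param p [pd_params()].
#' @param conc_at Function day -> drug concentration (ng/mL); must return 0
#'   before treatment start. Defaults to no exposure.
#' @return Named numeric vector of derivatives (mm^3/day).
#' @export
tgi_derivatives <- function(state, t, p, conc_at = function(t) 0) {
  x <- pmax(state, 0)
  keff <- p$k_aft * (1 + p$alpha_syn * p$hadb1_flag)
  kill <- keff * conc_at(t) * x[1]
  c(x1 = unname(natural_growth_rate(x[1], p) - kill),
    x2 = unname(kill - p$k1 * x[2]),
    x3 = unname(p$k1 * (x[2] - x[3])),
    x4 = unname(p$k1 * (x[3] - x[4])))
}

# Concentration forcing function (study clock in days) for a regimen: zero
# before the first dose, otherwise the typical multiple-dose profile with
# the PK clock in hours.
conc_forcing <- function(pk, reg) {
  if (is.null(reg)) return(function(t) t * 0)
  function(t) {
    h <- (t - reg$start_day) * 24
    out <- numeric(length(t))
    pos <- h >= 0
    if (any(pos)) out[pos] <- conc_profile(pk, reg, h[pos])
    out
  }
}

#' Simulate one treatment arm of the PK/PD model
#'
#' Integrates the tumor-growth-inhibition system from inoculation (t = 0,
#' X1 = V0, transit compartments empty) with the typical-individual
#' concentration profile (no inter-individual variability) as the drug
#' input. With `regimen = NULL` (or zero potency) the system reduces to
#' unperturbed growth.
#'
#' @param pk [pk_params()] (ignored when `regimen` is `NULL`).
#' @param pd [pd_params()].
#' @param regimen [dose_regimen()] or `NULL` for the control arm; the
#'   regimen's `start_day` places treatment on the study clock.
#' @param t_end End of simulation (days).
#' @param dt_out Output grid spacing (days).
#' @param rtol,atol Integration tolerances passed to [deSolve::lsoda()].
#' @return Object of class `simulation_result`: a data frame with columns
#'   `t_day`, `conc` (ng/mL), `x1`..`x4` and total volume `v` (mm^3).
#' @export
simulate_arm <- function(pk, pd, regimen = NULL, t_end = 40, dt_out = 0.1,
                         rtol = 1e-8, atol = 1e-10) {
  if (t_end <= 0) stopf("t_end must be positive")
  times <- unique(c(seq(0, t_end, by = dt_out), t_end))
  simulate_arm_at(pk, pd, regimen, times, rtol = rtol, atol = atol)
}

# Core integrator on an explicit day grid (also used by the fitting and VPC
# stages, which only need predictions at observation days).
simulate_arm_at <- function(pk, pd, regimen, times, rtol = 1e-8, atol = 1e-10) {
  conc_at <- conc_forcing(pk, regimen)
  deriv <- function(t, y, parms) list(tgi_derivatives(y, t, pd, conc_at))
  y0 <- c(x1 = pd$v0, x2 = 0, x3 = 0, x4 = 0)
  grid <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(y0, grid, deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stopf("integration failure in simulate_arm (lsoda istate %d)", attr(out, "istate")[1])
  out <- as.data.frame(out)
  res <- data.frame(t_day = out$time, conc = conc_at(out$time),
                    x1 = out$x1, x2 = out$x2, x3 = out$x3, x4 = out$x4)
  res$v <- res$x1 + res$x2 + res$x3 + res$x4
  res <- res[match(times, res$t_day), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("simulation_result", "data.frame"))
}

#' First crossing time of a tumor-volume threshold
#'
#' Linear interpolation of the simulated total volume between output points;
#' the crossing day is also reported rounded to whole days, the resolution
#' at which such milestones are usually quoted. Times are on the study clock
#' (t = 0 at inoculation).
#'
#' @param sim A `simulation_result` from [simulate_arm()].
#' @param threshold Volume threshold (mm^3).
#' @return List with `day` (rounded) and `day_raw` (interpolated); both `NA`
#'   if the trajectory never reaches the threshold within the simulated
#'   window.
#' @export
time_to_threshold <- function(sim, threshold) {
  v <- sim$v
  t <- sim$t_day
  if (v[1] >= threshold) return(list(day = 0, day_raw = 0))
  idx <- which(v >= threshold)
  if (!length(idx)) return(list(day = NA_real_, day_raw = NA_real_))
  i <- idx[1]
  raw <- t[i - 1] + (threshold - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
  list(day = round(raw), day_raw = raw)
}
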