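#' -2 log-likelihood under a proportional error model
#'
#' For observations y with model predictions f and residual model
#' y = f * (1 + eps), eps ~ N(0, sigma^2), contributes
#' log(2*pi) + 2*log(sigma*f) + ((y - f) / (sigma*f))^2 per observation.
#'
#' @param pred Model predictions (must be positive wherever observed).
#' @param obs Observations, same length.
#' @param sigma Proportional error SD (fraction, > 0).
#' @return The summed -2 log-likelihood.
#' @export
neg2ll_proportional <- function(pred, obs, sigma) {
  if (length(pred) != length(obs)) stopf("pred and obs must have equal length")
  if (sigma <= 0) stopf("sigma must be positive")
  bad <- which(pred <= 0)
  if (length(bad))
    stopf("likelihood error: non-positive prediction at observation %d", bad[1])
  sd_i <- sigma * pred
  sum(log(2 * pi) + 2 * log(sd_i) + ((obs - pred) / sd_i)^2)
}

# ---- shared optimizer machinery -------------------------------------------

# Deterministic multistart: the heuristic start plus symmetric perturbations
# on the log scale, so fits are reproducible without consuming RNG state.
multistart_points <- function(start, n = 5, spread = 0.35) {
  k <- length(start)
  pts <- list(start)
  if (n >= 2) pts[[2]] <- start + spread
  if (n >= 3) pts[[3]] <- start - spread
  if (n >= 4) pts[[4]] <- start + spread * rep_len(c(1, -1), k)
  if (n >= 5) pts[[5]] <- start + spread * rep_len(c(-1, 1), k)
  pts[seq_len(min(n, 5))]
}

run_multistart <- function(ofv, start, lower, upper, n_starts) {
  best <- NULL
  for (s in multistart_points(start, n_starts)) {
    s <- pmin(pmax(s, lower + 1e-8), upper - 1e-8)
    fit <- tryCatch(
      stats::nlminb(s, ofv, lower = lower, upper = upper,
                    control = list(eval.max = 2000, iter.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
  }
  if (is.null(best)) stopf("estimation failed: no start point converged")
  # Derivative-free polish of the winner; convergence is declared when the
  # polish cannot improve the objective materially (quasi-Newton line
  # searches on finite-difference gradients can stop with a spurious
  # "false convergence" code near the optimum).
  boxed <- function(p) {
    if (any(p < lower) || any(p > upper)) return(1e10)
    ofv(p)
  }
  improved <- Inf
  for (round in 1:3) {
    pol <- tryCatch(
      stats::optim(best$par, boxed, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(pol) || !is.finite(pol$value) || pol$value > best$objective) break
    improved <- best$objective - pol$value
    best$par <- pol$par
    best$objective <- pol$value
    if (improved < 0.01) break
  }
  if (best$convergence != 0 && improved < 0.05) best$convergence <- 0
  best
}

# SE/RSE on the natural scale for log-parameterized estimates, from the
# numerical Hessian of the -2 log-likelihood (cov = 2 * H^-1).
se_from_hessian <- function(ofv, theta_hat, est_natural) {
  hess <- tryCatch(stats::optimHess(theta_hat, ofv), error = function(e) NULL)
  se_log <- rep(NA_real_, length(theta_hat))
  if (!is.null(hess)) {
    cov <- tryCatch(2 * solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se_log[d > 0] <- sqrt(d[d > 0])
    }
  }
  list(se = est_natural * se_log, rse_percent = 100 * se_log)
}

new_fit_result <- function(stage, estimates, se, rse, ofv, converged,
                           n_obs, n_subjects, ...) {
  structure(c(list(stage = stage, estimates = estimates, se = se,
                   rse_percent = rse, ofv = ofv, converged = converged,
                   n_obs = n_obs, n_subjects = n_subjects), list(...)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s stage): OFV %.3f, %d observations, %d subject(s), converged: %s\n",
              x$stage, x$ofv, x$n_obs, x$n_subjects, x$converged))
  tab <- data.frame(estimate = x$estimates,
                    se = x$se[names(x$estimates)],
                    rse_pct = x$rse_percent[names(x$estimates)])
  print(round(tab, 5))
  if (!is.null(x$shrinkage))
    cat("eta shrinkage (%):", paste(sprintf("%s %.1f", names(x$shrinkage),
                                            x$shrinkage), collapse = ", "), "\n")
  invisible(x)
}

# ---- PK mixed-effects fit (Laplace marginal likelihood) -------------------

# Steady-state-day prediction for one animal: samples are taken post-dose on
# the final dosing day, i.e. at absolute PK time (n_doses - 1) * tau + t.
pk_pred_subject <- function(ka, cl, vd, reg, t_postdose_h) {
  p <- list(ka = ka, cl_f = cl, vd_f = vd)
  class(p) <- "pk_params"
  conc_profile(p, reg, (reg$n_doses - 1) * reg$tau_h + t_postdose_h)
}

# Multiple-dose prediction and its partials with respect to the log-scale
# random effects eta = (log CL deviation, log Vd deviation). Written out so
# the inner Laplace optimization can use analytic gradients.
pk_pred_grad <- function(ka, cl, vd, reg, t_abs_h) {
  ke <- cl / vd
  el <- outer(t_abs_h, (seq_len(reg$n_doses) - 1) * reg$tau_h, "-")
  el[el < 0] <- NA
  m <- 1000 * reg$dose_amount * ka / (vd * (ka - ke))
  eke <- exp(-ke * el); eka <- exp(-ka * el)
  b <- m * (eke - eka)
  # dB/dke at fixed vd: B/(ka-ke) - m*el*eke ; chain: dke/deta1 = ke,
  # dke/deta2 = -ke ; explicit vd dependence contributes -B per unit eta2.
  db_dke <- b / (ka - ke) - m * el * eke
  c_t <- rowSums(b, na.rm = TRUE)
  s_dke <- rowSums(db_dke, na.rm = TRUE)
  list(c = c_t, dc1 = ke * s_dke, dc2 = -c_t - ke * s_dke)
}

# Joint -2 log of data and random effects for one subject, with gradient.
pk_joint_q <- function(eta, ka, cl, vd, omega, sigma, reg, t_abs, dv,
                       grad = FALSE) {
  pg <- pk_pred_grad(ka, cl * exp(eta[1]), vd * exp(eta[2]), reg, t_abs)
  ci <- pg$c
  if (any(!is.finite(ci)) || any(ci <= 0))
    return(if (grad) c(NA, NA) else 1e10)
  r <- (dv - ci) / (sigma * ci)
  if (!grad)
    return(sum(log(2 * pi) + 2 * log(sigma * ci) + r^2) +
             sum(log(2 * pi) + 2 * log(omega) + (eta / omega)^2))
  dq_dc <- 2 / ci - 2 * r * dv / (sigma * ci^2)
  c(sum(dq_dc * pg$dc1), sum(dq_dc * pg$dc2)) + 2 * eta / omega^2
}

# Laplace approximation to -2 log of the marginal likelihood of one subject.
pk_laplace_subject <- function(theta, sub, eta_start = c(0, 0)) {
  ka <- exp(theta[1]); cl <- exp(theta[2]); vd <- exp(theta[3])
  omega <- pmax(exp(theta[4:5]), 1e-4); sigma <- exp(theta[6])
  t_abs <- (sub$reg$n_doses - 1) * sub$reg$tau_h + sub$t
  q <- function(eta) pk_joint_q(eta, ka, cl, vd, omega, sigma, sub$reg,
                                t_abs, sub$dv)
  gq <- function(eta) pk_joint_q(eta, ka, cl, vd, omega, sigma, sub$reg,
                                 t_abs, sub$dv, grad = TRUE)
  inner <- stats::optim(eta_start, q, gq, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 300))
  # Hessian of q by central differences of the analytic gradient.
  h <- matrix(0, 2, 2)
  step <- 1e-4
  for (k in 1:2) {
    e <- c(0, 0); e[k] <- step
    h[, k] <- (gq(inner$par + e) - gq(inner$par - e)) / (2 * step)
  }
  h <- (h + t(h)) / 2
  det_h <- h[1, 1] * h[2, 2] - h[1, 2] * h[2, 1]
  if (!is.finite(det_h) || det_h <= 0) return(list(neg2ll = 1e10, eta = inner$par))
  # -2 log integral exp(-q/2) d eta with d = 2:
  list(neg2ll = inner$value - 2 * log(2 * pi) + log(det_h) - 2 * log(2),
       eta = inner$par)
}

# Coarse grid heuristic for PK starting values from the arm-pooled mean
# profile: clearance from the mean AUC, (ka, kel) from a small grid search.
pk_start_heuristic <- function(subs) {
  t_h <- subs[[1]]$t
  mean_dv <- rowMeans(vapply(subs, function(s) s$dv[order(s$t)], numeric(length(t_h))))
  reg <- subs[[1]]$reg
  auc <- auc_linear_trapezoid(sort(t_h), mean_dv) * 24 / max(t_h)  # crude tau scale
  cl0 <- 1000 * reg$dose_amount / max(auc, 1e-6)
  best <- c(ka = 0.3, kel = 0.5, sse = Inf)
  for (ka in c(0.1, 0.2, 0.4, 0.8)) for (ke in c(0.15, 0.3, 0.6, 1.2)) {
    if (abs(ka - ke) < 1e-6) next
    vd <- cl0 / ke
    pred <- pk_pred_subject(ka, cl0, vd, reg, sort(t_h))
    sse <- sum((log(pmax(pred, 1e-9)) - log(pmax(mean_dv, 1e-9)))^2)
    if (sse < best["sse"]) best <- c(ka = ka, kel = ke, sse = sse)
  }
  c(log(best[["ka"]]), log(cl0), log(cl0 / best[["kel"]]),
    log(0.3), log(0.3), log(0.25))
}

#' Fit the PK mixed-effects model
#'
#' Nonlinear mixed-effects fit of the one-compartment oral model to
#' steady-state concentration records: fixed effects Ka, CL/F, Vd/F
#' (log-parameterized), log-normal inter-individual variability on CL and Vd,
#' and a proportional residual error. The marginal likelihood is approximated
#' by the Laplace method at the conditional modes of the subject-level random
#' effects (the closest tractable analogue of first-order conditional
#' estimation); standard errors come from the numerical Hessian of the
#' marginal -2 log-likelihood. Empirical Bayes estimates (the conditional
#' modes) and their shrinkage, 100 * (1 - SD(EBE)/omega), are reported.
#'
#' @param ds A [study_dataset()] with concentration records (DVID 1) and a
#'   dosing regimen for each sampled arm.
#' @param n_starts Number of deterministic multistart points (1-5).
#' @return Object of class `fit_result` with elements `estimates` (ka, cl_f,
#'   vd_f, omega_cl, omega_vd, sigma_prop), `se`, `rse_percent`, `ofv`,
#'   `eta` (per-subject EBEs), `shrinkage`, `converged`, `n_obs`,
#'   `n_subjects`, and `params` (the fitted [pk_params()]).
#' @export
fit_pk_nlme <- function(ds, n_starts = 5) {
  recs <- obs_records(ds, 1L)
  if (!nrow(recs)) stopf("no concentration records to fit")
  subs <- lapply(split(recs, recs$ID), function(s) {
    s <- s[order(s$TIME), ]
    reg <- ds$regimens[[s$ARM[1]]]
    if (is.null(reg)) stopf("no dosing regimen for arm %s", s$ARM[1])
    list(id = s$ID[1], t = s$TIME, dv = s$DV, reg = reg)
  })
  if (length(subs) < 2 || any(vapply(subs, function(s) length(s$t), 1L) < 2))
    stopf("need at least 2 subjects with at least 2 observations each")

  eta_warm <- new.env(parent = emptyenv())
  ofv <- function(theta) {
    tot <- 0
    for (s in subs) {
      w <- get0(s$id, envir = eta_warm, ifnotfound = c(0, 0))
      lp <- pk_laplace_subject(theta, s, eta_start = w)
      assign(s$id, lp$eta, envir = eta_warm)
      tot <- tot + lp$neg2ll
    }
    tot
  }

  start <- pk_start_heuristic(subs)
  lower <- c(rep(log(1e-3), 3), rep(log(1e-3), 2), log(1e-4))
  upper <- c(rep(log(1e4), 3), rep(log(5), 2), log(5))
  best <- run_multistart(ofv, start, lower, upper, n_starts)

  theta <- best$par
  est <- c(ka = exp(theta[1]), cl_f = exp(theta[2]), vd_f = exp(theta[3]),
           omega_cl = exp(theta[4]), omega_vd = exp(theta[5]),
           sigma_prop = exp(theta[6]))
  ses <- se_from_hessian(ofv, theta, est)
  names(ses$se) <- names(ses$rse_percent) <- names(est)

  eta <- t(vapply(subs, function(s)
    pk_laplace_subject(theta, s, get0(s$id, envir = eta_warm,
                                      ifnotfound = c(0, 0)))$eta, numeric(2)))
  eta_df <- data.frame(ID = vapply(subs, `[[`, "", "id"),
                       eta_cl = eta[, 1], eta_vd = eta[, 2],
                       row.names = NULL, stringsAsFactors = FALSE)
  shrink <- c(cl = 100 * (1 - stats::sd(eta[, 1]) / est[["omega_cl"]]),
              vd = 100 * (1 - stats::sd(eta[, 2]) / est[["omega_vd"]]))

  new_fit_result("pk", est, ses$se, ses$rse_percent, best$objective,
                 converged = best$convergence == 0,
                 n_obs = nrow(recs), n_subjects = length(subs),
                 eta = eta_df, shrinkage = shrink,
                 params = pk_params(est[["ka"]], est[["cl_f"]], est[["vd_f"]],
                                    est[["omega_cl"]], est[["omega_vd"]],
                                    est[["sigma_prop"]]))
}

# ---- pooled PD fits -------------------------------------------------------

# Typical-curve predictions for a set of tumor records sharing one arm.
pd_pred_for_days <- function(pk, pd, regimen, days, rtol = 1e-8) {
  sim <- simulate_arm_at(pk, pd, regimen, sort(unique(days)), rtol = rtol,
                         atol = 1e-10)
  sim$v[match(days, sim$t_day)]
}

# Tabulated typical concentration forcing on a fine day grid. The drug
# input does not depend on the PD parameters, so it is built once per fit;
# the solver interpolates it linearly as a forcing function.
conc_table <- function(pk, regimen, t_max_day, dt = 0.005) {
  grid <- seq(0, t_max_day + 1, by = dt)
  if (is.null(regimen)) return(cbind(c(0, t_max_day + 1), c(0, 0)))
  cbind(grid, conc_forcing(pk, regimen)(grid))
}

# Lean TGI integration used inside optimization loops: identical dynamics
# to simulate_arm, with the right-hand side compiled and the concentration
# supplied as an interpolated forcing table.
tgi_v_at_days <- function(days, v0, k1, keff, l0, l1, phi, ftable,
                          rtol = 1e-7, atol = 1e-9) {
  grid <- sort(unique(c(0, days)))
  out <- tryCatch(
    deSolve::lsoda(c(v0, 0, 0, 0), grid, func = "tgi_derivs",
                   parms = c(l0, l1, phi, keff, k1),
                   dllname = "xenopkpd", initfunc = "tgi_initmod",
                   initforc = "tgi_initforc", forcings = ftable,
                   fcontrol = list(method = "linear", rule = 2),
                   rtol = rtol, atol = atol),
    error = function(e) NULL)
  if (is.null(out) || attr(out, "istate")[1] < 0) return(NULL)
  v <- rowSums(out[, -1, drop = FALSE])
  v[match(days, out[, 1])]
}

#' Fit the unperturbed tumor growth model (control arm)
#'
#' Pooled maximum-likelihood fit of the Simeoni growth model (lambda0,
#' lambda1, V0; phi fixed) to control-arm tumor volumes under a proportional
#' residual error. No random effects are used: the profiles are pooled, and
#' only the typical curve and the residual SD are estimated.
#'
#' @param ds A [study_dataset()] containing CONTROL tumor records (DVID 2).
#' @param phi Shape factor, fixed (default 20).
#' @param n_starts Deterministic multistart points (1-5).
#' @return A `fit_result` with estimates lambda0, lambda1, v0, sigma_prop
#'   and the fitted control [pd_params()] in `$params`.
#' @export
fit_natural_growth <- function(ds, phi = 20, n_starts = 5) {
  recs <- obs_records(ds, 2L, arms = "CONTROL")
  if (length(unique(recs$TIME)) < 4)
    stopf("identifiability error: need at least 4 distinct observation days")
  days <- recs$TIME
  dv <- recs$DV
  zero_forcing <- conc_table(NULL, NULL, max(days))

  # Heuristics: early log-slope of the day means -> lambda0, late slope ->
  # lambda1, back-extrapolated intercept -> V0.
  mu <- tapply(dv, days, mean)
  ud <- as.numeric(names(mu))
  k <- max(2, ceiling(length(ud) / 3))
  early <- stats::lm(log(pmax(mu[seq_len(k)], 1e-3)) ~ ud[seq_len(k)])
  late_i <- seq(length(ud) - k + 1, length(ud))
  late <- stats::lm(mu[late_i] ~ ud[late_i])
  l0_0 <- max(stats::coef(early)[2], 0.01)
  v0_0 <- max(exp(stats::coef(early)[1]), 0.5)
  l1_0 <- max(stats::coef(late)[2], 1)
  start <- log(c(l0_0, l1_0, v0_0, 0.2))

  ofv <- function(theta) {
    pred <- tgi_v_at_days(days, v0 = exp(theta[3]), k1 = 0, keff = 0,
                          l0 = exp(theta[1]), l1 = exp(theta[2]), phi = phi,
                          ftable = zero_forcing)
    if (is.null(pred) || any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
    neg2ll_proportional(pred, dv, exp(theta[4]))
  }
  lower <- c(log(1e-4), log(1e-2), log(1e-2), log(1e-6))
  upper <- c(log(5), log(1e4), log(1e4), log(2))
  best <- run_multistart(ofv, start, lower, upper, n_starts)

  est <- c(lambda0 = exp(best$par[1]), lambda1 = exp(best$par[2]),
           v0 = exp(best$par[3]), sigma_prop = exp(best$par[4]))
  ses <- se_from_hessian(ofv, best$par, est)
  names(ses$se) <- names(ses$rse_percent) <- names(est)
  new_fit_result("growth", est, ses$se, ses$rse_percent, best$objective,
                 converged = best$convergence == 0, n_obs = length(dv),
                 n_subjects = length(unique(recs$ID)),
                 params = pd_params(est[["lambda0"]], est[["lambda1"]],
                                    phi = phi, v0 = est[["v0"]],
                                    sigma_prop = est[["sigma_prop"]]))
}

#' Fit the tumor-growth-inhibition model (treated arms)
#'
#' Joint pooled maximum-likelihood fit of V0, k1, the drug potency and the
#' synergy factor to the monotherapy and combination arms, with the growth
#' rates fixed at the control-fit values and the typical (no-IIV) PK profile
#' as the drug input. The combination arm carries `hadb1_flag = 1`, so the
#' synergy factor is identified by the contrast between the two arms; with
#' only one treated arm present it is reported as not identifiable (`NA`).
#'
#' @param ds A [study_dataset()] with AFT and/or COMB tumor records and
#'   their dosing regimens.
#' @param growth Named vector or list with `lambda0` and `lambda1` (fixed).
#' @param pk Typical [pk_params()] (e.g. from [fit_pk_nlme()]).
#' @param phi Shape factor, fixed (default 20).
#' @param n_starts Deterministic multistart points (1-5).
#' @return A `fit_result` with estimates v0, k1, k_aft, alpha_syn,
#'   sigma_prop.
#' @export
fit_tgi <- function(ds, growth, pk, phi = 20, n_starts = 5) {
  recs <- obs_records(ds, 2L, arms = c("AFT", "COMB"))
  arms <- sort(unique(recs$ARM))
  if (!length(arms)) stopf("no treated-arm tumor records to fit")
  both_arms <- length(arms) == 2
  l0 <- growth[["lambda0"]]; l1 <- growth[["lambda1"]]
  by_arm <- split(recs, recs$ARM)

  # Heuristic starts: V0 near the control back-extrapolation scale, transit
  # rate around 1/day, potency scaled so the kill rate at the average
  # steady-state exposure is comparable to lambda0.
  reg0 <- ds$regimens[[arms[1]]]
  cavg <- css_avg(pk, reg0)
  start <- c(log(max(min(recs$DV), 5)), log(1), log(l0 / max(cavg, 1)), log(1 + 0.2),
             log(0.2))

  t_max <- max(recs$TIME)
  cf_by_arm <- lapply(stats::setNames(arms, arms), function(arm)
    conc_table(pk, ds$regimens[[arm]], t_max))
  ofv <- function(theta) {
    v0 <- exp(theta[1]); k1 <- exp(theta[2]); kaft <- exp(theta[3])
    alpha <- exp(theta[4]) - 1; sigma <- exp(theta[5])
    tot <- 0
    for (arm in arms) {
      a <- by_arm[[arm]]
      keff <- kaft * (1 + alpha * (arm == "COMB"))
      pred <- tgi_v_at_days(a$TIME, v0, k1, keff, l0, l1, phi, cf_by_arm[[arm]])
      if (is.null(pred) || any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
      tot <- tot + neg2ll_proportional(pred, a$DV, sigma)
    }
    tot
  }

  lower <- c(log(1e-2), log(1e-2), log(1e-7), log(1e-3), log(1e-6))
  upper <- c(log(1e4), log(50), log(1), log(20), log(2))
  if (!both_arms) {  # alpha not identifiable: pin at 0 (factor 1)
    lower[4] <- upper[4] <- 0
    start[4] <- 0
  }
  best <- run_multistart(ofv, start, lower, upper, n_starts)

  est <- c(v0 = exp(best$par[1]), k1 = exp(best$par[2]),
           k_aft = exp(best$par[3]),
           alpha_syn = if (both_arms) exp(best$par[4]) - 1 else NA_real_,
           sigma_prop = exp(best$par[5]))
  ses <- se_from_hessian(ofv, best$par, exp(best$par))
  se <- c(ses$se[1:3], if (both_arms) ses$se[4] else NA_real_, ses$se[5])
  rse <- c(ses$rse_percent[1:3],
           if (both_arms) 100 * ses$se[4] / abs(est[["alpha_syn"]]) else NA_real_,
           ses$rse_percent[5])
  names(se) <- names(rse) <- names(est)
  new_fit_result("tgi", est, se, rse, best$objective,
                 converged = best$convergence == 0, n_obs = nrow(recs),
                 n_subjects = length(unique(recs$ID)),
                 growth_fixed = c(lambda0 = l0, lambda1 = l1, phi = phi))
}

#' Sequential PK/PD estimation workflow
#'
#' Reproduces the sequential model-building strategy: (1) mixed-effects fit
#' of the PK model to the concentration data; (2) pooled fit of the
#' unperturbed growth model to the control arm; (3) pooled fit of the
#' tumor-growth-inhibition model to the treated arms with the growth rates
#' fixed and the typical fitted PK profile as drug input. Secondary
#' parameters are derived from the estimates: the switching threshold W_th =
#' lambda1/lambda0, the eradication thresholds C_T = lambda0/K (monotherapy
#' and combination), the potency fold 1 + alpha_syn, and the model-predicted
#' average steady-state concentration.
#'
#' @param ds A full [study_dataset()] with PK and PD records.
#' @param n_starts Deterministic multistart points passed to each stage.
#' @return Object of class `sequential_fit`: list with `pk`, `growth`,
#'   `tgi` fit results and a `secondary` named numeric vector.
#' @export
sequential_workflow <- function(ds, n_starts = 5) {
  pk_fit <- fit_pk_nlme(ds, n_starts = n_starts)
  growth_fit <- fit_natural_growth(ds, n_starts = n_starts)
  tgi_fit <- fit_tgi(ds, growth = growth_fit$estimates, pk = pk_fit$params,
                     n_starts = n_starts)
  reg <- ds$regimens[["AFT"]] %||% ds$regimens[["COMB"]]
  alpha <- tgi_fit$estimates[["alpha_syn"]]
  l0 <- growth_fit$estimates[["lambda0"]]
  kaft <- tgi_fit$estimates[["k_aft"]]
  secondary <- c(
    w_th = growth_fit$estimates[["lambda1"]] / l0,
    c_t_mono = l0 / kaft,
    c_t_comb = if (is.na(alpha)) NA_real_ else l0 / (kaft * (1 + alpha)),
    potency_fold = 1 + alpha,
    cavg_ss = if (is.null(reg)) NA_real_ else css_avg(pk_fit$params, reg))
  structure(list(pk = pk_fit, growth = growth_fit, tgi = tgi_fit,
                 secondary = secondary),
            class = "sequential_fit")
}

#' @export
print.sequential_fit <- function(x, ...) {
  cat("Sequential PK/PD fit\n\n-- PK stage --\n"); print(x$pk)
  cat("\n-- Natural growth stage --\n"); print(x$growth)
  cat("\n-- Tumor growth inhibition stage --\n"); print(x$tgi)
  cat("\nSecondary parameters:\n")
  print(round(x$secondary, 4))
  invisible(x)
}
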