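# Percentiles use linear interpolation between order statistics (type 7);
# VPC dialects differ between tools, so the choice is fixed and documented.
pctl <- function(x, probs) unname(stats::quantile(x, probs, type = 7, names = FALSE))

#' Study model container
#'
#' Bundles the fitted (or true) PK parameters with the control-arm and
#' treated-arm PD parameters, so the full system can be simulated arm by
#' arm: CONTROL and HADB1 follow the unperturbed control dynamics (the
#' herbal monotherapy showed minimal suppression and contributes no modeled
#' drug effect), AFT uses the treated parameters with `hadb1_flag = 0`, COMB
#' with `hadb1_flag = 1`.
#'
#' @param pk [pk_params()].
#' @param pd_control Control-arm [pd_params()].
#' @param pd_treated Treated-arm [pd_params()] (the flag is set per arm).
#' @return Object of class `study_model`.
#' @export
study_model <- function(pk, pd_control, pd_treated) {
  structure(list(pk = pk, pd_control = pd_control, pd_treated = pd_treated),
            class = "study_model")
}

# PD parameters and regimen for one arm of a study model.
arm_dynamics <- function(model, arm, regimens) {
  if (arm %in% c("CONTROL", "HADB1"))
    return(list(pd = model$pd_control, reg = NULL))
  pd <- model$pd_treated
  pd$hadb1_flag <- as.integer(arm == "COMB")
  list(pd = pd, reg = regimens[[arm]])
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicate studies at the observation design of `data`,
#' computes the 5th/50th/95th percentile of the simulated values in each
#' time bin for every replicate, and reports the 2.5-97.5 percentile
#' envelope of each statistic across replicates next to the observed
#' percentiles. Concentration data are binned at their exact nominal sample
#' times; tumor data by study day and arm. PK replicates redraw both the
#' inter-individual random effects and the residual error; tumor replicates
#' redraw the residual error only, matching the pooled PD model.
#'
#' @param object A [pk_params()] (concentration VPC) or [study_model()]
#'   (tumor-volume VPC).
#' @param data A [study_dataset()] providing the observation design.
#' @param n_rep Number of replicate studies (default 1000; below 100 the
#'   result is flagged with `low_replicates = TRUE`).
#' @param seed Optional RNG seed for reproducibility.
#' @param ... Unused.
#' @return Object of class `vpc_result`: a data frame with one row per bin
#'   (`arm`, `bin`, `n_obs`, observed `obs_p5/p50/p95`, and simulated bands
#'   `p5_lo/p5_hi`, `p50_lo/p50_hi`, `p95_lo/p95_hi`), with attributes
#'   `n_replicates` and `low_replicates`.
#' @export
vpc <- function(object, data, n_rep = 1000, seed = NULL, ...) UseMethod("vpc")

vpc_assemble <- function(obs_df, sim_fun, n_rep, seed) {
  if (!is.null(seed)) set.seed(seed)
  bins <- split(seq_len(nrow(obs_df)), list(obs_df$arm, obs_df$bin), drop = TRUE)
  stat_obs <- t(vapply(bins, function(i) pctl(obs_df$value[i], c(.05, .5, .95)),
                       numeric(3)))
  sims <- array(NA_real_, dim = c(length(bins), 3, n_rep))
  for (r in seq_len(n_rep)) {
    v <- sim_fun()
    sims[, , r] <- t(vapply(bins, function(i) pctl(v[i], c(.05, .5, .95)),
                            numeric(3)))
  }
  band <- function(k, pr) apply(sims[, k, , drop = FALSE], 1,
                                function(x) pctl(x, pr))
  out <- data.frame(
    arm = vapply(bins, function(i) obs_df$arm[i[1]], ""),
    bin = vapply(bins, function(i) obs_df$bin[i[1]], 0),
    n_obs = lengths(bins),
    obs_p5 = stat_obs[, 1], obs_p50 = stat_obs[, 2], obs_p95 = stat_obs[, 3],
    p5_lo = band(1, .025), p5_hi = band(1, .975),
    p50_lo = band(2, .025), p50_hi = band(2, .975),
    p95_lo = band(3, .025), p95_hi = band(3, .975),
    row.names = NULL)
  out <- out[order(out$arm, out$bin), ]
  rownames(out) <- NULL
  structure(out, class = c("vpc_result", "data.frame"),
            n_replicates = n_rep, low_replicates = n_rep < 100)
}

#' @rdname vpc
#' @export
vpc.pk_params <- function(object, data, n_rep = 1000, seed = NULL, ...) {
  recs <- obs_records(data, 1L)
  if (!nrow(recs)) stopf("no concentration records for the VPC")
  ids <- unique(recs$ID)
  design <- lapply(ids, function(id) {
    s <- recs[recs$ID == id, ]
    reg <- data$regimens[[s$ARM[1]]]
    if (is.null(reg)) stopf("no dosing regimen for arm %s", s$ARM[1])
    list(t = s$TIME, reg = reg)
  })
  obs_df <- data.frame(arm = "ALL", bin = recs$TIME, value = recs$DV)
  sim_fun <- function() {
    unlist(lapply(design, function(d) {
      eta <- stats::rnorm(2, 0, c(object$omega_cl, object$omega_vd))
      pred <- pk_pred_subject(object$ka, object$cl_f * exp(eta[1]),
                              object$vd_f * exp(eta[2]), d$reg, d$t)
      pmax(pred * (1 + stats::rnorm(length(pred), 0, object$sigma_prop)), 0)
    }), use.names = FALSE)
  }
  vpc_assemble(obs_df, sim_fun, n_rep, seed)
}

#' @rdname vpc
#' @export
vpc.study_model <- function(object, data, n_rep = 1000, seed = NULL, ...) {
  recs <- obs_records(data, 2L)
  if (!nrow(recs)) stopf("no tumor records for the VPC")
  recs <- recs[order(recs$ARM, recs$ID, recs$TIME), ]
  typ <- list()
  for (arm in unique(recs$ARM)) {
    dyn <- arm_dynamics(object, arm, data$regimens)
    days <- recs$TIME[recs$ARM == arm]
    typ[[arm]] <- pd_pred_for_days(object$pk, dyn$pd, dyn$reg, days)
  }
  typical <- unlist(typ[unique(recs$ARM)], use.names = FALSE)
  sigma <- ifelse(recs$ARM %in% c("AFT", "COMB"),
                  object$pd_treated$sigma_prop, object$pd_control$sigma_prop)
  obs_df <- data.frame(arm = recs$ARM, bin = recs$TIME, value = recs$DV)
  sim_fun <- function()
    pmax(typical * (1 + stats::rnorm(length(typical), 0, sigma)), 0.1)
  vpc_assemble(obs_df, sim_fun, n_rep, seed)
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d bins, %d replicates%s\n", nrow(x),
              attr(x, "n_replicates"),
              if (isTRUE(attr(x, "low_replicates"))) " (warning: < 100 replicates)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Fraction of observations inside the simulated 90% prediction band
#'
#' Utility for calibration checks: the share of observed values falling
#' between the per-bin 5th and 95th simulated percentiles (here taken as the
#' centers of the VPC bands).
#'
#' @param object,data,n_rep,seed As in [vpc()].
#' @return Coverage as a fraction in [0, 1].
#' @export
vpc_coverage <- function(object, data, n_rep = 500, seed = NULL) {
  recs <- if (inherits(object, "pk_params")) obs_records(data, 1L)
          else {
            r <- obs_records(data, 2L)
            r[order(r$ARM, r$ID, r$TIME), ]
          }
  v <- vpc(object, data, n_rep = n_rep, seed = seed)
  lo <- (v$p5_lo + v$p5_hi) / 2
  hi <- (v$p95_lo + v$p95_hi) / 2
  arm <- if (inherits(object, "pk_params")) rep("ALL", nrow(recs)) else recs$ARM
  key <- match(paste(arm, recs$TIME), paste(v$arm, v$bin))
  mean(recs$DV >= lo[key] & recs$DV <= hi[key])
}

#' Goodness-of-fit table
#'
#' One row per observation with the population prediction, the individual
#' prediction (PK stage only, from the empirical Bayes estimates), and the
#' standardized proportional residual (obs - pred) / (sigma * pred).
#'
#' @param fit A `fit_result` from [fit_pk_nlme()], [fit_natural_growth()] or
#'   [fit_tgi()], or a `sequential_fit` (rows for all three stages).
#' @param ds The [study_dataset()] the model was fitted to.
#' @param pk Typical [pk_params()], required for a `tgi` stage fit.
#' @return Data frame with columns `stage`, `ID`, `ARM`, `time`, `obs`,
#'   `pred`, `ipred`, `residual`.
#' @export
gof_table <- function(fit, ds, pk = NULL) {
  if (inherits(fit, "sequential_fit")) {
    return(rbind(gof_table(fit$pk, ds),
                 gof_table(fit$growth, ds),
                 gof_table(fit$tgi, ds, pk = fit$pk$params)))
  }
  if (!isTRUE(fit$converged)) stopf("goodness-of-fit requires a converged fit")
  sigma <- fit$estimates[["sigma_prop"]]
  if (fit$stage == "pk") {
    recs <- obs_records(ds, 1L)
    p <- fit$params
    pred <- ipred <- numeric(nrow(recs))
    for (id in unique(recs$ID)) {
      i <- recs$ID == id
      reg <- ds$regimens[[recs$ARM[i][1]]]
      eta <- fit$eta[fit$eta$ID == id, ]
      pred[i] <- pk_pred_subject(p$ka, p$cl_f, p$vd_f, reg, recs$TIME[i])
      ipred[i] <- pk_pred_subject(p$ka, p$cl_f * exp(eta$eta_cl),
                                  p$vd_f * exp(eta$eta_vd), reg, recs$TIME[i])
    }
  } else if (fit$stage == "growth") {
    recs <- obs_records(ds, 2L, arms = "CONTROL")
    pred <- pd_pred_for_days(NULL, fit$params, NULL, recs$TIME)
    ipred <- rep(NA_real_, nrow(recs))
  } else {
    if (is.null(pk)) stopf("a tgi-stage GOF table needs the typical PK parameters")
    recs <- obs_records(ds, 2L, arms = c("AFT", "COMB"))
    recs <- recs[order(recs$ARM, recs$ID, recs$TIME), ]
    g <- fit$growth_fixed
    pred <- numeric(nrow(recs))
    for (arm in unique(recs$ARM)) {
      i <- recs$ARM == arm
      est <- fit$estimates
      alpha <- if (is.na(est[["alpha_syn"]])) 0 else est[["alpha_syn"]]
      pd <- pd_params(g[["lambda0"]], g[["lambda1"]], phi = g[["phi"]],
                      v0 = est[["v0"]], k1 = est[["k1"]], k_aft = est[["k_aft"]],
                      alpha_syn = alpha, hadb1_flag = as.integer(arm == "COMB"))
      pred[i] <- pd_pred_for_days(pk, pd, ds$regimens[[arm]], recs$TIME[i])
    }
    ipred <- rep(NA_real_, nrow(recs))
  }
  data.frame(stage = fit$stage, ID = recs$ID, ARM = recs$ARM, time = recs$TIME,
             obs = recs$DV, pred = pred, ipred = ipred,
             residual = (recs$DV - pred) / (sigma * pred),
             row.names = NULL, stringsAsFactors = FALSE)
}
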