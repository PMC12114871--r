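#' Run the full reference analysis end to end
#'
#' Self-contained driver tying all stages together:
#' \enumerate{
#'   \item Deterministic simulation of the three arms at the reference
#'     parameter values (all arms started from the treated-group baseline
#'     volume so they are compared from a common baseline; treatment daily
#'     from day 7 for 30 doses) and the first crossing of the 350 mm^3
#'     tumor-volume threshold per arm.
#'   \item Secondary parameters at the reference estimates: switching
#'     threshold W_th, eradication thresholds C_T (monotherapy and
#'     combination), potency fold 1 + alpha_syn, and the average
#'     steady-state concentration both model-predicted and from the observed
#'     steady-state AUC.
#'   \item A synthetic study at the default design, the sequential
#'     estimation workflow on it, and a parameter-recovery table.
#'   \item A tumor-volume VPC of the fitted model against the synthetic
#'     data, with its 90%-band coverage.
#' }
#'
#' @param outdir Output directory (created if missing); receives a JSON
#'   bundle and CSV tables. `NULL` skips writing.
#' @param seed Master seed for the synthetic study and the VPC.
#' @param auc_ss Observed steady-state AUC (ng*h/mL) used for the model-free
#'   average concentration; defaults to the reported monotherapy value.
#' @param threshold Tumor-volume threshold (mm^3) for the crossing times.
#' @param n_starts Multistart points per estimation stage.
#' @param n_rep_vpc VPC replicates.
#' @param n_profiles Tumor profiles per arm of the synthetic study (the
#'   study default is 100; smaller values give a faster, noisier report).
#' @return List of class `study_report` with elements `crossings`,
#'   `secondary`, `fit`, `recovery`, `vpc`, `vpc_coverage`, `seed`.
#' @export
reproduce_study <- function(outdir = NULL, seed = 1, auc_ss = 287.63,
                            threshold = 350, n_starts = 5, n_rep_vpc = 500,
                            n_profiles = 100) {
  pk <- reference_pk_params()
  pd_treated <- reference_pd_params("treated")
  reg <- reference_regimen(start_day = 7)
  # Common baseline across simulated arms: the treated-group V0.
  pd_control_sim <- pd_params(lambda0 = pd_treated$lambda0,
                              lambda1 = pd_treated$lambda1,
                              phi = pd_treated$phi, v0 = pd_treated$v0)
  arms <- list(
    CONTROL = simulate_arm(pk, pd_control_sim, NULL, t_end = 40, dt_out = 0.05),
    AFT = simulate_arm(pk, pd_treated, reg, t_end = 40, dt_out = 0.05),
    COMB = {
      pd_comb <- pd_treated; pd_comb$hadb1_flag <- 1L
      simulate_arm(pk, pd_comb, reg, t_end = 40, dt_out = 0.05)
    })
  crossings <- lapply(arms, time_to_threshold, threshold = threshold)
  crossings_df <- data.frame(
    arm = names(crossings),
    day = vapply(crossings, `[[`, 0, "day"),
    day_raw = vapply(crossings, `[[`, 0, "day_raw"), row.names = NULL)

  secondary <- c(
    w_th = switching_threshold(pd_treated),
    c_t_mono = threshold_concentration(pd_treated),
    c_t_comb = threshold_concentration(pd_treated, combination = TRUE),
    potency_fold = 1 + pd_treated$alpha_syn,
    cavg_ss_model = css_avg(pk, reg),
    cavg_ss_observed = cavg_from_auc(auc_ss, reg$tau_h))

  cfg <- synthetic_config(seed = seed, n_pd_profiles_per_arm = n_profiles)
  ds <- gen_full_study(cfg)
  fit <- sequential_workflow(ds, n_starts = n_starts)
  truth <- c(ka = cfg$true_pk$ka, cl_f = cfg$true_pk$cl_f,
             vd_f = cfg$true_pk$vd_f,
             lambda0 = cfg$true_pd_control$lambda0,
             lambda1 = cfg$true_pd_control$lambda1,
             v0_control = cfg$true_pd_control$v0,
             v0_treated = cfg$true_pd_treated$v0,
             k1 = cfg$true_pd_treated$k1,
             k_aft = cfg$true_pd_treated$k_aft,
             alpha_syn = cfg$true_pd_treated$alpha_syn)
  est <- c(fit$pk$estimates[c("ka", "cl_f", "vd_f")],
           fit$growth$estimates[c("lambda0", "lambda1")],
           v0_control = unname(fit$growth$estimates[["v0"]]),
           v0_treated = unname(fit$tgi$estimates[["v0"]]),
           fit$tgi$estimates[c("k1", "k_aft", "alpha_syn")])
  recovery <- data.frame(parameter = names(truth), truth = unname(truth),
                         estimate = unname(est[names(truth)]),
                         rel_error_pct = 100 * (unname(est[names(truth)]) - unname(truth)) /
                           unname(truth))

  model <- study_model(fit$pk$params,
                       fit$growth$params,
                       pd_params(fit$growth$estimates[["lambda0"]],
                                 fit$growth$estimates[["lambda1"]], phi = 20,
                                 v0 = fit$tgi$estimates[["v0"]],
                                 k1 = fit$tgi$estimates[["k1"]],
                                 k_aft = fit$tgi$estimates[["k_aft"]],
                                 alpha_syn = fit$tgi$estimates[["alpha_syn"]],
                                 sigma_prop = fit$tgi$estimates[["sigma_prop"]]))
  v <- vpc(model, ds, n_rep = n_rep_vpc, seed = child_seed(seed, "vpc"))
  cov <- vpc_coverage(model, ds, n_rep = n_rep_vpc,
                      seed = child_seed(seed, "vpc_cov"))

  report <- structure(list(crossings = crossings_df, secondary = secondary,
                           fit = fit, recovery = recovery, vpc = v,
                           vpc_coverage = cov, seed = seed),
                      class = "study_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(crossings_df, file.path(outdir, "crossings.csv"),
                     row.names = FALSE)
    utils::write.csv(recovery, file.path(outdir, "recovery.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(v), file.path(outdir, "vpc.csv"),
                     row.names = FALSE)
    for (a in names(arms))
      utils::write.csv(as.data.frame(arms[[a]]),
                       file.path(outdir, sprintf("sim_%s.csv", a)),
                       row.names = FALSE)
    bundle <- list(
      seed = seed,
      crossings = stats::setNames(as.list(crossings_df$day), crossings_df$arm),
      secondary = as.list(secondary),
      estimates = list(pk = as.list(fit$pk$estimates),
                       growth = as.list(fit$growth$estimates),
                       tgi = as.list(fit$tgi$estimates),
                       secondary = as.list(fit$secondary)),
      vpc_coverage = cov)
    jsonlite::write_json(bundle, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Reference analysis report (seed", x$seed, ")\n\n")
  cat(sprintf("Time to %s threshold:\n", "tumor-volume"))
  print(x$crossings)
  cat("\nSecondary parameters:\n"); print(round(x$secondary, 3))
  cat("\nParameter recovery on the synthetic study:\n")
  print(transform(x$recovery, truth = signif(truth, 4),
                  estimate = signif(estimate, 4),
                  rel_error_pct = round(rel_error_pct, 2)))
  cat(sprintf("\nVPC 90%%-band coverage: %.1f%%\n", 100 * x$vpc_coverage))
  invisible(x)
}
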