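#' Configuration of the synthetic xenograft study
#'
#' Describes the study design the generator emulates. The defaults reproduce
#' the source experiment: 2 PK arms (monotherapy and combination) of 6 mice
#' sampled at 0.5, 2, 4 and 8 h post-dose on day 30 of daily 10 mg/kg oral
#' dosing; and 4 PD arms (control, monotherapy, herbal-only, combination)
#' with 100 tumor profiles per arm observed daily from day 7 to day 37,
#' treatment starting on day 7 post-inoculation. True parameters default to
#' the reference estimates ([reference_pk_params()], [reference_pd_params()]).
#'
#' @param seed Master seed; per-arm child streams are derived
#'   deterministically from it, so adding an arm never perturbs the others.
#' @param n_pk_per_arm Animals per PK arm.
#' @param pk_sample_times_h Post-dose sampling times (hours), increasing.
#' @param n_pd_profiles_per_arm Tumor profiles per PD arm.
#' @param pd_obs_days Tumor observation days (study clock).
#' @param arms Arm labels to generate.
#' @param true_pk True [pk_params()].
#' @param true_pd_control,true_pd_treated True [pd_params()] per group.
#' @param treatment_start_day First dosing day (study clock).
#' @param dose,tau_h,n_doses Dosing regimen of the modeled drug.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_pk_per_arm = 6,
                             pk_sample_times_h = c(0.5, 2, 4, 8),
                             n_pd_profiles_per_arm = 100,
                             pd_obs_days = 7:37,
                             arms = c("CONTROL", "AFT", "HADB1", "COMB"),
                             true_pk = reference_pk_params(),
                             true_pd_control = reference_pd_params("control"),
                             true_pd_treated = reference_pd_params("treated"),
                             treatment_start_day = 7,
                             dose = 10, tau_h = 24, n_doses = 30) {
  if (n_pk_per_arm < 1 || n_pd_profiles_per_arm < 1)
    stopf("subject counts must be at least 1")
  if (any(pk_sample_times_h <= 0) || any(diff(pk_sample_times_h) <= 0))
    stopf("pk_sample_times_h must be positive and increasing")
  if (!all(arms %in% STUDY_ARMS))
    stopf("unknown arm label(s): %s", paste(setdiff(arms, STUDY_ARMS), collapse = ", "))
  structure(list(seed = seed, n_pk_per_arm = n_pk_per_arm,
                 pk_sample_times_h = pk_sample_times_h,
                 n_pd_profiles_per_arm = n_pd_profiles_per_arm,
                 pd_obs_days = pd_obs_days, arms = arms, true_pk = true_pk,
                 true_pd_control = true_pd_control,
                 true_pd_treated = true_pd_treated,
                 treatment_start_day = treatment_start_day,
                 dose = dose, tau_h = tau_h, n_doses = n_doses),
            class = "synthetic_config")
}

synth_regimen <- function(cfg)
  dose_regimen(cfg$dose, cfg$tau_h, cfg$n_doses, cfg$treatment_start_day)

#' Generate a synthetic steady-state PK dataset
#'
#' For each animal of the two dosed arms, draws log-normal inter-individual
#' deviations on CL and Vd, evaluates the day-30 post-dose concentrations at
#' the nominal sampling times, and applies proportional normal residual
#' error, obs = pred * (1 + eps). Negative draws are truncated at 0 and
#' counted in the metadata.
#'
#' @param cfg A [synthetic_config()].
#' @return A [study_dataset()] of concentration records (DVID 1).
#' @export
gen_pk_dataset <- function(cfg) {
  pk <- cfg$true_pk
  reg <- synth_regimen(cfg)
  pk_arms <- intersect(cfg$arms, DRUG_ARMS)
  rows <- list()
  n_trunc <- 0L
  for (arm in pk_arms) {
    set.seed(child_seed(cfg$seed, paste0("pk_", arm)))
    for (i in seq_len(cfg$n_pk_per_arm)) {
      eta <- stats::rnorm(2, 0, c(pk$omega_cl, pk$omega_vd))
      pred <- pk_pred_subject(pk$ka, pk$cl_f * exp(eta[1]),
                              pk$vd_f * exp(eta[2]), reg, cfg$pk_sample_times_h)
      obs <- pred * (1 + stats::rnorm(length(pred), 0, pk$sigma_prop))
      n_trunc <- n_trunc + sum(obs < 0)
      rows[[length(rows) + 1L]] <- data.frame(
        ID = sprintf("PK_%s_%02d", arm, i), TIME = cfg$pk_sample_times_h,
        DV = pmax(obs, 0), MDV = 0L, DVID = 1L, ARM = arm,
        stringsAsFactors = FALSE)
    }
  }
  regimens <- stats::setNames(rep(list(reg), length(pk_arms)), pk_arms)
  study_dataset(do.call(rbind, rows), regimens,
                metadata = list(seed = cfg$seed, n_truncated = n_trunc,
                                truth = list(pk = unclass(pk))))
}

# Arm-typical tumor curve under the generator's truth.
synth_typical_curve <- function(cfg, arm, days) {
  reg <- synth_regimen(cfg)
  if (arm %in% c("CONTROL", "HADB1"))
    return(pd_pred_for_days(NULL, cfg$true_pd_control, NULL, days))
  pd <- cfg$true_pd_treated
  pd$hadb1_flag <- as.integer(arm == "COMB")
  pd_pred_for_days(cfg$true_pk, pd, reg, days)
}

#' Generate a synthetic tumor-growth dataset
#'
#' Simulates the typical tumor-volume curve for each arm (the herbal-only
#' arm follows the control dynamics, reflecting its minimal observed
#' suppression), then draws profiles around it with proportional normal
#' noise at the group residual scale. Volumes are floored at 0.1 mm^3.
#'
#' @param cfg A [synthetic_config()].
#' @return A [study_dataset()] of tumor records (DVID 2).
#' @export
gen_pd_dataset <- function(cfg) {
  rows <- list()
  for (arm in cfg$arms) {
    typical <- synth_typical_curve(cfg, arm, cfg$pd_obs_days)
    sigma <- if (arm %in% DRUG_ARMS) cfg$true_pd_treated$sigma_prop
             else cfg$true_pd_control$sigma_prop
    set.seed(child_seed(cfg$seed, paste0("pd_", arm)))
    for (i in seq_len(cfg$n_pd_profiles_per_arm)) {
      obs <- typical * (1 + stats::rnorm(length(typical), 0, sigma))
      rows[[length(rows) + 1L]] <- data.frame(
        ID = sprintf("PD_%s_%03d", arm, i), TIME = cfg$pd_obs_days,
        DV = pmax(obs, 0.1), MDV = 0L, DVID = 2L, ARM = arm,
        stringsAsFactors = FALSE)
    }
  }
  pd_arms <- intersect(cfg$arms, DRUG_ARMS)
  regimens <- stats::setNames(rep(list(synth_regimen(cfg)), length(pd_arms)), pd_arms)
  study_dataset(do.call(rbind, rows), regimens,
                metadata = list(seed = cfg$seed,
                                truth = list(pd_control = unclass(cfg$true_pd_control),
                                             pd_treated = unclass(cfg$true_pd_treated))))
}

#' Generate the full synthetic study
#'
#' Concatenates the PK and PD datasets with consistent arm labels and a
#' single regimen per dosed arm; the metadata embeds the master seed and the
#' true generating parameters.
#'
#' @param cfg A [synthetic_config()].
#' @return A merged [study_dataset()].
#' @export
gen_full_study <- function(cfg) {
  pk_ds <- gen_pk_dataset(cfg)
  pd_ds <- gen_pd_dataset(cfg)
  study_dataset(rbind(pk_ds$records, pd_ds$records),
                regimens = utils::modifyList(pd_ds$regimens, pk_ds$regimens),
                metadata = list(seed = cfg$seed,
                                n_truncated_pk = pk_ds$metadata$n_truncated,
                                truth = list(pk = unclass(cfg$true_pk),
                                             pd_control = unclass(cfg$true_pd_control),
                                             pd_treated = unclass(cfg$true_pd_treated))))
}
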