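#' Reference parameter values from the xenograft study
#'
#' Typical parameter estimates reported for the afatinib xenograft
#' experiment: the one-compartment oral PK model (Ka 0.2 1/h, CL/F 24.5
#' L/h/kg, Vd/F 56.1 L/kg, IIV 30.9%/50.2% on CL and Vd, 29% proportional
#' error) and the Simeoni tumor-growth-inhibition model (lambda0 0.156
#' 1/day, lambda1 34.9 mm^3/day, phi 20 fixed; control V0 21.4 mm^3 with
#' 16.9% proportional error; treated V0 32.7 mm^3, k1 2.2 1/day, potency
#' 0.0034 mL/ng/day, synergy factor 0.45, 21.5% proportional error). These
#' are the defaults of the synthetic-data generator and the inputs of the
#' reference simulations.
#'
#' @param group `"control"` or `"treated"` column of the PD estimates.
#' @param combination For `reference_pd_params`, set `hadb1_flag = 1`
#'   (combination-arm dynamics).
#' @return A [pk_params()] or [pd_params()] object.
#' @export
reference_pk_params <- function() {
  pk_params(ka = 0.2, cl_f = 24.5, vd_f = 56.1,
            omega_cl = 0.309, omega_vd = 0.502, sigma_prop = 0.290)
}

#' @rdname reference_pk_params
#' @export
reference_pd_params <- function(group = c("treated", "control"),
                                combination = FALSE) {
  group <- match.arg(group)
  if (group == "control") {
    if (combination) stopf("combination dynamics require the treated group")
    pd_params(lambda0 = 0.156, lambda1 = 34.9, phi = 20, v0 = 21.4,
              sigma_prop = 0.169)
  } else {
    pd_params(lambda0 = 0.156, lambda1 = 34.9, phi = 20, v0 = 32.7,
              k1 = 2.2, k_aft = 0.0034, alpha_syn = 0.45,
              hadb1_flag = as.integer(combination), sigma_prop = 0.215)
  }
}

#' @rdname reference_pk_params
#' @param start_day Day of the first administration (study clock).
#' @export
reference_regimen <- function(start_day = 7) {
  dose_regimen(dose_amount = 10, tau_h = 24, n_doses = 30, start_day = start_day)
}
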