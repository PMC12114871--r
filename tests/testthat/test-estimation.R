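test_that("proportional -2 log-likelihood matches hand arithmetic", {
  pred <- c(10, 20, 40)
  sig <- 0.2
  expect_equal(neg2ll_proportional(pred, pred, sig),
               sum(log(2 * pi) + 2 * log(sig * pred)))
  expect_equal(neg2ll_proportional(10, 11, 0.2),
               log(2 * pi) + 2 * log(2) + 0.25)
  # worse residuals strictly increase the deviance
  vals <- vapply(c(0, 1, 2, 4), function(d)
    neg2ll_proportional(10, 10 + d, 0.2), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(neg2ll_proportional(c(10, 0), c(9, 1), 0.2), "observation 2")
  expect_error(neg2ll_proportional(10, 10, 0), "sigma")
})

test_that("Laplace marginal likelihood agrees with Gauss-Hermite quadrature", {
  subs <- tiny_pk_subjects(seed = 11)
  theta <- log(c(0.2, 24.5, 56.1, 0.309, 0.502, 0.29))
  lap <- sum(vapply(subs, function(s)
    xenopkpd:::pk_laplace_subject(theta, s)$neg2ll, 0))
  gh <- sum(vapply(subs, function(s) gh_marginal_neg2ll(theta, s, 21), 0))
  expect_lt(abs(lap - gh), 0.5)
  # and at a second, deliberately misspecified point
  theta2 <- log(c(0.35, 20, 40, 0.2, 0.3, 0.35))
  lap2 <- sum(vapply(subs, function(s)
    xenopkpd:::pk_laplace_subject(theta2, s)$neg2ll, 0))
  gh2 <- sum(vapply(subs, function(s) gh_marginal_neg2ll(theta2, s, 21), 0))
  expect_lt(abs(lap2 - gh2), 0.5)
})

test_that("subject order does not affect the PK objective", {
  cfg <- synthetic_config(seed = 21, n_pk_per_arm = 3)
  ds <- gen_pk_dataset(cfg)
  f1 <- fit_pk_nlme(ds, n_starts = 1)
  ds_rev <- ds
  ds_rev$records <- ds$records[rev(seq_len(nrow(ds$records))), ]
  f2 <- fit_pk_nlme(ds_rev, n_starts = 1)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-8)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("PK fit structure: EBEs, shrinkage and RSE definitions hold", {
  cfg <- synthetic_config(seed = 42)
  ds <- gen_pk_dataset(cfg)
  fit <- fit_pk_nlme(ds, n_starts = 2)
  expect_true(fit$converged)
  expect_equal(fit$n_subjects, 12)
  expect_equal(fit$n_obs, 48)
  expect_equal(nrow(fit$eta), 12)
  # rse = 100 * se / estimate wherever defined
  ok <- !is.na(fit$se)
  expect_equal(fit$rse_percent[ok],
               100 * fit$se[ok] / abs(fit$estimates[ok]), tolerance = 1e-6)
  expect_true(all(fit$shrinkage <= 100))
  expect_equal(fit$shrinkage[["cl"]],
               100 * (1 - sd(fit$eta$eta_cl) / fit$estimates[["omega_cl"]]),
               tolerance = 1e-8)
})

test_that("PK fixed effects are recovered from a rich design", {
  cfg <- synthetic_config(seed = 7, n_pk_per_arm = 12,
                          pk_sample_times_h = c(0.5, 1, 2, 3, 4, 6, 8, 12))
  ds <- gen_pk_dataset(cfg)
  fit <- fit_pk_nlme(ds, n_starts = 3)
  truth <- c(ka = 0.2, cl_f = 24.5, vd_f = 56.1)
  rel <- abs(fit$estimates[names(truth)] / truth - 1)
  expect_true(all(rel < 0.25), info = paste(round(100 * rel, 1), collapse = "/"))
})

test_that("variance components collapse when the data carry no IIV", {
  pk0 <- pk_params(ka = 0.2, cl_f = 24.5, vd_f = 56.1,
                   omega_cl = 0, omega_vd = 0, sigma_prop = 0.05)
  cfg <- synthetic_config(seed = 9, true_pk = pk0)
  ds <- gen_pk_dataset(cfg)
  fit <- fit_pk_nlme(ds, n_starts = 2)
  expect_lt(fit$estimates[["omega_cl"]], 0.05)
  expect_lt(fit$estimates[["omega_vd"]], 0.05)
})

test_that("natural growth fit recovers noise-free truth and scales correctly", {
  pd0 <- reference_pd_params("control")
  pd0$sigma_prop <- 0
  cfg <- synthetic_config(seed = 31, n_pd_profiles_per_arm = 2,
                          arms = "CONTROL", true_pd_control = pd0)
  ds <- gen_pd_dataset(cfg)
  fit <- fit_natural_growth(ds, n_starts = 3)
  expect_equal(fit$estimates[["lambda0"]], 0.156, tolerance = 0.01)
  expect_equal(fit$estimates[["lambda1"]], 34.9, tolerance = 0.01)
  expect_equal(fit$estimates[["v0"]], 21.4, tolerance = 0.01)

  ds2 <- ds
  ds2$records$DV <- 2 * ds2$records$DV
  fit2 <- fit_natural_growth(ds2, n_starts = 3)
  expect_equal(fit2$estimates[["v0"]], 2 * fit$estimates[["v0"]],
               tolerance = 0.02)
  expect_equal(fit2$estimates[["lambda1"]], 2 * fit$estimates[["lambda1"]],
               tolerance = 0.02)
  expect_equal(fit2$estimates[["lambda0"]], fit$estimates[["lambda0"]],
               tolerance = 0.02)

  few <- ds
  few$records <- few$records[few$records$TIME %in% 7:9, ]
  expect_error(fit_natural_growth(few), "identifiability")
})

test_that("TGI fit recovers noise-free treated dynamics within 2%", {
  pdt0 <- reference_pd_params("treated"); pdt0$sigma_prop <- 0
  cfg <- synthetic_config(seed = 33, n_pd_profiles_per_arm = 2,
                          arms = c("AFT", "COMB"), true_pd_treated = pdt0)
  ds <- gen_pd_dataset(cfg)
  fit <- fit_tgi(ds, growth = c(lambda0 = 0.156, lambda1 = 34.9),
                 pk = reference_pk_params(), n_starts = 3)
  truth <- c(v0 = 32.7, k1 = 2.2, k_aft = 0.0034, alpha_syn = 0.45)
  rel <- abs(fit$estimates[names(truth)] / truth - 1)
  expect_true(all(rel < 0.02), info = paste(round(100 * rel, 2), collapse = "/"))
})

test_that("the synergy factor is flagged unidentifiable with one treated arm", {
  cfg <- synthetic_config(seed = 35, n_pd_profiles_per_arm = 5, arms = "AFT")
  ds <- gen_pd_dataset(cfg)
  fit <- fit_tgi(ds, growth = c(lambda0 = 0.156, lambda1 = 34.9),
                 pk = reference_pk_params(), n_starts = 2)
  expect_true(is.na(fit$estimates[["alpha_syn"]]))
  expect_false(is.na(fit$estimates[["k_aft"]]))
})

test_that("a no-synergy study yields an alpha estimate consistent with zero", {
  pdt0 <- reference_pd_params("treated"); pdt0$alpha_syn <- 0
  cfg <- synthetic_config(seed = 37, n_pd_profiles_per_arm = 40,
                          arms = c("AFT", "COMB"), true_pd_treated = pdt0)
  ds <- gen_pd_dataset(cfg)
  fit <- fit_tgi(ds, growth = c(lambda0 = 0.156, lambda1 = 34.9),
                 pk = reference_pk_params(), n_starts = 2)
  a <- fit$estimates[["alpha_syn"]]
  se <- fit$se[["alpha_syn"]]
  expect_true(abs(a) <= 1.96 * se + 0.02,
              info = sprintf("alpha %.4f, se %.4f", a, se))
})
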