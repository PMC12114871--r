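test_that("the percentile operator matches a hand-rolled type-7 definition", {
  manual_pctl <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(sample(5:40, 1))
    for (p in c(0.05, 0.5, 0.95, 0.975))
      expect_equal(xenopkpd:::pctl(x, p), manual_pctl(x, p), tolerance = 1e-12)
  }
})

make_small_study <- function(seed = 61, n_prof = 30) {
  cfg <- synthetic_config(seed = seed, n_pd_profiles_per_arm = n_prof,
                          pd_obs_days = seq(7, 37, by = 3))
  list(cfg = cfg, ds = gen_full_study(cfg),
       model = study_model(cfg$true_pk, cfg$true_pd_control,
                           cfg$true_pd_treated))
}

test_that("VPC is deterministic given a seed and well-ordered within bins", {
  s <- make_small_study()
  v1 <- vpc(s$model, s$ds, n_rep = 80, seed = 5)
  v2 <- vpc(s$model, s$ds, n_rep = 80, seed = 5)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_true(isTRUE(attr(v1, "low_replicates")))
  expect_true(all(v1$obs_p5 <= v1$obs_p50 & v1$obs_p50 <= v1$obs_p95))
  expect_true(all(v1$p5_lo <= v1$p5_hi & v1$p50_lo <= v1$p50_hi &
                    v1$p95_lo <= v1$p95_hi))
})

test_that("VPC bands are scale-equivariant", {
  s <- make_small_study(seed = 62, n_prof = 15)
  v1 <- vpc(s$model, s$ds, n_rep = 120, seed = 9)
  ds2 <- s$ds
  ds2$records$DV[ds2$records$DVID == 2] <- 2 * ds2$records$DV[ds2$records$DVID == 2]
  m2 <- s$model
  for (f in c("pd_control", "pd_treated")) {
    m2[[f]]$v0 <- 2 * m2[[f]]$v0
    m2[[f]]$lambda1 <- 2 * m2[[f]]$lambda1
  }
  # doubling volumes doubles V0 and lambda1 and halves the volume-scaled
  # potency axis; the drug term K*C*X1 already scales with X1
  v2 <- vpc(m2, ds2, n_rep = 120, seed = 9)
  for (col in c("obs_p50", "p50_lo", "p50_hi", "p95_lo", "p95_hi"))
    expect_equal(v2[[col]], 2 * v1[[col]], tolerance = 1e-6)
})

test_that("concentration VPC covers model-true observations", {
  cfg <- synthetic_config(seed = 71, n_pk_per_arm = 20)
  ds <- gen_pk_dataset(cfg)
  v <- vpc(cfg$true_pk, ds, n_rep = 300, seed = 2)
  expect_equal(nrow(v), 4)    # one bin per nominal sample time
  expect_equal(v$n_obs, rep(40L, 4))
  # observed medians sit inside their simulated confidence bands in at
  # least 90% of bins when averaged over independent studies
  frac <- vapply(1:6, function(s) {
    d <- gen_pk_dataset(synthetic_config(seed = 500 + s, n_pk_per_arm = 20))
    vv <- vpc(cfg$true_pk, d, n_rep = 300, seed = s)
    mean(vv$obs_p50 >= vv$p50_lo & vv$obs_p50 <= vv$p50_hi)
  }, 0)
  expect_gte(mean(frac), 0.9)
})

test_that("tumor VPC on model-true data is self-calibrated", {
  s <- make_small_study(seed = 63, n_prof = 100)
  v <- vpc(s$model, s$ds, n_rep = 200, seed = 3)
  inside <- v$obs_p50 >= v$p50_lo & v$obs_p50 <= v$p50_hi
  expect_gte(mean(inside), 0.9)
  cov <- vpc_coverage(s$model, s$ds, n_rep = 200, seed = 4)
  expect_gt(cov, 0.85); expect_lt(cov, 0.95)
})

test_that("goodness-of-fit tables standardize residuals correctly", {
  pdc0 <- reference_pd_params("control"); pdc0$sigma_prop <- 0
  cfg0 <- synthetic_config(seed = 81, n_pd_profiles_per_arm = 2,
                           arms = "CONTROL", true_pd_control = pdc0)
  ds0 <- gen_pd_dataset(cfg0)
  fit0 <- fit_natural_growth(ds0, n_starts = 2)
  g0 <- gof_table(fit0, ds0)
  expect_equal(nrow(g0), nrow(ds0$records))
  # noise-free data: predictions coincide with observations (the
  # standardized residual is 0/0-shaped because sigma-hat collapses, so the
  # check is on the relative scale)
  expect_lt(max(abs(g0$obs / g0$pred - 1)), 1e-3)

  cfg <- synthetic_config(seed = 82, n_pd_profiles_per_arm = 60,
                          arms = "CONTROL")
  ds <- gen_pd_dataset(cfg)
  fit <- fit_natural_growth(ds, n_starts = 2)
  g <- gof_table(fit, ds)
  expect_equal(nrow(g), nrow(ds$records))
  expect_equal(var(g$residual), 1, tolerance = 0.1)
  expect_equal(mean(g$residual), 0, tolerance = 0.05)
})

test_that("PK goodness-of-fit reports individual predictions from the EBEs", {
  cfg <- synthetic_config(seed = 83, n_pk_per_arm = 4)
  ds <- gen_pk_dataset(cfg)
  fit <- fit_pk_nlme(ds, n_starts = 1)
  g <- gof_table(fit, ds)
  expect_equal(nrow(g), fit$n_obs)
  expect_true(all(is.finite(g$pred)) && all(is.finite(g$ipred)))
  # conditioning on the subject-level random effects improves the fit
  sse_pop <- sum((g$obs / g$pred - 1)^2)
  sse_ind <- sum((g$obs / g$ipred - 1)^2)
  expect_lt(sse_ind, sse_pop)
})
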