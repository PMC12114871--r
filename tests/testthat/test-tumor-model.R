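test_that("growth rate interpolates between exponential and linear regimes", {
  p <- ref_pd_control
  wth <- switching_threshold(p)
  expect_equal(wth, 34.9 / 0.156, tolerance = 1e-12)
  expect_equal(natural_growth_rate(wth / 10, p) / (wth / 10), p$lambda0,
               tolerance = 1e-3)
  expect_equal(natural_growth_rate(10 * wth, p), p$lambda1, tolerance = 1e-3)
  expect_equal(natural_growth_rate(0, p), 0)
  # overflow safety far above the threshold
  expect_equal(natural_growth_rate(1e6, p), p$lambda1, tolerance = 1e-6)

  p11 <- pd_params(lambda0 = 1, lambda1 = 1, v0 = 1)
  expect_equal(switching_threshold(p11), 1)
  p2 <- pd_params(lambda0 = 0.156, lambda1 = 2 * 34.9, v0 = 1)
  expect_equal(switching_threshold(p2), 2 * wth)
})

test_that("eradication threshold concentration follows lambda0 / potency", {
  expect_equal(threshold_concentration(ref_pd_treated), 0.156 / 0.0034)
  expect_equal(round(threshold_concentration(ref_pd_treated)), 46)
  expect_equal(threshold_concentration(ref_pd_treated, combination = TRUE),
               0.156 / (0.0034 * 1.45), tolerance = 1e-12)
  p2 <- ref_pd_treated; p2$lambda0 <- 2 * p2$lambda0
  expect_equal(threshold_concentration(p2),
               2 * threshold_concentration(ref_pd_treated))
  p0 <- pd_params(0.156, 34.9, v0 = 1, k_aft = 0)
  expect_equal(threshold_concentration(p0), Inf)
})

test_that("TGI derivatives reduce to natural growth and balance mass", {
  s <- c(x1 = 100, x2 = 5, x3 = 3, x4 = 1)
  p <- ref_pd_treated
  d0 <- tgi_derivatives(s, 10, p, conc_at = function(t) 0)
  expect_equal(d0[["x1"]], natural_growth_rate(100, p))
  expect_equal(d0[["x2"]], -p$k1 * 5)

  cfun <- function(t) 20
  d1 <- tgi_derivatives(s, 10, p, cfun)
  expect_equal(sum(d1), natural_growth_rate(100, p) - p$k1 * s[["x4"]])
  # kill-term linearity in concentration
  d2 <- tgi_derivatives(s, 10, p, function(t) 40)
  expect_equal(d0[["x1"]] - d2[["x1"]], 2 * (d0[["x1"]] - d1[["x1"]]))
  # combination flag scales the kill by 1 + alpha_syn = 1.45
  pc <- p; pc$hadb1_flag <- 1L
  dc <- tgi_derivatives(s, 10, pc, cfun)
  kill_mono <- d0[["x1"]] - d1[["x1"]]
  kill_comb <- d0[["x1"]] - dc[["x1"]]
  expect_equal(kill_comb / kill_mono, 1.45, tolerance = 1e-12)
})

test_that("control simulation matches growth laws and the randomization window", {
  pd <- pd_params(0.156, 34.9, v0 = 32.7)
  sim <- simulate_arm(ref_pk, pd, NULL, t_end = 20, dt_out = 0.5)
  expect_equal(sim$v, sim$x1 + sim$x2 + sim$x3 + sim$x4)  # exact by construction
  expect_equal(sim$x2 + sim$x3 + sim$x4, rep(0, nrow(sim)))
  v7 <- sim$v[sim$t_day == 7]
  expect_equal(v7, 32.7 * exp(0.156 * 7), tolerance = 0.01)
  expect_gt(v7, 80); expect_lt(v7, 100)
  # phi = 20 approximates the piecewise-exact switch within 2%
  expect_equal(sim$v, piecewise_growth(sim$t_day, 0.156, 34.9, 32.7),
               tolerance = 0.02)
})

test_that("treated simulation honors null effects and grid independence", {
  reg <- reference_regimen(7)
  p0 <- ref_pd_treated; p0$k_aft <- 0
  s_null <- simulate_arm(ref_pk, p0, reg, t_end = 15, dt_out = 0.5)
  pc <- pd_params(p0$lambda0, p0$lambda1, v0 = p0$v0)
  s_ctrl <- simulate_arm(ref_pk, pc, NULL, t_end = 15, dt_out = 0.5)
  expect_equal(s_null$v, s_ctrl$v, tolerance = 1e-8)

  s1 <- simulate_arm(ref_pk, ref_pd_treated, reg, t_end = 15, dt_out = 0.5)
  s2 <- simulate_arm(ref_pk, ref_pd_treated, reg, t_end = 15, dt_out = 0.25)
  shared <- match(s1$t_day, s2$t_day)
  expect_equal(s2$v[shared], s1$v, tolerance = 1e-6)
  # conservation under treatment too
  expect_equal(s1$v, s1$x1 + s1$x2 + s1$x3 + s1$x4)
})

test_that("sustained exposure below the threshold stabilizes the tumor, above it clears it", {
  p <- ref_pd_treated
  ct <- threshold_concentration(p)
  run_const <- function(conc, t_end = 400) {
    f <- function(t, y, parms) list(tgi_derivatives(y, t, p, function(tt) conc))
    out <- deSolve::lsoda(c(x1 = p$v0, x2 = 0, x3 = 0, x4 = 0),
                          seq(0, t_end, by = 2), f, NULL,
                          rtol = 1e-8, atol = 1e-10)
    rowSums(as.data.frame(out)[, -1])
  }
  below <- run_const(0.8 * ct)
  n <- length(below)
  expect_gt(below[n], 0)
  # approaches a stable size: late relative change is tiny
  expect_lt(abs(below[n] - below[n - 1]) / below[n], 1e-3)
  above <- run_const(1.5 * ct)
  expect_lt(above[n], 1e-2)
})

test_that("threshold crossing times interpolate, round and respect monotonicity", {
  pd <- pd_params(0.156, 34.9, v0 = 32.7)
  sim <- simulate_arm(ref_pk, pd, NULL, t_end = 25, dt_out = 0.05)
  expect_equal(time_to_threshold(sim, 10)$day, 0)
  expect_true(is.na(time_to_threshold(sim, 1e6)$day))
  cross <- time_to_threshold(sim, 350)
  expect_equal(cross$day, round(cross$day_raw))

  reg <- reference_regimen(7)
  days <- vapply(c(0, 0.45, 0.9), function(a) {
    p <- ref_pd_treated; p$alpha_syn <- a; p$hadb1_flag <- 1L
    s <- simulate_arm(ref_pk, p, reg, t_end = 40, dt_out = 0.1)
    time_to_threshold(s, 350)$day_raw
  }, 0)
  expect_true(all(diff(days) > 0))  # stronger synergy never crosses earlier
})

test_that("the linear growth rate alternative shifts the crossing by under 0.2 day", {
  reg <- reference_regimen(7)
  cross_for <- function(l1) {
    p <- pd_params(0.156, l1, v0 = 32.7, k1 = 2.2, k_aft = 0.0034,
                   alpha_syn = 0.45)
    s <- simulate_arm(ref_pk, p, reg, t_end = 40, dt_out = 0.05)
    time_to_threshold(s, 350)$day_raw
  }
  expect_lt(abs(cross_for(34.9) - cross_for(35.5)), 0.2)
})
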