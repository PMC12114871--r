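# Independent oracles used across the test suite. Each reimplements a
# quantity by a different route than the package (quadrature, enumeration,
# ODE integration, piecewise closed forms) so agreement is evidence, not
# tautology.

# Gauss-Hermite nodes/weights via the Golub-Welsch eigen decomposition of
# the Jacobi matrix (weight exp(-x^2)).
gh_rule <- function(n) {
  b <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- b
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Marginal -2 log-likelihood of one subject of the PK mixed-effects model by
# 2-d Gauss-Hermite quadrature over the (CL, Vd) random effects.
gh_marginal_neg2ll <- function(theta, sub, n_nodes = 21) {
  ka <- exp(theta[1]); cl <- exp(theta[2]); vd <- exp(theta[3])
  omega <- exp(theta[4:5]); sigma <- exp(theta[6])
  t_abs <- (sub$reg$n_doses - 1) * sub$reg$tau_h + sub$t
  p_y <- function(e1, e2) {
    pr <- xenopkpd:::pk_pred_grad(ka, cl * exp(e1), vd * exp(e2), sub$reg, t_abs)$c
    prod(stats::dnorm(sub$dv, pr, sigma * pr))
  }
  g <- gh_rule(n_nodes)
  tot <- 0
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    tot <- tot + g$w[i] * g$w[j] *
      p_y(sqrt(2) * omega[1] * g$x[i], sqrt(2) * omega[2] * g$x[j])
  }
  -2 * log(tot / pi)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
perm_mwu_p <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b)
  n <- length(a)
  combos <- utils::combn(length(pooled), n)
  u_obs <- u_stat(a, b)
  m <- length(pooled) - n
  mid <- n * m / 2
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  # two-sided: deviations from the null center at least as extreme
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# One-compartment oral PK by ODE integration with depot resets at each dose.
ode_pk_profile <- function(p, reg, times_h) {
  deriv <- function(t, y, parms)
    list(c(-p$ka * y[1], p$ka * y[1] - kel(p) * y[2]))
  dose_t <- (seq_len(reg$n_doses) - 1) * reg$tau_h
  ev <- data.frame(var = "a1", time = dose_t, value = reg$dose_amount,
                   method = "add")
  grid <- sort(unique(c(times_h, dose_t)))
  out <- deSolve::lsoda(c(a1 = 0, a2 = 0), unique(c(0, grid)), deriv, NULL,
                        events = list(data = ev), rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(out)
  1000 * out$a2[match(times_h, out$time)] / p$vd_f
}

# Piecewise-exact unperturbed growth (the phi -> Inf limit of the smooth
# model): exponential to W_th, linear afterwards.
piecewise_growth <- function(t, lambda0, lambda1, v0) {
  wth <- lambda1 / lambda0
  t_sw <- log(wth / v0) / lambda0
  ifelse(t <= t_sw, v0 * exp(lambda0 * t), wth + lambda1 * (t - t_sw))
}

# Analytic integral of the single-dose Bateman curve over [0, T].
bateman_auc <- function(p, dose, T) {
  ke <- kel(p)
  m <- 1000 * dose * p$ka / (p$vd_f * (p$ka - ke))
  m * ((1 - exp(-ke * T)) / ke - (1 - exp(-p$ka * T)) / p$ka)
}
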