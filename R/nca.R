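#' Linear trapezoidal AUC
#'
#' Area under the concentration-time curve from time zero to the last
#' observation, by the linear trapezoidal rule. Because dosing is oral and no
#' pre-dose sample exists, a (0, 0) anchor is prepended whenever the first
#' sample time is positive; this is a documented dialect choice (some NCA
#' tools use linear-up/log-down instead).
#'
#' @param times Sampling times (hours), strictly increasing.
#' @param concs Concentrations (ng/mL), same length.
#' @return AUC (ng*h/mL).
#' @export
auc_linear_trapezoid <- function(times, concs) {
  if (length(times) != length(concs)) stopf("times and concs must have equal length")
  if (length(times) < 2) stopf("insufficient data: need at least 2 points for AUC")
  if (any(diff(times) <= 0)) stopf("validation error: times must be strictly increasing")
  if (times[1] > 0) {
    times <- c(0, times)
    concs <- c(0, concs)
  }
  sum(diff(times) * (utils::head(concs, -1) + utils::tail(concs, -1)) / 2)
}

#' Observed maximum concentration
#'
#' The maximum of the observed values, with no interpolation; ties resolve
#' to the common maximum value regardless of which time attains it.
#'
#' @inheritParams auc_linear_trapezoid
#' @return Cmax (ng/mL).
#' @export
cmax_observed <- function(times, concs) {
  if (!length(concs)) stopf("insufficient data: need at least 1 point for Cmax")
  max(concs)
}

#' Mann-Whitney U test (two-sided)
#'
#' Wrapper around [stats::wilcox.test()] returning the U statistic and the
#' two-sided p-value: exact when the combined sample size is at most 20 and
#' there are no ties, normal approximation with tie/continuity correction
#' otherwise. If every value in both groups is identical the test is
#' degenerate and p = 1 is returned by convention.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `u` (number of (a, b) pairs with a > b, ties counted
#'   1/2) and `p` (two-sided p-value).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stopf("both groups must be non-empty")
  u <- sum(outer(group_a, group_b, ">")) + 0.5 * sum(outer(group_a, group_b, "=="))
  if (length(unique(c(group_a, group_b))) == 1L)
    return(list(u = u, p = 1))
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && (length(group_a) + length(group_b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  list(u = u, p = min(unname(wt$p.value), 1))
}

#' Per-subject noncompartmental analysis of a study dataset
#'
#' Computes AUC to the last steady-state sample and observed Cmax for every
#' subject with concentration records, summarizes mean +/- SD per arm, and
#' compares the two dosed arms by the two-sided Mann-Whitney U test.
#'
#' @param ds A [study_dataset()] containing concentration records (DVID 1).
#' @return List of class `nca_result`: `per_subject` (one row per animal),
#'   `by_arm` (mean/SD of AUC and Cmax), and `tests` (U and p for AUC and
#'   Cmax between the two arms, when exactly two arms are present).
#' @export
nca_summary <- function(ds) {
  r <- obs_records(ds, dvid = 1L)
  if (!nrow(r)) stopf("insufficient data: no concentration records")
  per <- do.call(rbind, lapply(split(r, r$ID), function(s) {
    s <- s[order(s$TIME), ]
    data.frame(ID = s$ID[1], ARM = s$ARM[1],
               auc_last = auc_linear_trapezoid(s$TIME, s$DV),
               cmax = cmax_observed(s$TIME, s$DV),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  by_arm <- do.call(rbind, lapply(split(per, per$ARM), function(a) {
    data.frame(ARM = a$ARM[1], n = nrow(a),
               auc_mean = mean(a$auc_last), auc_sd = stats::sd(a$auc_last),
               cmax_mean = mean(a$cmax), cmax_sd = stats::sd(a$cmax))
  }))
  rownames(by_arm) <- NULL
  tests <- NULL
  arms <- unique(per$ARM)
  if (length(arms) == 2) {
    a <- per[per$ARM == arms[1], ]
    b <- per[per$ARM == arms[2], ]
    tests <- list(arms = arms,
                  auc = mann_whitney_u(a$auc_last, b$auc_last),
                  cmax = mann_whitney_u(a$cmax, b$cmax))
  }
  structure(list(per_subject = per, by_arm = by_arm, tests = tests),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Noncompartmental analysis (steady state)\n")
  for (i in seq_len(nrow(x$by_arm)))
    cat(sprintf("  %s (n=%d): AUC_lst,ss %.2f +/- %.2f ng*h/mL, Cmax_ss %.2f +/- %.2f ng/mL\n",
                x$by_arm$ARM[i], x$by_arm$n[i], x$by_arm$auc_mean[i],
                x$by_arm$auc_sd[i], x$by_arm$cmax_mean[i], x$by_arm$cmax_sd[i]))
  if (!is.null(x$tests))
    cat(sprintf("  Mann-Whitney %s vs %s: AUC p = %.3f, Cmax p = %.3f\n",
                x$tests$arms[1], x$tests$arms[2], x$tests$auc$p, x$tests$cmax$p))
  invisible(x)
}
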