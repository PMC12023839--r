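# GLS variance of the treatment effect estimator and Wald-test power.
#
# The computation works on cluster-period means, which is exact for the
# underlying mixed model: a cluster's mean outcomes over its Tk observed
# periods have covariance tau^2 R_sub + (sigma_eps^2 / m) I. Fixed effects
# are categorical period effects (one column per period that is observed in
# at least one sequence) plus the treatment indicator. All clusters on a
# sequence are interchangeable, so per-sequence contributions are computed
# once and weighted by Ns.

.not_estimable <- function(msg = "treatment effect is not estimable for this design") {
  stop(errorCondition(msg, class = c("swce_not_estimable", "error")))
}

# reciprocal condition number threshold separating structural singularity
# from float noise on these small matrices; scalar positivity threshold
.RCOND_TOL <- 1e-10
.SCALAR_TOL <- 1e-12

# Per-sequence building blocks of the GLS information, weighted by Ns:
#   A_s = Ns * X' V^-1 X   (scalar)
#   b_s = Ns * Z' V^-1 X   (length T)
#   M_s = Ns * Z' V^-1 Z   (T x T, nonzero only on observed periods)
# A sequence with no observed cells contributes zeros.
.sequence_parts <- function(design, s, corr) {
  T_ <- design$n_periods
  J <- which(design$observed[s, ])
  if (length(J) == 0L) {
    return(list(A = 0, b = numeric(T_), M = matrix(0, T_, T_)))
  }
  Ns <- design$clusters_per_sequence[s]
  tau2 <- corr$icc
  sig2 <- 1 - corr$icc
  V <- tau2 * .corr_matrix(J, corr) + diag(sig2 / design$cluster_period_size,
                                           length(J))
  Vi <- chol2inv(chol(V))
  X <- design$treatment[s, J]
  ViX <- Vi %*% X
  b <- numeric(T_)
  b[J] <- ViX
  M <- matrix(0, T_, T_)
  M[J, J] <- Vi
  list(A = Ns * drop(crossprod(X, ViX)), b = Ns * b, M = Ns * M)
}

# Reduce accumulated parts to var(theta-hat); NA if not estimable.
# `keep` = periods observed in at least one sequence (period-effect columns
# for globally unobserved periods are dropped, otherwise the period
# information matrix is structurally singular).
.variance_from_parts <- function(A, b, M, keep) {
  if (length(keep) == 0L) return(NA_real_)
  Mr <- M[keep, keep, drop = FALSE]
  if (!all(is.finite(Mr)) || rcond(Mr) < .RCOND_TOL) return(NA_real_)
  info <- A - drop(crossprod(b[keep], solve(Mr, b[keep])))
  if (!is.finite(info) || info <= .SCALAR_TOL) return(NA_real_)
  1 / info
}

.treatment_variance_or_na <- function(design, corr) {
  S <- design$n_sequences
  T_ <- design$n_periods
  A <- 0
  b <- numeric(T_)
  M <- matrix(0, T_, T_)
  for (s in seq_len(S)) {
    p <- .sequence_parts(design, s, corr)
    A <- A + p$A
    b <- b + p$b
    M <- M + p$M
  }
  keep <- which(colSums(design$observed) > 0L)
  .variance_from_parts(A, b, M, keep)
}

#' GLS variance of the treatment effect estimator
#'
#' Evaluates the generalized least squares variance of the estimated
#' treatment effect for a complete or incomplete stepped wedge design with
#' categorical period effects, on the standardized outcome scale (total
#' outcome variance 1). Valid for any observation mask as long as the
#' treatment effect remains estimable.
#'
#' @param design an `sw_design`.
#' @param corr an [corr_spec()] object.
#' @return Positive scalar variance.
#' @seealso [sw_power()], [is_estimable()]
#' @export
treatment_variance <- function(design, corr) {
  stopifnot(inherits(design, "sw_design"), inherits(corr, "sw_corr"))
  v <- .treatment_variance_or_na(design, corr)
  if (is.na(v)) .not_estimable()
  v
}

#' Is the treatment effect estimable for a design?
#'
#' `TRUE` iff the GLS computation yields a finite positive variance: the
#' period-effect information matrix (restricted to periods observed
#' somewhere) is invertible and the residual treatment information is
#' positive. For example, a design observed only under control, or a single
#' sequence whose treatment indicator is confounded with period effects,
#' is not estimable.
#'
#' @inheritParams treatment_variance
#' @return Logical scalar.
#' @export
is_estimable <- function(design, corr) {
  stopifnot(inherits(design, "sw_design"), inherits(corr, "sw_corr"))
  !is.na(.treatment_variance_or_na(design, corr))
}

#' Specify effect size, test size and the power constraint
#'
#' @param effect_size standardized effect size to detect (> 0).
#' @param alpha two-sided significance level of the Wald test.
#' @param min_power minimum acceptable power used by design selection.
#' @return An object of class `sw_power_spec`.
#' @export
power_spec <- function(effect_size, alpha = 0.05, min_power = 0.8) {
  effect_size <- as.numeric(effect_size)
  alpha <- as.numeric(alpha)
  min_power <- as.numeric(min_power)
  if (length(effect_size) != 1L || is.na(effect_size) || effect_size < 0) {
    stop("`effect_size` must be a single non-negative value")
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)")
  }
  if (length(min_power) != 1L || is.na(min_power) || min_power <= 0 ||
      min_power >= 1) {
    stop("`min_power` must be in (0, 1)")
  }
  structure(
    list(effect_size = effect_size, alpha = alpha, min_power = min_power),
    class = "sw_power_spec"
  )
}

#' @export
print.sw_power_spec <- function(x, ...) {
  cat(sprintf("effect size %g, two-sided alpha %g, minimum power %g\n",
              x$effect_size, x$alpha, x$min_power))
  invisible(x)
}

#' Asymptotic power of the two-sided Wald test
#'
#' Normal-approximation power to detect the standardized effect size:
#' `Phi(theta_d / sqrt(var) - z_{1 - alpha/2})`. The normal (not t)
#' reference distribution is used throughout; no degrees-of-freedom
#' correction is applied.
#'
#' @param design an `sw_design`.
#' @param corr an [corr_spec()] object.
#' @param pw an [power_spec()] object.
#' @return Power in (0, 1).
#' @export
sw_power <- function(design, corr, pw) {
  stopifnot(inherits(pw, "sw_power_spec"))
  v <- treatment_variance(design, corr)
  .power_from_variance(v, pw)
}

.power_from_variance <- function(variance, pw) {
  stats::pnorm(pw$effect_size / sqrt(variance) -
                 stats::qnorm(1 - pw$alpha / 2))
}
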