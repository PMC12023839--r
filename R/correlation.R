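# Within-cluster correlation structures for cluster-period means.

#' Specify a within-cluster correlation structure
#'
#' The linear mixed model underlying all variance computations has a
#' cluster-period random effect with correlation matrix R across periods
#' and an independent participant-level error. With within-period
#' intracluster correlation rho (ICC) and cluster autocorrelation r (CAC),
#' the correlation between two participants in the same cluster measured in
#' periods j and j' is:
#' * `discrete_time_decay`: rho * r^|j - j'|
#' * `block_exchangeable`: rho within the same period, rho * r otherwise
#' * `exchangeable`: rho regardless of period separation (r is ignored;
#'   identical to either other structure with r = 1)
#'
#' The total outcome variance is normalized to 1, so the cluster-period
#' random effect variance is tau^2 = rho and the residual variance is
#' 1 - rho; effect sizes are then on the standardized outcome scale.
#'
#' @param structure one of `"discrete_time_decay"`, `"block_exchangeable"`,
#'   `"exchangeable"`.
#' @param icc within-period intracluster correlation rho, in \[0, 1).
#' @param cac cluster autocorrelation r, in \[0, 1\]; ignored for
#'   `"exchangeable"`.
#' @return An object of class `sw_corr`.
#' @export
corr_spec <- function(structure = c("discrete_time_decay",
                                    "block_exchangeable",
                                    "exchangeable"),
                      icc, cac = 1) {
  structure <- match.arg(structure)
  icc <- as.numeric(icc)
  cac <- as.numeric(cac)
  if (length(icc) != 1L || is.na(icc) || icc < 0 || icc >= 1) {
    stop("`icc` must be a single value in [0, 1)")
  }
  if (length(cac) != 1L || is.na(cac) || cac < 0 || cac > 1) {
    stop("`cac` must be a single value in [0, 1]")
  }
  if (structure == "exchangeable") cac <- 1
  structure(
    list(structure = structure, icc = icc, cac = cac),
    class = "sw_corr"
  )
}

#' @export
print.sw_corr <- function(x, ...) {
  cat(sprintf("correlation structure: %s (ICC = %g, CAC = %g)\n",
              x$structure, x$icc, x$cac))
  invisible(x)
}

# Period-level correlation matrix R restricted to observed period labels J.
# Gaps widen the time distance under decay: the labels are the ORIGINAL
# period indices, not a re-numbering of the observed periods.
.corr_matrix <- function(J, corr) {
  n <- length(J)
  switch(corr$structure,
    discrete_time_decay = corr$cac^abs(outer(J, J, "-")),
    block_exchangeable = {
      R <- matrix(corr$cac, n, n)
      diag(R) <- 1
      R
    },
    exchangeable = matrix(1, n, n) + diag(0, n)
  )
}

#' Covariance matrix of one cluster's observed cluster-period means
#'
#' For a single cluster on the given sequence, returns the Tk x Tk
#' covariance matrix of its observed cluster-period mean outcomes:
#' diagonal tau^2 + sigma_eps^2 / m and off-diagonal tau^2 * r_jj', with
#' tau^2 = rho and sigma_eps^2 = 1 - rho (total variance 1) and r_jj'
#' determined by the correlation structure evaluated at the original period
#' labels (so under discrete-time decay, a gap in measurement widens the
#' correlation distance).
#'
#' @param design an `sw_design`.
#' @param sequence_index 1-based sequence index; must have at least one
#'   observed period.
#' @param corr an [corr_spec()] object.
#' @return Symmetric positive-definite matrix of dimension Tk x Tk.
#' @export
cluster_covariance <- function(design, sequence_index, corr) {
  stopifnot(inherits(design, "sw_design"), inherits(corr, "sw_corr"))
  s <- as.integer(sequence_index)
  if (length(s) != 1L || is.na(s) || s < 1L || s > design$n_sequences) {
    stop("`sequence_index` out of range")
  }
  J <- which(design$observed[s, ])
  if (length(J) == 0L) {
    stop(sprintf("sequence %d has no observed periods", s))
  }
  tau2 <- corr$icc
  sig2 <- 1 - corr$icc
  V <- tau2 * .corr_matrix(J, corr) + diag(sig2 / design$cluster_period_size,
                                           length(J))
  # for rho in [0,1), r in [0,1] the result is positive definite; guard anyway
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("cluster covariance matrix is not positive definite")
  V
}
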