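# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: the GLS oracle works on the stacked
# individual-level covariance matrix, the gap oracle on an explicit
# run-length encoding, and the search oracle on exhaustive enumeration.

# Brute-force individual-level GLS variance of the treatment effect.
# Builds the full (sum over clusters of m * Tk)-dimensional covariance
# matrix participant by participant and inverts it densely. Only usable
# for tiny designs.
oracle_individual_gls <- function(design, corr) {
  m <- design$cluster_period_size
  tau2 <- corr$icc
  sig2 <- 1 - corr$icc
  period_corr <- function(j, jp) {
    switch(corr$structure,
      discrete_time_decay = corr$cac^abs(j - jp),
      block_exchangeable = if (j == jp) 1 else corr$cac,
      exchangeable = 1
    )
  }
  keep <- which(colSums(design$observed) > 0L)
  rows <- list() # one entry per participant: c(cluster, period, treatment)
  cl <- 0L
  for (s in seq_len(design$n_sequences)) {
    J <- which(design$observed[s, ])
    if (length(J) == 0L) next
    for (rep in seq_len(design$clusters_per_sequence[s])) {
      cl <- cl + 1L
      for (j in J) {
        for (i in seq_len(m)) {
          rows[[length(rows) + 1L]] <- c(cl, j, design$treatment[s, j])
        }
      }
    }
  }
  n <- length(rows)
  info <- do.call(rbind, rows)
  Sigma <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (info[a, 1L] != info[b, 1L]) next
      Sigma[a, b] <- tau2 * period_corr(info[a, 2L], info[b, 2L])
      if (a == b) Sigma[a, b] <- Sigma[a, b] + sig2
    }
  }
  # fixed effects: one dummy per globally observed period, plus treatment
  X <- matrix(0, n, length(keep) + 1L)
  for (a in seq_len(n)) {
    X[a, match(info[a, 2L], keep)] <- 1
    X[a, length(keep) + 1L] <- info[a, 3L]
  }
  fisher <- t(X) %*% solve(Sigma, X)
  if (rcond(fisher) < 1e-12) return(NA_real_)
  solve(fisher)[length(keep) + 1L, length(keep) + 1L]
}

# Run-length-encoding gap counter: gaps are FALSE-runs strictly between
# TRUE runs; each is attributed to the treatment of the first observed
# period after it.
oracle_gap_counts <- function(obs, trt) {
  r <- rle(obs)
  n_runs <- length(r$values)
  gaps_int <- 0L
  gaps_con <- 0L
  pos <- cumsum(r$lengths)
  for (k in seq_len(n_runs)) {
    if (!r$values[k] && k > 1L && k < n_runs) {
      next_obs_period <- pos[k] + 1L
      if (trt[next_obs_period] == 1L) gaps_int <- gaps_int + 1L
      else gaps_con <- gaps_con + 1L
    }
  }
  c(intervention = gaps_int, control = gaps_con)
}

# Exhaustive single-removal argmax of cost efficiency (for checking the
# greedy search's first step). Returns c(sequence, period) of the best
# removal under the package's tie-break (smallest sequence, then period).
oracle_best_single_removal <- function(design, corr, costs) {
  best <- NULL
  best_ce <- -Inf
  for (s in seq_len(design$n_sequences)) {
    for (j in seq_len(design$n_periods)) {
      if (!design$observed[s, j]) next
      cand <- design
      cand$observed[s, j] <- FALSE
      if (!any(cand$observed) || !is_estimable(cand, corr)) next
      ce <- 1 / (treatment_variance(cand, corr) * total_cost(cand, costs))
      if (ce > best_ce * (1 + 1e-12) && ce > best_ce) {
        best_ce <- ce
        best <- c(s, j)
      }
    }
  }
  best
}

# Random observation mask over a complete design, biased toward keeping
# most cells so estimable designs are common.
random_masked_design <- function(S, clusters = rep(1L, S), m = 1L,
                                 p_keep = 0.7) {
  d <- sw_complete(S, clusters, m)
  mask <- matrix(stats::runif(S * (S + 1L)) < p_keep, S, S + 1L)
  if (!any(mask)) mask[1L, 1L] <- TRUE
  d$observed <- mask
  d
}

alliance_design <- function() sw_complete(5, c(8, 7, 7, 7, 8), 7)

alliance_costs <- function() {
  cost_spec(
    cost_per_cluster = 2500,
    participant_cost_intervention = 140,
    participant_cost_control = 80,
    restart_cost_intervention = 230
  )
}

large15_design <- function() sw_complete(14, rep(1L, 14), 50)
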