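# Total trial cost for (in)complete stepped wedge designs.

#' Specify trial cost parameters
#'
#' The seven cost parameters of the total-cost formula. All are per-trial
#' currency amounts in the same (arbitrary) unit and must be non-negative:
#'
#' * `cost_per_cluster` (c): charged once per cluster whose sequence
#'   measures at least one period.
#' * `cluster_cost_intervention` / `cluster_cost_control` (k, k'): charged
#'   once per cluster whose sequence measures at least one period under the
#'   respective condition.
#' * `participant_cost_intervention` / `participant_cost_control` (p, p'):
#'   charged per participant measured under the respective condition.
#' * `restart_cost_intervention` / `restart_cost_control` (g, g'): charged
#'   per cluster per data-collection gap, attributed to the condition under
#'   which measurement restarts after the gap.
#'
#' @param cost_per_cluster,cluster_cost_intervention,cluster_cost_control
#'   cluster-level costs (c, k, k').
#' @param participant_cost_intervention,participant_cost_control
#'   per-participant costs (p, p').
#' @param restart_cost_intervention,restart_cost_control restart costs
#'   (g, g').
#' @return An object of class `sw_costs`.
#' @export
cost_spec <- function(cost_per_cluster = 0,
                      cluster_cost_intervention = 0,
                      cluster_cost_control = 0,
                      participant_cost_intervention = 0,
                      participant_cost_control = 0,
                      restart_cost_intervention = 0,
                      restart_cost_control = 0) {
  vals <- c(
    cost_per_cluster = cost_per_cluster,
    cluster_cost_intervention = cluster_cost_intervention,
    cluster_cost_control = cluster_cost_control,
    participant_cost_intervention = participant_cost_intervention,
    participant_cost_control = participant_cost_control,
    restart_cost_intervention = restart_cost_intervention,
    restart_cost_control = restart_cost_control
  )
  vals <- vapply(vals, as.numeric, numeric(1))
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("all cost parameters must be non-negative numbers")
  }
  structure(as.list(vals), class = "sw_costs")
}

#' @export
print.sw_costs <- function(x, ...) {
  cat(sprintf(
    "costs: c = %g, k = %g, k' = %g, p = %g, p' = %g, g = %g, g' = %g\n",
    x$cost_per_cluster, x$cluster_cost_intervention, x$cluster_cost_control,
    x$participant_cost_intervention, x$participant_cost_control,
    x$restart_cost_intervention, x$restart_cost_control
  ))
  invisible(x)
}

#' Total trial cost of a design
#'
#' Sums, over sequences s with Ns clusters each: the cluster cost c for
#' present sequences, the condition-implementation costs k/k' for sequences
#' with at least one measured intervention/control period, the participant
#' costs m p Ts + m p' T's over measured periods, and the restart costs
#' g ns + g' n's over data-collection gaps. No rounding is applied; with
#' integer inputs the result is integer-exact. Works for any design,
#' estimable or not.
#'
#' @param design an `sw_design`.
#' @param costs an [cost_spec()] object.
#' @return Non-negative total cost.
#' @export
total_cost <- function(design, costs) {
  stopifnot(inherits(design, "sw_design"), inherits(costs, "sw_costs"))
  m <- design$cluster_period_size
  total <- 0
  for (s in seq_len(design$n_sequences)) {
    z <- sequence_summary(design, s)
    Ns <- design$clusters_per_sequence[s]
    total <- total + Ns * (
      costs$cost_per_cluster * z$present +
        costs$cluster_cost_intervention * z$has_intervention_period +
        costs$cluster_cost_control * z$has_control_period +
        m * costs$participant_cost_intervention * z$t_intervention +
        m * costs$participant_cost_control * z$t_control +
        costs$restart_cost_intervention * z$gaps_intervention +
        costs$restart_cost_control * z$gaps_control
    )
  }
  total
}
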