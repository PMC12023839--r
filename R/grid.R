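# Correlation-parameter uncertainty: per-grid-point searches and the
# union ("superset") of the optimal designs.

#' Specify a grid of correlation parameter values
#'
#' Cartesian product of candidate ICC and CAC values under one correlation
#' structure, used to represent uncertainty about the true correlation
#' parameters at the design stage.
#'
#' @param icc_values numeric vector of ICC values in \[0, 1).
#' @param cac_values numeric vector of CAC values in \[0, 1\].
#' @param structure correlation structure, as in [corr_spec()].
#' @return An object of class `sw_corr_grid` whose `points` element is a
#'   data frame of (icc, cac) pairs in row-major order over ascending icc,
#'   then ascending cac.
#' @export
correlation_grid <- function(icc_values, cac_values,
                             structure = c("discrete_time_decay",
                                           "block_exchangeable",
                                           "exchangeable")) {
  structure <- match.arg(structure)
  if (length(icc_values) < 1L || length(cac_values) < 1L) {
    stop("`icc_values` and `cac_values` must be non-empty")
  }
  icc_values <- sort(unique(as.numeric(icc_values)))
  cac_values <- sort(unique(as.numeric(cac_values)))
  # range checks via the scalar constructor
  for (icc in icc_values) for (cac in cac_values) corr_spec(structure, icc, cac)
  points <- expand.grid(cac = cac_values, icc = icc_values)[, c("icc", "cac")]
  rownames(points) <- NULL
  base::structure(
    list(icc_values = icc_values, cac_values = cac_values,
         structure = structure, points = points),
    class = "sw_corr_grid"
  )
}

#' @export
print.sw_corr_grid <- function(x, ...) {
  cat(sprintf("correlation grid: %s, ICC {%s} x CAC {%s} (%d points)\n",
              x$structure, paste(x$icc_values, collapse = ", "),
              paste(x$cac_values, collapse = ", "), nrow(x$points)))
  invisible(x)
}

#' Evaluate one design across a correlation grid
#'
#' Computes the GLS variance and power of a fixed design at every grid
#' point. Points where the design is not estimable are reported with `NA`
#' rather than raising an error.
#'
#' @param design an `sw_design`.
#' @param grid an [correlation_grid()].
#' @param pw an [power_spec()].
#' @return Data frame with columns `icc`, `cac`, `variance`, `power`,
#'   `estimable`.
#' @export
evaluate_design_over_grid <- function(design, grid, pw) {
  stopifnot(inherits(design, "sw_design"), inherits(grid, "sw_corr_grid"),
            inherits(pw, "sw_power_spec"))
  out <- grid$points
  out$variance <- NA_real_
  out$power <- NA_real_
  out$estimable <- FALSE
  for (i in seq_len(nrow(out))) {
    corr <- corr_spec(grid$structure, out$icc[i], out$cac[i])
    v <- .treatment_variance_or_na(design, corr)
    if (!is.na(v)) {
      out$variance[i] <- v
      out$power[i] <- .power_from_variance(v, pw)
      out$estimable[i] <- TRUE
    }
  }
  out
}

#' Superset design across a correlation grid
#'
#' Implements the pragmatic procedure for correlation-parameter
#' uncertainty: run the greedy removal search and power-constrained optimal
#' selection at every (ICC, CAC) grid point, then form the "superset"
#' design whose observed cells are the union of the observed cells of all
#' per-point optimal designs. Because adding cells can only decrease the
#' variance, the superset's power at each contributing grid point is at
#' least that point's optimal-design power, hence at least `min_power`.
#'
#' Grid points at which even the complete reference design is under-powered
#' cannot contribute an optimal design; they are recorded in
#' `skipped_points` (with a warning) and excluded from the union.
#'
#' @param reference the complete reference design; must be estimable at
#'   every grid point.
#' @param grid an [correlation_grid()].
#' @param costs an [cost_spec()].
#' @param pw an [power_spec()].
#' @return An object of class `sw_superset`: a list with
#'   `per_point` (data frame: icc, cac, complete_power, optimal_iteration,
#'   optimal_power, optimal_cost, optimal_rce, skipped),
#'   `per_point_optimal` (list of optimal `sw_design`s or `NULL`),
#'   `superset` (the union `sw_design`), `cell_inclusion_counts` (S x T
#'   integer matrix), `per_point_power` (data frame: icc, cac, variance,
#'   power of the superset), `cost` (total cost of the superset), and
#'   `skipped_points` (data frame of under-powered grid points).
#' @export
superset_search <- function(reference, grid, costs, pw) {
  stopifnot(inherits(reference, "sw_design"), inherits(grid, "sw_corr_grid"),
            inherits(costs, "sw_costs"), inherits(pw, "sw_power_spec"))
  np <- nrow(grid$points)
  per_point_optimal <- vector("list", np)
  per_point <- grid$points
  per_point$complete_power <- NA_real_
  per_point$optimal_iteration <- NA_integer_
  per_point$optimal_power <- NA_real_
  per_point$optimal_cost <- NA_real_
  per_point$optimal_rce <- NA_real_
  per_point$skipped <- FALSE

  counts <- matrix(0L, reference$n_sequences, reference$n_periods)
  union_mask <- matrix(FALSE, reference$n_sequences, reference$n_periods)

  for (i in seq_len(np)) {
    corr <- corr_spec(grid$structure, per_point$icc[i], per_point$cac[i])
    complete_power <- sw_power(reference, corr, pw)
    per_point$complete_power[i] <- complete_power
    if (complete_power < pw$min_power) {
      per_point$skipped[i] <- TRUE
      next
    }
    trace <- greedy_removal_search(reference, corr, costs, pw)
    opt <- select_optimal(trace, pw)
    if (is.null(opt)) {
      # reference meets the power constraint but no reduced design does;
      # this point contributes no cells beyond flagging itself
      per_point$skipped[i] <- TRUE
      next
    }
    per_point_optimal[[i]] <- opt$design
    per_point$optimal_iteration[i] <- opt$index
    per_point$optimal_power[i] <- opt$metrics$power
    per_point$optimal_cost[i] <- opt$metrics$cost
    per_point$optimal_rce[i] <- opt$metrics$rce
    counts <- counts + opt$design$observed
    union_mask <- union_mask | opt$design$observed
  }

  skipped <- per_point[per_point$skipped, c("icc", "cac", "complete_power")]
  rownames(skipped) <- NULL
  if (nrow(skipped) > 0L) {
    warning(sprintf(
      "%d grid point(s) under-powered for the reference design; excluded from the superset",
      nrow(skipped)
    ))
  }
  if (!any(union_mask)) {
    stop("no grid point yielded an optimal design; cannot form a superset")
  }

  superset <- reference
  superset$observed <- union_mask

  contributing <- which(!per_point$skipped)
  ppp <- evaluate_design_over_grid(superset, grid, pw)

  base::structure(
    list(
      per_point = per_point,
      per_point_optimal = per_point_optimal,
      superset = superset,
      cell_inclusion_counts = counts,
      per_point_power = ppp,
      cost = total_cost(superset, costs),
      skipped_points = skipped
    ),
    class = "sw_superset"
  )
}

#' @export
print.sw_superset <- function(x, ...) {
  contributing <- sum(!x$per_point$skipped)
  cat(sprintf(
    "Superset design from %d/%d grid points: %d observed cells, cost %g\n",
    contributing, nrow(x$per_point), sum(x$superset$observed), x$cost
  ))
  pp <- x$per_point_power[!x$per_point$skipped, ]
  if (nrow(pp) > 0L && all(pp$estimable)) {
    cat(sprintf("superset power across contributing points: %.1f%% to %.1f%%\n",
                100 * min(pp$power), 100 * max(pp$power)))
  }
  if (nrow(x$skipped_points) > 0L) {
    cat(sprintf("skipped (under-powered) grid points: %d\n",
                nrow(x$skipped_points)))
  }
  invisible(x)
}

#' Write per-grid-point superset report
#'
#' One row per grid point: icc, cac, complete_power, optimal_iteration,
#' optimal_power, optimal_cost, optimal_rce, skipped.
#'
#' @param result an `sw_superset`.
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_superset_points_csv <- function(result, path) {
  stopifnot(inherits(result, "sw_superset"))
  df <- result$per_point
  df$skipped <- as.integer(df$skipped)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write per-cell superset report
#'
#' One row per sequence-period cell: sequence, period, treatment,
#' inclusion_count (number of grid optima containing the cell),
#' in_superset.
#'
#' @param result an `sw_superset`.
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_superset_cells_csv <- function(result, path) {
  stopifnot(inherits(result, "sw_superset"))
  d <- result$superset
  df <- expand.grid(
    period = seq_len(d$n_periods),
    sequence = seq_len(d$n_sequences)
  )[, c("sequence", "period")]
  df$treatment <- d$treatment[cbind(df$sequence, df$period)]
  df$inclusion_count <- result$cell_inclusion_counts[cbind(df$sequence, df$period)]
  df$in_superset <- as.integer(d$observed[cbind(df$sequence, df$period)])
  df <- df[order(df$sequence, df$period), ]
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
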