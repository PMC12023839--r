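# Cost efficiency, the greedy sequence-period-cell removal search, and
# selection of the optimal design under the power constraint.

#' Cost efficiency of a design
#'
#' The ratio of the precision of the treatment effect estimator to the
#' total trial cost: `CE = 1 / (var(theta-hat) * C)`. Larger is better.
#'
#' @param design an `sw_design` (must be estimable).
#' @param corr an [corr_spec()] object.
#' @param costs an [cost_spec()] object; the design's total cost must be
#'   positive, otherwise CE is undefined.
#' @return Positive cost efficiency.
#' @export
cost_efficiency <- function(design, corr, costs) {
  v <- treatment_variance(design, corr)
  C <- total_cost(design, costs)
  if (C <= 0) stop("total cost is zero; cost efficiency is undefined")
  1 / (v * C)
}

#' Relative cost efficiency of a candidate design
#'
#' `RCE = CE(candidate) / CE(reference)`, equivalently the cost ratio
#' C(reference)/C(candidate) divided by the variance ratio
#' var(candidate)/var(reference). The reference design has RCE exactly 1
#' against itself.
#'
#' @param reference,candidate estimable `sw_design` objects.
#' @inheritParams cost_efficiency
#' @return Positive relative cost efficiency.
#' @export
relative_cost_efficiency <- function(reference, candidate, corr, costs) {
  cost_efficiency(candidate, corr, costs) /
    cost_efficiency(reference, corr, costs)
}

#' Variance, power, cost and (relative) cost efficiency of one design
#'
#' @param design an estimable `sw_design`.
#' @param corr an [corr_spec()] object.
#' @param costs an [cost_spec()] object.
#' @param pw an [power_spec()] object.
#' @param reference optional reference design for the RCE; if omitted,
#'   `rce` is `NA`.
#' @return A list of class `sw_metrics` with elements `variance`, `power`,
#'   `cost`, `ce`, `rce`.
#' @export
design_metrics <- function(design, corr, costs, pw, reference = NULL) {
  v <- treatment_variance(design, corr)
  C <- total_cost(design, costs)
  ce <- 1 / (v * C)
  rce <- if (is.null(reference)) {
    NA_real_
  } else {
    ce / cost_efficiency(reference, corr, costs)
  }
  structure(
    list(variance = v, power = .power_from_variance(v, pw), cost = C,
         ce = ce, rce = rce),
    class = "sw_metrics"
  )
}

#' @export
print.sw_metrics <- function(x, ...) {
  cat(sprintf(
    "variance %.6g | power %.1f%% | cost %g | CE %.4g | RCE %s\n",
    x$variance, 100 * x$power, x$cost, x$ce,
    if (is.na(x$rce)) "-" else sprintf("%.4g", x$rce)
  ))
  invisible(x)
}

# per-sequence cost contribution (Ns-weighted); total_cost = sum over s
.sequence_cost <- function(design, s, costs) {
  z <- sequence_summary(design, s)
  m <- design$cluster_period_size
  design$clusters_per_sequence[s] * (
    costs$cost_per_cluster * z$present +
      costs$cluster_cost_intervention * z$has_intervention_period +
      costs$cluster_cost_control * z$has_control_period +
      m * costs$participant_cost_intervention * z$t_intervention +
      m * costs$participant_cost_control * z$t_control +
      costs$restart_cost_intervention * z$gaps_intervention +
      costs$restart_cost_control * z$gaps_control
  )
}

#' Greedy cost-efficiency-maximizing cell removal search
#'
#' Starting from a reference design D0, iteratively removes one
#' sequence-period cell at a time: at each step every currently observed
#' cell whose removal leaves an estimable design is evaluated, and the cell
#' yielding the reduced design with the highest cost efficiency is removed.
#' Cells whose removal destroys estimability are skipped as candidates; the
#' search stops when no candidate remains, so the final design is minimally
#' viable along the greedy path. Ties in cost efficiency (within 1e-12
#' relative) are broken deterministically in favor of the smallest sequence
#' index, then the smallest period index.
#'
#' The search is fully deterministic: identical inputs produce identical
#' traces.
#'
#' @param reference the complete (or other starting) design; must be
#'   estimable.
#' @param corr an [corr_spec()] object.
#' @param costs an [cost_spec()] object (total cost of the reference must
#'   be positive).
#' @param pw an [power_spec()] object; its `min_power` is used to mark the
#'   optimal design in the trace.
#' @return An object of class `sw_trace`: a list with the `reference`
#'   design, `reference_metrics`, `steps` (one element per removal, each
#'   with `iteration`, `removed` = c(sequence, period), `design`, and
#'   `metrics`), `table` (the per-iteration summary data frame, see
#'   [trace_table()]), and `optimal_index` (iteration index of the
#'   RCE-maximizing design meeting the power constraint, or `NA`).
#' @seealso [select_optimal()], [write_trace_csv()]
#' @export
greedy_removal_search <- function(reference, corr, costs, pw) {
  stopifnot(inherits(reference, "sw_design"), inherits(corr, "sw_corr"),
            inherits(costs, "sw_costs"), inherits(pw, "sw_power_spec"))
  S <- reference$n_sequences
  T_ <- reference$n_periods

  # cached per-sequence information parts and cost terms for current design
  parts <- lapply(seq_len(S), function(s) .sequence_parts(reference, s, corr))
  A <- sum(vapply(parts, `[[`, numeric(1), "A"))
  b <- Reduce(`+`, lapply(parts, `[[`, "b"))
  M <- Reduce(`+`, lapply(parts, `[[`, "M"))
  cost_terms <- vapply(seq_len(S), function(s)
    .sequence_cost(reference, s, costs), numeric(1))

  keep0 <- which(colSums(reference$observed) > 0L)
  v0 <- .variance_from_parts(A, b, M, keep0)
  if (is.na(v0)) .not_estimable("reference design is not estimable")
  C0 <- sum(cost_terms)
  if (C0 <= 0) stop("reference design has zero total cost")
  ce0 <- 1 / (v0 * C0)
  ref_metrics <- structure(
    list(variance = v0, power = .power_from_variance(v0, pw), cost = C0,
         ce = ce0, rce = 1),
    class = "sw_metrics"
  )

  current <- reference
  steps <- list()
  l <- 0L
  repeat {
    best <- NULL
    best_ce <- -Inf
    # enumerate candidates sequence-major for the deterministic tie-break
    for (s in seq_len(S)) {
      js <- which(current$observed[s, ])
      if (length(js) == 0L) next
      for (j in js) {
        cand <- current
        cand$observed[s, j] <- FALSE
        if (!any(cand$observed)) next
        p_new <- .sequence_parts(cand, s, corr)
        keep <- which(colSums(cand$observed) > 0L)
        v <- .variance_from_parts(
          A - parts[[s]]$A + p_new$A,
          b - parts[[s]]$b + p_new$b,
          M - parts[[s]]$M + p_new$M,
          keep
        )
        if (is.na(v)) next
        C <- sum(cost_terms) - cost_terms[s] + .sequence_cost(cand, s, costs)
        ce <- 1 / (v * C)
        # strict improvement beyond 1e-12 relative: first (smallest s, j) wins ties
        if (ce > best_ce * (1 + 1e-12) && ce > best_ce) {
          best_ce <- ce
          best <- list(s = s, j = j, variance = v, cost = C, ce = ce)
        }
      }
    }
    if (is.null(best)) break
    l <- l + 1L
    current$observed[best$s, best$j] <- FALSE
    p_new <- .sequence_parts(current, best$s, corr)
    A <- A - parts[[best$s]]$A + p_new$A
    b <- b - parts[[best$s]]$b + p_new$b
    M <- M - parts[[best$s]]$M + p_new$M
    parts[[best$s]] <- p_new
    cost_terms[best$s] <- .sequence_cost(current, best$s, costs)
    metrics <- structure(
      list(variance = best$variance,
           power = .power_from_variance(best$variance, pw),
           cost = best$cost, ce = best$ce, rce = best$ce / ce0),
      class = "sw_metrics"
    )
    steps[[l]] <- list(iteration = l, removed = c(best$s, best$j),
                       design = current, metrics = metrics)
  }

  trace <- structure(
    list(reference = reference, corr = corr, costs = costs, pw = pw,
         reference_metrics = ref_metrics, steps = steps,
         table = NULL, optimal_index = NA_integer_),
    class = "sw_trace"
  )
  trace$table <- trace_table(trace)
  opt <- select_optimal(trace, pw)
  trace$optimal_index <- if (is.null(opt)) NA_integer_ else opt$index
  trace
}

#' Select the optimal design from a removal trace
#'
#' Among the trace's reduced designs with power at least `min_power`,
#' returns the one maximizing the relative cost efficiency. The reference
#' design itself is not a member of the searched design space, so if no
#' reduced design meets the power constraint the result is `NULL`
#' (meaning: use the complete design, or none is adequate if even the
#' reference is under-powered).
#'
#' @param trace an `sw_trace` from [greedy_removal_search()].
#' @param pw an [power_spec()]; defaults to the one stored in the trace.
#' @return `NULL`, or a list with `index` (iteration number), `design`, and
#'   `metrics`.
#' @export
select_optimal <- function(trace, pw = NULL) {
  stopifnot(inherits(trace, "sw_trace"))
  if (is.null(pw)) pw <- trace$pw
  stopifnot(inherits(pw, "sw_power_spec"))
  if (length(trace$steps) == 0L) return(NULL)
  pows <- vapply(trace$steps, function(st) st$metrics$power, numeric(1))
  rces <- vapply(trace$steps, function(st) st$metrics$rce, numeric(1))
  ok <- which(pows >= pw$min_power)
  if (length(ok) == 0L) return(NULL)
  idx <- ok[which.max(rces[ok])]
  list(index = idx, design = trace$steps[[idx]]$design,
       metrics = trace$steps[[idx]]$metrics)
}

#' Per-iteration summary table of a removal trace
#'
#' @param trace an `sw_trace`.
#' @return Data frame with columns `iteration`, `removed_sequence`,
#'   `removed_period`, `cells_remaining`, `fraction_removed`, `variance`,
#'   `power`, `cost`, `ce`, `rce`, `meets_power` (0/1); iteration 0 is the
#'   reference design.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "sw_trace"))
  ref <- trace$reference
  n_ref <- sum(ref$observed)
  row0 <- data.frame(
    iteration = 0L, removed_sequence = NA_integer_,
    removed_period = NA_integer_, cells_remaining = n_ref,
    fraction_removed = 0,
    variance = trace$reference_metrics$variance,
    power = trace$reference_metrics$power,
    cost = trace$reference_metrics$cost,
    ce = trace$reference_metrics$ce, rce = 1,
    meets_power = as.integer(trace$reference_metrics$power >=
                               trace$pw$min_power)
  )
  if (length(trace$steps) == 0L) return(row0)
  rows <- lapply(trace$steps, function(st) {
    data.frame(
      iteration = st$iteration,
      removed_sequence = st$removed[1L],
      removed_period = st$removed[2L],
      cells_remaining = sum(st$design$observed),
      fraction_removed = fraction_removed(st$design, ref),
      variance = st$metrics$variance,
      power = st$metrics$power,
      cost = st$metrics$cost,
      ce = st$metrics$ce,
      rce = st$metrics$rce,
      meets_power = as.integer(st$metrics$power >= trace$pw$min_power)
    )
  })
  out <- rbind(row0, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Write a removal trace to CSV
#'
#' Writes the [trace_table()] in a fixed column order for diffability.
#'
#' @param trace an `sw_trace`.
#' @param path output file path.
#' @return Invisibly, the table written.
#' @export
write_trace_csv <- function(trace, path) {
  tab <- trace$table
  if (is.null(tab)) tab <- trace_table(trace)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' @export
print.sw_trace <- function(x, ...) {
  cat(sprintf(
    "Greedy removal trace: %d reduced designs from a %d-cell reference\n",
    length(x$steps), sum(x$reference$observed)
  ))
  cat("reference: ")
  print(x$reference_metrics)
  if (!is.na(x$optimal_index)) {
    st <- x$steps[[x$optimal_index]]
    cat(sprintf("optimal design (iteration %d, %.0f%% of cells removed): ",
                x$optimal_index,
                100 * fraction_removed(st$design, x$reference)))
    print(st$metrics)
  } else {
    cat("no reduced design meets the power constraint\n")
  }
  invisible(x)
}
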