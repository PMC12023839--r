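test_that("cost efficiency identities", {
  d <- alliance_design()
  corr <- corr_spec("discrete_time_decay", 0.05, 0.95)
  costs <- alliance_costs()
  ce <- cost_efficiency(d, corr, costs)
  expect_equal(ce * total_cost(d, costs) * treatment_variance(d, corr), 1)

  doubled <- cost_spec(
    cost_per_cluster = 5000, participant_cost_intervention = 280,
    participant_cost_control = 160, restart_cost_intervention = 460
  )
  expect_equal(cost_efficiency(d, corr, doubled), ce / 2)

  expect_equal(relative_cost_efficiency(d, d, corr, costs), 1)
  expect_error(cost_efficiency(d, corr, cost_spec()), "zero")
})

test_that("tiny-design CE equals composition of the independent oracles", {
  d <- sw_complete(2, c(1, 1), 2)
  corr <- corr_spec("discrete_time_decay", 0.2, 0.8)
  costs <- cost_spec(cost_per_cluster = 10, participant_cost_intervention = 3,
                     participant_cost_control = 2)
  v_oracle <- oracle_individual_gls(d, corr)
  # hand cost: 2 clusters * 10 + m=2 * (3 * 3 int periods + 2 * 3 con periods)
  c_hand <- 2 * 10 + 2 * (3 * 3 + 2 * 3)
  expect_equal(cost_efficiency(d, corr, costs), 1 / (v_oracle * c_hand),
               tolerance = 1e-10)
})

test_that("greedy first step matches exhaustive single-removal enumeration", {
  pw <- power_spec(0.26)
  set.seed(23)
  for (rep in 1:5) {
    d <- sw_complete(3, sample(1:3, 3, replace = TRUE), sample(2:5, 1))
    corr <- corr_spec("discrete_time_decay", stats::runif(1, 0.01, 0.3),
                      stats::runif(1, 0.7, 1))
    costs <- cost_spec(
      cost_per_cluster = sample(100:2000, 1),
      participant_cost_intervention = sample(10:100, 1),
      participant_cost_control = sample(10:100, 1),
      restart_cost_intervention = sample(0:300, 1)
    )
    trace <- greedy_removal_search(d, corr, costs, pw)
    expect_equal(trace$steps[[1]]$removed,
                 oracle_best_single_removal(d, corr, costs))
  }
})

test_that("trace invariants hold along the ALLIANCE search", {
  d <- alliance_design()
  corr <- corr_spec("discrete_time_decay", 0.05, 0.95)
  pw <- power_spec(0.26)
  trace <- greedy_removal_search(d, corr, alliance_costs(), pw)

  prev <- d
  prev_var <- trace$reference_metrics$variance
  for (st in trace$steps) {
    # exactly one cell removed per step
    expect_equal(sum(prev$observed) - sum(st$design$observed), 1L)
    expect_true(all(!st$design$observed | prev$observed))
    # every trace design estimable, variance non-decreasing
    expect_true(is_estimable(st$design, corr))
    expect_gte(st$metrics$variance, prev_var * (1 - 1e-12))
    prev <- st$design
    prev_var <- st$metrics$variance
  }
  # terminal design is minimally viable along the path
  final <- trace$steps[[length(trace$steps)]]$design
  cells <- which(final$observed, arr.ind = TRUE)
  for (i in seq_len(nrow(cells))) {
    cand <- final
    cand$observed[cells[i, 1], cells[i, 2]] <- FALSE
    expect_false(any(cand$observed) && is_estimable(cand, corr))
  }
})

test_that("without restart costs the cost strictly decreases along the trace", {
  d <- sw_complete(4, rep(2, 4), 3)
  corr <- corr_spec("discrete_time_decay", 0.1, 0.9)
  costs <- cost_spec(cost_per_cluster = 500,
                     participant_cost_intervention = 20,
                     participant_cost_control = 10)
  trace <- greedy_removal_search(d, corr, costs, power_spec(0.26))
  costs_along <- vapply(trace$steps, function(st) st$metrics$cost, numeric(1))
  expect_true(all(diff(c(trace$reference_metrics$cost, costs_along)) < 0))
  # and the RCE numerator (cost ratio) is then always >= 1
  expect_true(all(trace$reference_metrics$cost / costs_along >= 1))
})

test_that("search is deterministic", {
  d <- alliance_design()
  corr <- corr_spec("discrete_time_decay", 0.05, 0.95)
  t1 <- greedy_removal_search(d, corr, alliance_costs(), power_spec(0.26))
  t2 <- greedy_removal_search(d, corr, alliance_costs(), power_spec(0.26))
  expect_identical(t1$table, t2$table)
})

test_that("select_optimal respects the power constraint", {
  d <- alliance_design()
  corr <- corr_spec("discrete_time_decay", 0.05, 0.95)
  trace <- greedy_removal_search(d, corr, alliance_costs(), power_spec(0.26))
  opt <- select_optimal(trace)
  expect_gte(opt$metrics$power, 0.8)
  tab <- trace$table
  qualifying <- tab[tab$iteration > 0 & tab$meets_power == 1, ]
  expect_equal(opt$metrics$rce, max(qualifying$rce))

  # unreachable power constraint: no qualifying reduced design
  expect_null(select_optimal(trace, power_spec(0.26, min_power = 0.999)))
})

test_that("non-estimable reference raises the dedicated error", {
  d <- sw_complete(2, c(1, 1), 1)
  d$observed <- d$treatment == 0L
  expect_error(
    greedy_removal_search(d, corr_spec("exchangeable", 0.1), alliance_costs(),
                          power_spec(0.26)),
    class = "swce_not_estimable"
  )
})

test_that("trace table has the documented shape", {
  d <- sw_complete(3, rep(1, 3), 2)
  corr <- corr_spec("exchangeable", 0.1)
  costs <- cost_spec(cost_per_cluster = 10, participant_cost_intervention = 1,
                     participant_cost_control = 1)
  trace <- greedy_removal_search(d, corr, costs, power_spec(0.26))
  tab <- trace$table
  expect_equal(names(tab),
               c("iteration", "removed_sequence", "removed_period",
                 "cells_remaining", "fraction_removed", "variance", "power",
                 "cost", "ce", "rce", "meets_power"))
  expect_equal(tab$iteration, 0:(nrow(tab) - 1L))
  expect_equal(tab$cells_remaining, sum(d$observed) - tab$iteration)
  expect_equal(tab$rce[1], 1)
})
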