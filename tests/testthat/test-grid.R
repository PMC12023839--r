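test_that("correlation_grid validates and orders points", {
  g <- correlation_grid(c(0.1, 0.01), c(0.9, 0.8))
  expect_equal(g$icc_values, c(0.01, 0.1))
  expect_equal(g$points$icc, c(0.01, 0.01, 0.1, 0.1))
  expect_equal(g$points$cac, c(0.8, 0.9, 0.8, 0.9))
  expect_error(correlation_grid(numeric(0), 0.8), "non-empty")
  expect_error(correlation_grid(1.2, 0.8), "icc")
})

test_that("grid evaluation agrees with direct calls and flags failures", {
  d <- alliance_design()
  pw <- power_spec(0.26)
  g1 <- correlation_grid(0.05, 0.95)
  df <- evaluate_design_over_grid(d, g1, pw)
  expect_equal(df$power, sw_power(d, corr_spec("discrete_time_decay", 0.05, 0.95), pw))
  expect_true(df$estimable)

  bad <- d
  bad$observed <- bad$treatment == 0L
  df2 <- evaluate_design_over_grid(bad, g1, pw)
  expect_false(df2$estimable)
  expect_true(is.na(df2$power))
})

test_that("singleton grid superset equals that point's optimal design", {
  d <- alliance_design()
  costs <- alliance_costs()
  pw <- power_spec(0.26)
  g1 <- correlation_grid(0.05, 0.95)
  res <- superset_search(d, g1, costs, pw)
  trace <- greedy_removal_search(d, corr_spec("discrete_time_decay", 0.05, 0.95),
                                 costs, pw)
  opt <- select_optimal(trace)
  expect_equal(res$superset$observed, opt$design$observed)
  expect_equal(res$cost, opt$metrics$cost)
  expect_equal(res$cell_inclusion_counts, opt$design$observed + 0L,
               ignore_attr = TRUE)
})

test_that("superset is the union and dominates per-point optima", {
  d <- alliance_design()
  costs <- alliance_costs()
  pw <- power_spec(0.26)
  g <- correlation_grid(c(0.01, 0.1), 0.8)
  res <- superset_search(d, g, costs, pw)

  masks <- lapply(res$per_point_optimal, function(x) x$observed)
  masks <- masks[!vapply(masks, is.null, logical(1))]
  expect_equal(res$superset$observed, Reduce(`|`, masks))
  expect_equal(res$cell_inclusion_counts, Reduce(`+`, lapply(masks, `+`, 0L)))
  expect_true(all(res$cell_inclusion_counts[res$superset$observed] >= 1L))
  expect_true(all(res$cell_inclusion_counts <= length(masks)))

  # power monotonicity: superset power >= optimal power at each point
  for (i in seq_len(nrow(res$per_point))) {
    if (res$per_point$skipped[i]) next
    expect_gte(res$per_point_power$power[i],
               res$per_point$optimal_power[i] - 1e-12)
    expect_gte(res$per_point_power$power[i], pw$min_power)
  }
})

test_that("under-powered grid points are skipped with a warning", {
  d <- alliance_design()
  costs <- alliance_costs()
  # ALLIANCE complete powers on this grid span ~82.8% to ~94.7%; demanding
  # 90% makes some points infeasible from the start
  pw <- power_spec(0.26, min_power = 0.9)
  g <- correlation_grid(c(0.01, 0.1), 0.8)
  expect_warning(res <- superset_search(d, g, costs, pw), "under-powered")
  expect_equal(nrow(res$skipped_points), 1L)
  expect_equal(res$skipped_points$icc, 0.1)
  # skipped point contributes nothing to the union
  expect_null(res$per_point_optimal[[which(res$per_point$skipped)]])
  # all-skipped grid cannot form a superset
  expect_error(
    suppressWarnings(superset_search(d, g, costs,
                                     power_spec(0.26, min_power = 0.99))),
    "no grid point"
  )
})

test_that("superset reports round-trip through CSV", {
  d <- alliance_design()
  res <- suppressWarnings(
    superset_search(d, correlation_grid(0.05, c(0.9, 0.95)),
                    alliance_costs(), power_spec(0.26))
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_superset_points_csv(res, p1)
  write_superset_cells_csv(res, p2)
  pts <- utils::read.csv(p1)
  expect_equal(nrow(pts), 2L)
  expect_equal(names(pts)[1:2], c("icc", "cac"))
  cells <- utils::read.csv(p2)
  expect_equal(nrow(cells), 30L)
  expect_equal(sum(cells$in_superset), sum(res$superset$observed))
  expect_equal(sum(cells$inclusion_count), sum(res$cell_inclusion_counts))
})
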