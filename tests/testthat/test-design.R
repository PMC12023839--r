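test_that("sw_complete builds the standard schedule", {
  d <- alliance_design()
  expect_equal(d$n_sequences, 5L)
  expect_equal(d$n_periods, 6L)
  expect_equal(sum(d$clusters_per_sequence), 37L)
  expect_true(all(d$observed))
  # sequence s: control in 1..s, intervention after
  for (s in 1:5) {
    expect_equal(d$treatment[s, ], c(rep(0L, s), rep(1L, 6L - s)))
  }

  d14 <- large15_design()
  expect_equal(d14$n_periods, 15L)
  expect_equal(sum(d14$observed), 210L)

  d2 <- sw_complete(2, c(1, 1), 1)
  expect_equal(d2$treatment, rbind(c(0L, 1L, 1L), c(0L, 0L, 1L)))

  expect_error(sw_complete(1, 1, 1), "n_sequences")
  expect_error(sw_complete(3, c(1, 0, 1), 1), "positive")
  expect_error(sw_complete(3, c(1, 1), 1), "one entry per sequence")
})

test_that("remove_cell has value semantics and validates", {
  d <- alliance_design()
  d2 <- remove_cell(d, 1, 4)
  expect_true(d$observed[1, 4])          # input untouched
  expect_false(d2$observed[1, 4])
  expect_equal(sum(d$observed) - sum(d2$observed), 1L)
  expect_error(remove_cell(d2, 1, 4), "already unobserved")
  expect_error(remove_cell(d, 9, 1), "out of range")
  expect_error(remove_cell(d, 1, 7), "out of range")
})

test_that("sequence presence flips exactly at the last removal", {
  d <- sw_complete(2, c(1, 1), 1)
  for (j in 1:3) {
    expect_true(sequence_summary(d, 1)$present)
    d <- remove_cell(d, 1, j)
  }
  expect_false(sequence_summary(d, 1)$present)
  z <- sequence_summary(d, 1)
  expect_equal(z$t_intervention + z$t_control +
                 z$gaps_intervention + z$gaps_control, 0L)
  expect_false(z$has_intervention_period)
  expect_false(z$has_control_period)
})

test_that("sequence_summary reproduces the worked incomplete-design counts", {
  # 5-sequence incomplete design: sequence 1 measures control p1,
  # intervention p2, p3, pauses p4-p5, resumes intervention in p6
  d <- alliance_design()
  d <- remove_cell(d, 1, 4)
  d <- remove_cell(d, 1, 5)
  z1 <- sequence_summary(d, 1)
  expect_equal(z1$t_intervention, 3L)
  expect_equal(z1$t_control, 1L)
  expect_equal(z1$gaps_intervention, 1L)
  expect_equal(z1$gaps_control, 0L)

  # sequence 2 measures p2 (control), p3, p4 (intervention): no gaps
  for (j in c(1, 5, 6)) d <- remove_cell(d, 2, j)
  z2 <- sequence_summary(d, 2)
  expect_equal(z2$t_intervention, 2L)
  expect_equal(z2$t_control, 1L)
  expect_equal(z2$gaps_intervention, 0L)
  expect_equal(z2$gaps_control, 0L)

  # a pause before a control-period restart is a control-condition gap
  d5 <- remove_cell(alliance_design(), 5, 2)
  z5 <- sequence_summary(d5, 5)
  expect_equal(z5$gaps_control, 1L)
  expect_equal(z5$gaps_intervention, 0L)
})

test_that("complete designs have no gaps; alternating masks count per run", {
  d <- alliance_design()
  for (s in 1:5) {
    z <- sequence_summary(d, s)
    expect_equal(z$gaps_intervention + z$gaps_control, 0L)
  }
  # observed/unobserved/observed/unobserved/observed inside one condition
  d6 <- sw_complete(5, rep(1, 5), 1)
  d6$observed[1, ] <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  z <- sequence_summary(d6, 1)
  expect_equal(z$gaps_intervention + z$gaps_control, 2L)
  # leading unobserved run is not a gap
  expect_equal(z$t_control, 0L)
})

test_that("gap counts match the run-length-encoding oracle on random masks", {
  set.seed(42)
  for (rep in 1:200) {
    S <- sample(2:6, 1)
    d <- random_masked_design(S, p_keep = stats::runif(1, 0.2, 0.9))
    s <- sample(S, 1)
    z <- sequence_summary(d, s)
    orc <- oracle_gap_counts(d$observed[s, ], d$treatment[s, ])
    expect_equal(z$gaps_intervention, unname(orc["intervention"]))
    expect_equal(z$gaps_control, unname(orc["control"]))
    # reconstruction and condition-partition invariants
    J <- which(d$observed[s, ])
    expect_equal(z$t_intervention + z$t_control, length(J))
    expect_equal(z$t_intervention, sum(d$treatment[s, J] == 1L))
    expect_lte(z$gaps_intervention + z$gaps_control,
               max(0L, length(J) - 1L))
  }
})

test_that("fraction_removed", {
  d <- alliance_design()
  expect_equal(fraction_removed(d, d), 0)
  expect_equal(fraction_removed(remove_cell(d, 1, 1), d), 1 / 30)
  expect_error(fraction_removed(sw_complete(2, c(1, 1), 1), d), "dimensions")
})

test_that("schematic round-trips and CSV export are consistent", {
  d <- alliance_design()
  d <- remove_cell(d, 1, 4)
  d <- remove_cell(d, 5, 2)
  sch <- design_schematic(d)
  expect_equal(sch[1], "011.11")
  d2 <- parse_schematic(sch, d$clusters_per_sequence, d$cluster_period_size)
  expect_equal(d2$observed, d$observed)
  expect_equal(d2$treatment, d$treatment)

  expect_error(parse_schematic(c("01", "0"), c(1, 1), 1), "same number")
  expect_error(parse_schematic("0x1", 1, 1), "invalid schematic")

  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("sequence", "period", "treatment", "observed", "clusters"))
  expect_equal(nrow(df), 30L)
  expect_equal(sum(df$observed), sum(d$observed))
  expect_equal(df$clusters[df$sequence == 1][1], 8L)
})
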