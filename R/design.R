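# Sequence-by-period representation of (in)complete stepped wedge designs.
#
# A design is an S x T grid: `treatment` holds the condition implemented by
# every cluster of sequence s in period j (0 control, 1 intervention) and
# `observed` marks the sequence-period cells in which measurements are
# actually collected. All clusters randomized to a sequence share one
# observation pattern, so removal operates on sequence-period (not
# cluster-period) cells. Indices are 1-based everywhere, matching the usual
# trial-report convention.

#' Construct a stepped wedge design object
#'
#' Low-level constructor for a (possibly incomplete) stepped wedge design.
#' Most users will start from [sw_complete()] and derive incomplete designs
#' with [remove_cell()] or [greedy_removal_search()].
#'
#' @param treatment S x T matrix of 0/1 treatment indicators (0 = control,
#'   1 = intervention), one row per sequence, one column per period.
#' @param observed S x T logical matrix; `TRUE` where the cluster-periods of
#'   that sequence-period collect measurements. Defaults to all observed.
#' @param clusters_per_sequence integer vector of length S; number of
#'   clusters randomized to each sequence (all share the sequence's
#'   schedule and observation pattern).
#' @param cluster_period_size number of participants measured in each
#'   observed cluster-period (constant across the design).
#' @return An object of class `sw_design` with elements `n_sequences`,
#'   `n_periods`, `treatment`, `observed`, `clusters_per_sequence`,
#'   `cluster_period_size`.
#' @seealso [sw_complete()], [remove_cell()], [sequence_summary()]
#' @export
sw_design <- function(treatment, observed = NULL, clusters_per_sequence,
                      cluster_period_size) {
  treatment <- as.matrix(treatment)
  if (!all(treatment %in% c(0, 1))) {
    stop("`treatment` must be a matrix over {0, 1}")
  }
  storage.mode(treatment) <- "integer"
  S <- nrow(treatment)
  T_ <- ncol(treatment)
  if (S < 1L || T_ < 1L) stop("`treatment` must have at least one row and column")
  if (is.null(observed)) {
    observed <- matrix(TRUE, S, T_)
  }
  observed <- as.matrix(observed)
  if (!is.logical(observed) || any(is.na(observed))) {
    stop("`observed` must be a logical matrix without NAs")
  }
  if (!identical(dim(observed), dim(treatment))) {
    stop("`observed` and `treatment` must have identical dimensions")
  }
  if (!any(observed)) stop("design must have at least one observed cell")
  clusters_per_sequence <- as.integer(clusters_per_sequence)
  if (length(clusters_per_sequence) != S) {
    stop("`clusters_per_sequence` must have one entry per sequence")
  }
  if (any(is.na(clusters_per_sequence)) || any(clusters_per_sequence < 1L)) {
    stop("`clusters_per_sequence` entries must be positive integers")
  }
  m <- as.integer(cluster_period_size)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    stop("`cluster_period_size` must be a single positive integer")
  }
  structure(
    list(
      n_sequences = S,
      n_periods = T_,
      treatment = treatment,
      observed = observed,
      clusters_per_sequence = clusters_per_sequence,
      cluster_period_size = m
    ),
    class = "sw_design"
  )
}

#' Construct a complete stepped wedge design
#'
#' Builds the standard complete stepped wedge: S sequences over T = S + 1
#' periods, where sequence s implements the control condition in periods
#' 1..s and the intervention in periods s+1..T, and every sequence-period
#' cell is measured.
#'
#' @param n_sequences number of sequences S (at least 2; with a single
#'   sequence the treatment effect is confounded with period effects).
#' @param clusters_per_sequence integer vector of length S of clusters
#'   randomized to each sequence.
#' @param cluster_period_size participants measured per cluster-period.
#' @return An `sw_design` with `n_periods = n_sequences + 1`.
#' @examples
#' # the ALLIANCE-style design: 5 sequences, 37 clusters, 7 per cluster-period
#' d <- sw_complete(5, c(8, 7, 7, 7, 8), 7)
#' print(d)
#' @export
sw_complete <- function(n_sequences, clusters_per_sequence, cluster_period_size) {
  S <- as.integer(n_sequences)
  if (length(S) != 1L || is.na(S) || S < 2L) {
    stop("`n_sequences` must be an integer >= 2")
  }
  T_ <- S + 1L
  treatment <- matrix(0L, S, T_)
  for (s in seq_len(S)) {
    treatment[s, (s + 1L):T_] <- 1L
  }
  sw_design(
    treatment = treatment,
    observed = matrix(TRUE, S, T_),
    clusters_per_sequence = clusters_per_sequence,
    cluster_period_size = cluster_period_size
  )
}

#' Remove one sequence-period cell from a design
#'
#' Returns a new design identical to `design` except that the named cell is
#' no longer observed. The input design is not modified. Removing a cell
#' that is already unobserved is an error (it would indicate a bookkeeping
#' bug in a search over designs).
#'
#' @param design an `sw_design`.
#' @param sequence_index,period_index 1-based cell coordinates.
#' @return A new `sw_design`.
#' @export
remove_cell <- function(design, sequence_index, period_index) {
  stopifnot(inherits(design, "sw_design"))
  s <- as.integer(sequence_index)
  j <- as.integer(period_index)
  if (length(s) != 1L || is.na(s) || s < 1L || s > design$n_sequences) {
    stop("`sequence_index` out of range")
  }
  if (length(j) != 1L || is.na(j) || j < 1L || j > design$n_periods) {
    stop("`period_index` out of range")
  }
  if (!design$observed[s, j]) {
    stop(sprintf("cell (%d, %d) is already unobserved", s, j))
  }
  design$observed[s, j] <- FALSE
  if (!any(design$observed)) {
    stop("removal would leave a design with no observed cells")
  }
  design
}

#' Structural summary of one sequence
#'
#' Counts, for one sequence of a (possibly incomplete) design: the measured
#' periods under each condition, the number of data-collection gaps under
#' each condition, and presence indicators. A gap is a maximal run of
#' unmeasured periods with at least one measured period on each side;
#' leading and trailing unmeasured runs are not gaps. Each gap is attributed
#' to the condition of the first measured period after it (the condition
#' under which data collection restarts, which is what incurs the restart
#' cost).
#'
#' @param design an `sw_design`.
#' @param sequence_index 1-based sequence index.
#' @return A list of class `sw_sequence_summary` with elements
#'   `t_intervention`, `t_control` (measured-period counts),
#'   `gaps_intervention`, `gaps_control` (gap counts), and logicals
#'   `present`, `has_intervention_period`, `has_control_period`. A sequence
#'   with no measured cells returns the all-zero/`FALSE` summary.
#' @export
sequence_summary <- function(design, sequence_index) {
  stopifnot(inherits(design, "sw_design"))
  s <- as.integer(sequence_index)
  if (length(s) != 1L || is.na(s) || s < 1L || s > design$n_sequences) {
    stop("`sequence_index` out of range")
  }
  obs <- design$observed[s, ]
  trt <- design$treatment[s, ]
  J <- which(obs)
  if (length(J) == 0L) {
    return(structure(
      list(
        t_intervention = 0L, t_control = 0L,
        gaps_intervention = 0L, gaps_control = 0L,
        present = FALSE, has_intervention_period = FALSE,
        has_control_period = FALSE
      ),
      class = "sw_sequence_summary"
    ))
  }
  t_int <- sum(trt[J] == 1L)
  t_con <- sum(trt[J] == 0L)
  gaps_int <- 0L
  gaps_con <- 0L
  if (length(J) > 1L) {
    # a jump of > 1 between consecutive observed periods is exactly one gap;
    # restart condition = condition at the observed period ending the gap
    ends <- J[-1L][diff(J) > 1L]
    gaps_int <- sum(trt[ends] == 1L)
    gaps_con <- sum(trt[ends] == 0L)
  }
  structure(
    list(
      t_intervention = t_int, t_control = t_con,
      gaps_intervention = gaps_int, gaps_control = gaps_con,
      present = TRUE,
      has_intervention_period = t_int > 0L,
      has_control_period = t_con > 0L
    ),
    class = "sw_sequence_summary"
  )
}

#' Fraction of reference cells removed
#'
#' Proportion of the reference design's observed sequence-period cells that
#' are unobserved in `design`, as used to index designs along a removal
#' trace ("x% of cells removed").
#'
#' @param design,reference `sw_design` objects on the same grid.
#' @return A proportion in \[0, 1\].
#' @export
fraction_removed <- function(design, reference) {
  stopifnot(inherits(design, "sw_design"), inherits(reference, "sw_design"))
  if (design$n_sequences != reference$n_sequences ||
      design$n_periods != reference$n_periods) {
    stop("`design` and `reference` must share grid dimensions")
  }
  n_ref <- sum(reference$observed)
  (n_ref - sum(design$observed)) / n_ref
}

#' Text schematic of a design
#'
#' One string per sequence, one character per period: `"0"` observed
#' control, `"1"` observed intervention, `"."` unobserved.
#'
#' @param design an `sw_design`.
#' @return Character vector of length `n_sequences`.
#' @seealso [parse_schematic()]
#' @export
design_schematic <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  vapply(seq_len(design$n_sequences), function(s) {
    ch <- ifelse(design$observed[s, ],
                 as.character(design$treatment[s, ]), ".")
    paste(ch, collapse = "")
  }, character(1))
}

#' Parse a text schematic into a design
#'
#' Inverse of [design_schematic()]: rows of `'0'`/`'1'`/`'.'` characters.
#' Unobserved cells need a treatment assignment for bookkeeping; within each
#' row the condition of a `'.'` cell is filled by carrying the last seen
#' condition forward (and the first seen condition backward for leading
#' dots), which is unambiguous for monotone treatment schedules.
#'
#' @param rows character vector, one string per sequence, equal lengths.
#' @param clusters_per_sequence,cluster_period_size as in [sw_design()].
#' @return An `sw_design`.
#' @export
parse_schematic <- function(rows, clusters_per_sequence, cluster_period_size) {
  if (!is.character(rows) || length(rows) < 1L) {
    stop("`rows` must be a non-empty character vector")
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("all schematic rows must have the same number of periods")
  }
  S <- length(rows)
  T_ <- nchar(rows[1L])
  treatment <- matrix(0L, S, T_)
  observed <- matrix(FALSE, S, T_)
  for (s in seq_len(S)) {
    ch <- strsplit(rows[s], "")[[1L]]
    bad <- setdiff(unique(ch), c("0", "1", "."))
    if (length(bad) > 0L) {
      stop(sprintf("invalid schematic character(s): %s", paste(bad, collapse = " ")))
    }
    observed[s, ] <- ch != "."
    val <- rep(NA_integer_, T_)
    val[ch == "0"] <- 0L
    val[ch == "1"] <- 1L
    if (all(is.na(val))) {
      val[] <- 0L # fully-unobserved sequence: condition is irrelevant
    } else {
      # carry last observed condition forward, then first backward
      for (j in seq_len(T_)[-1L]) if (is.na(val[j])) val[j] <- val[j - 1L]
      for (j in rev(seq_len(T_ - 1L))) if (is.na(val[j])) val[j] <- val[j + 1L]
    }
    treatment[s, ] <- val
  }
  sw_design(treatment, observed, clusters_per_sequence, cluster_period_size)
}

#' Export a design as a tidy CSV
#'
#' Writes one row per sequence-period cell with columns `sequence`,
#' `period`, `treatment`, `observed`, `clusters` (1-based indices).
#'
#' @param design an `sw_design`.
#' @param path file path to write.
#' @return Invisibly, the data frame written.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "sw_design"))
  df <- expand.grid(
    period = seq_len(design$n_periods),
    sequence = seq_len(design$n_sequences)
  )[, c("sequence", "period")]
  df$treatment <- design$treatment[cbind(df$sequence, df$period)]
  df$observed <- design$observed[cbind(df$sequence, df$period)]
  df$clusters <- design$clusters_per_sequence[df$sequence]
  df <- df[order(df$sequence, df$period), ]
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf(
    "Stepped wedge design: %d sequences x %d periods, %d clusters, m = %d\n",
    x$n_sequences, x$n_periods, sum(x$clusters_per_sequence),
    x$cluster_period_size
  ))
  cat(sprintf("Observed cells: %d / %d\n", sum(x$observed), length(x$observed)))
  sch <- design_schematic(x)
  for (s in seq_along(sch)) {
    cat(sprintf("  seq %d (N=%d): %s\n", s, x$clusters_per_sequence[s], sch[s]))
  }
  invisible(x)
}

#' @export
print.sw_sequence_summary <- function(x, ...) {
  cat(sprintf(
    "measured periods: %d intervention, %d control; gaps: %d intervention, %d control; present: %s\n",
    x$t_intervention, x$t_control, x$gaps_intervention, x$gaps_control,
    x$present
  ))
  invisible(x)
}
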