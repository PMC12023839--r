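# Flat-text run configurations: parsing, validation and execution.
#
# The config format is one `key: value` pair per line; blank lines and
# lines starting with '#' are ignored. Keys mirror the usual symbols for
# this design problem (c, k, kp, p, pp, g, gp, icc, cac, effect_size,
# alpha, min_power). Unknown keys are errors, for typo safety. `icc` and
# `cac` accept comma-separated lists; if either has more than one value the
# run is a correlation-grid superset run, otherwise a single-point search.

.CONFIG_KEYS <- c(
  "design", "n_sequences", "clusters_per_sequence", "cluster_period_size",
  "schematic", "structure", "icc", "cac", "effect_size", "alpha",
  "min_power", "c", "k", "kp", "p", "pp", "g", "gp",
  "min_power_filter", "write_trace", "write_schematics"
)

.parse_num_list <- function(x, field) {
  v <- suppressWarnings(as.numeric(strsplit(x, ",")[[1L]]))
  if (length(v) == 0L || any(is.na(v))) {
    stop(sprintf("config field `%s`: cannot parse '%s' as number(s)", field, x))
  }
  v
}

.parse_flag <- function(x, field) {
  x <- tolower(trimws(x))
  if (x %in% c("true", "yes", "1")) return(TRUE)
  if (x %in% c("false", "no", "0")) return(FALSE)
  stop(sprintf("config field `%s`: expected true/false, got '%s'", field, x))
}

.num1 <- function(kv, field, default = NULL, lo = -Inf, hi = Inf,
                  lo_open = FALSE, hi_open = FALSE) {
  if (is.null(kv[[field]])) {
    if (is.null(default)) stop(sprintf("config field `%s` is required", field))
    return(default)
  }
  v <- .parse_num_list(kv[[field]], field)
  if (length(v) != 1L) stop(sprintf("config field `%s` must be a single number", field))
  ok <- (v > lo || (!lo_open && v == lo)) && (v < hi || (!hi_open && v == hi))
  if (!ok) {
    stop(sprintf("config field `%s` = %g is out of range", field, v))
  }
  v
}

#' Load and validate a run configuration file
#'
#' Reads a flat `key: value` configuration describing a design, a
#' correlation specification (single point or grid), cost parameters and
#' the power specification. Every field is range-checked before any
#' computation; unknown keys are rejected. Defaults: `alpha` 0.05,
#' `min_power` 0.8, `structure` discrete_time_decay, all costs 0.
#'
#' @param path path to the configuration file.
#' @return An object of class `sw_config`: a list with `design`
#'   (`sw_design`), `corr` (`sw_corr`) or `grid` (`sw_corr_grid`), `costs`
#'   (`sw_costs`), `pw` (`sw_power_spec`), `mode` (`"search"` or
#'   `"superset"`), and output flags.
#' @examples
#' cfg <- load_config(system.file("extdata", "alliance.cfg", package = "swce"))
#' cfg$design
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 1L) stop(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(substr(ln, 1L, pos - 1L))
    val <- trimws(substr(ln, pos + 1L, nchar(ln)))
    if (!key %in% .CONFIG_KEYS) {
      stop(sprintf("unknown config key `%s`", key))
    }
    if (!is.null(kv[[key]])) stop(sprintf("duplicate config key `%s`", key))
    kv[[key]] <- val
  }

  design_kind <- if (is.null(kv$design)) "standard_sw" else kv$design
  m <- as.integer(.num1(kv, "cluster_period_size", lo = 1))
  if (design_kind == "standard_sw") {
    S <- as.integer(.num1(kv, "n_sequences", lo = 2))
    if (is.null(kv$clusters_per_sequence)) {
      stop("config field `clusters_per_sequence` is required")
    }
    Ns <- .parse_num_list(kv$clusters_per_sequence, "clusters_per_sequence")
    design <- sw_complete(S, Ns, m)
  } else if (design_kind == "schematic") {
    if (is.null(kv$schematic)) stop("config field `schematic` is required")
    rows <- trimws(strsplit(kv$schematic, ",")[[1L]])
    if (is.null(kv$clusters_per_sequence)) {
      stop("config field `clusters_per_sequence` is required")
    }
    Ns <- .parse_num_list(kv$clusters_per_sequence, "clusters_per_sequence")
    design <- parse_schematic(rows, Ns, m)
  } else {
    stop(sprintf("config field `design` must be 'standard_sw' or 'schematic', got '%s'",
                 design_kind))
  }

  struct <- if (is.null(kv$structure)) "discrete_time_decay" else kv$structure
  if (!struct %in% c("discrete_time_decay", "block_exchangeable", "exchangeable")) {
    stop(sprintf("config field `structure`: unknown structure '%s'", struct))
  }
  if (is.null(kv$icc)) stop("config field `icc` is required")
  icc <- .parse_num_list(kv$icc, "icc")
  cac <- if (is.null(kv$cac)) {
    if (struct != "exchangeable") stop("config field `cac` is required")
    1
  } else {
    .parse_num_list(kv$cac, "cac")
  }
  if (any(icc < 0 | icc >= 1)) stop("config field `icc`: values must be in [0, 1)")
  if (any(cac < 0 | cac > 1)) stop("config field `cac`: values must be in [0, 1]")

  pw <- power_spec(
    effect_size = .num1(kv, "effect_size", lo = 0, lo_open = TRUE),
    alpha = .num1(kv, "alpha", default = 0.05, lo = 0, hi = 1,
                  lo_open = TRUE, hi_open = TRUE),
    min_power = .num1(kv, "min_power", default = 0.8, lo = 0, hi = 1,
                      lo_open = TRUE, hi_open = TRUE)
  )
  costs <- cost_spec(
    cost_per_cluster = .num1(kv, "c", default = 0, lo = 0),
    cluster_cost_intervention = .num1(kv, "k", default = 0, lo = 0),
    cluster_cost_control = .num1(kv, "kp", default = 0, lo = 0),
    participant_cost_intervention = .num1(kv, "p", default = 0, lo = 0),
    participant_cost_control = .num1(kv, "pp", default = 0, lo = 0),
    restart_cost_intervention = .num1(kv, "g", default = 0, lo = 0),
    restart_cost_control = .num1(kv, "gp", default = 0, lo = 0)
  )

  mode <- if (length(icc) > 1L || length(cac) > 1L) "superset" else "search"
  out <- list(
    design = design, costs = costs, pw = pw, mode = mode,
    structure = struct,
    min_power_filter = if (is.null(kv$min_power_filter)) FALSE else
      .parse_flag(kv$min_power_filter, "min_power_filter"),
    write_trace = if (is.null(kv$write_trace)) TRUE else
      .parse_flag(kv$write_trace, "write_trace"),
    write_schematics = if (is.null(kv$write_schematics)) TRUE else
      .parse_flag(kv$write_schematics, "write_schematics")
  )
  if (mode == "superset") {
    out$grid <- correlation_grid(icc, cac, struct)
  } else {
    out$corr <- corr_spec(struct, icc, cac)
  }
  structure(out, class = "sw_config")
}

#' @export
print.sw_config <- function(x, ...) {
  cat(sprintf("run configuration (%s mode)\n", x$mode))
  print(x$design)
  if (x$mode == "search") print(x$corr) else print(x$grid)
  print(x$costs)
  print(x$pw)
  invisible(x)
}

.run_log <- function(config) {
  c(
    sprintf("mode: %s", config$mode),
    sprintf("design: %d sequences x %d periods, clusters (%s), m = %d",
            config$design$n_sequences, config$design$n_periods,
            paste(config$design$clusters_per_sequence, collapse = ","),
            config$design$cluster_period_size),
    sprintf("structure: %s", config$structure),
    if (config$mode == "search") {
      sprintf("icc: %g | cac: %g", config$corr$icc, config$corr$cac)
    } else {
      sprintf("icc: %s | cac: %s",
              paste(config$grid$icc_values, collapse = ","),
              paste(config$grid$cac_values, collapse = ","))
    },
    sprintf("effect_size: %g | alpha: %g | min_power: %g",
            config$pw$effect_size, config$pw$alpha, config$pw$min_power),
    sprintf("costs: c=%g k=%g kp=%g p=%g pp=%g g=%g gp=%g",
            config$costs$cost_per_cluster,
            config$costs$cluster_cost_intervention,
            config$costs$cluster_cost_control,
            config$costs$participant_cost_intervention,
            config$costs$participant_cost_control,
            config$costs$restart_cost_intervention,
            config$costs$restart_cost_control),
    "tie_break: smallest sequence index, then smallest period index (1e-12 relative CE tolerance)"
  )
}

#' Execute a run configuration
#'
#' Runs the single-point greedy search or the grid superset procedure as
#' configured and writes all outputs to a directory: a run log echoing
#' every parameter, the trace CSV and per-iteration design schematics
#' (search mode), the per-point and per-cell reports (superset mode), and
#' a machine-readable `summary.json`. All outputs are deterministic:
#' re-running the same configuration reproduces them byte-for-byte.
#'
#' @param config an `sw_config` from [load_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `status` (`"ok"` or
#'   `"no_qualifying_design"`) and the computed `trace` or `superset`
#'   object.
#' @export
run_config <- function(config, out_dir) {
  stopifnot(inherits(config, "sw_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(.run_log(config), file.path(out_dir, "run_log.txt"))

  if (config$mode == "search") {
    trace <- greedy_removal_search(config$design, config$corr, config$costs,
                                   config$pw)
    tab <- trace$table
    if (config$min_power_filter) {
      tab <- tab[tab$meets_power == 1L, ]
    }
    if (config$write_trace) {
      utils::write.csv(tab, file.path(out_dir, "trace.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    if (config$write_schematics) {
      con <- file(file.path(out_dir, "designs.txt"), "w")
      writeLines(c("iteration 0 (reference)", design_schematic(config$design)), con)
      for (st in trace$steps) {
        writeLines(c(
          sprintf("iteration %d (removed sequence %d, period %d)",
                  st$iteration, st$removed[1L], st$removed[2L]),
          design_schematic(st$design)
        ), con)
      }
      close(con)
    }
    opt <- select_optimal(trace, config$pw)
    summary <- list(
      mode = "search",
      reference = list(
        cells = sum(config$design$observed),
        variance = trace$reference_metrics$variance,
        power = trace$reference_metrics$power,
        cost = trace$reference_metrics$cost,
        ce = trace$reference_metrics$ce
      ),
      n_reduced_designs = length(trace$steps),
      optimal = if (is.null(opt)) NULL else list(
        iteration = opt$index,
        fraction_removed = fraction_removed(opt$design, config$design),
        variance = opt$metrics$variance,
        power = opt$metrics$power,
        cost = opt$metrics$cost,
        ce = opt$metrics$ce,
        rce = opt$metrics$rce,
        schematic = design_schematic(opt$design)
      )
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    status <- if (is.null(opt)) "no_qualifying_design" else "ok"
    return(invisible(list(status = status, trace = trace, optimal = opt)))
  }

  # superset mode
  result <- withCallingHandlers(
    superset_search(config$design, config$grid, config$costs, config$pw),
    warning = function(w) {
      message(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  write_superset_points_csv(result, file.path(out_dir, "superset_points.csv"))
  write_superset_cells_csv(result, file.path(out_dir, "superset_cells.csv"))
  if (config$write_schematics) {
    writeLines(c("superset design", design_schematic(result$superset)),
               file.path(out_dir, "designs.txt"))
  }
  contributing <- !result$per_point$skipped
  summary <- list(
    mode = "superset",
    superset = list(
      cells = sum(result$superset$observed),
      fraction_removed = fraction_removed(result$superset, config$design),
      cost = result$cost,
      min_power = min(result$per_point_power$power[contributing]),
      max_power = max(result$per_point_power$power[contributing]),
      schematic = design_schematic(result$superset)
    ),
    n_grid_points = nrow(result$per_point),
    n_skipped = nrow(result$skipped_points)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(status = "ok", superset = result))
}
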