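#' Load a run configuration
#'
#' Reads a YAML run configuration, validates it against the known schema
#' (unknown keys are rejected with the offending name), and resolves the
#' parameter and control blocks into [snn_params()] / [learn_control()]
#' objects. Shipped per-task configurations live under
#' `system.file("configs", package = "spikelearn")`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with elements `task`, `params`,
#'   `control`, `seed`, `iterations`, and task-specific extras.
#' @examples
#' cfg <- load_config(system.file("configs", "few_presentations.yaml",
#'                                package = "spikelearn"))
#' cfg$params$T
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("empty configuration: ", path)
  top_allowed <- c("task", "params", "control", "seed", "iterations",
                   "clock_channels", "eval_every", "n_realizations",
                   "noise_ratios", "max_presentations", "criterion",
                   "output_dir")
  unknown <- setdiff(names(raw), top_allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  tasks <- c("trajectory3d", "xor", "few_presentations", "robustness")
  if (is.null(raw$task) || !raw$task %in% tasks)
    stop("key 'task' must be one of: ", paste(tasks, collapse = ", "))
  if (is.null(raw$seed)) stop("key 'seed' is mandatory (no implicit RNG)")
  base_task <- if (raw$task == "robustness") "trajectory3d" else raw$task
  # YAML 1.1 parses bare N/T keys as booleans; map them back
  names(raw$params)[names(raw$params) == "FALSE"] <- "N"
  names(raw$params)[names(raw$params) == "TRUE"] <- "T"
  pkeys <- setdiff(names(formals(snn_params)), c("exc", "..."))
  unknown <- setdiff(names(raw$params), pkeys)
  if (length(unknown))
    stop("unknown 'params' key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(task_params, c(list(task = base_task), raw$params))
  ckeys <- names(formals(learn_control))
  unknown <- setdiff(names(raw$control), ckeys)
  if (length(unknown))
    stop("unknown 'control' key(s): ", paste(unknown, collapse = ", "))
  control <- do.call(learn_control, raw$control %||% list())
  cfg <- raw
  cfg$params <- params
  cfg$control <- control
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes a [load_config()]-compatible YAML file; `save_config` followed by
#' `load_config` round-trips losslessly.
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$params <- unclass(out$params)
  out$params$exc <- NULL
  out$control <- Filter(Negate(is.null), unclass(out$control))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a raster (or any matrix) as CSV for inspection
#'
#' Rows are time steps, columns neurons; the time index is the first column.
#'
#' @param raster `N x T` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  df <- as.data.frame(t(raster))
  names(df) <- paste0("n", seq_len(nrow(raster)))
  df <- cbind(t = seq_len(ncol(raster)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a raster written by [write_raster_csv()]
#'
#' @param path CSV path.
#' @return An `N x T` matrix.
#' @export
read_raster_csv <- function(path) {
  df <- utils::read.csv(path)
  t(as.matrix(df[, -1, drop = FALSE]))
}

#' Write a run report
#'
#' Persists the artifacts of a completed experiment run to a directory:
#' metric curves as CSV, weights and rasters as RDS containers, decoded
#' trajectories as CSV, and a JSON summary carrying the headline numbers,
#' the seeds and the package version for provenance.
#'
#' @param run A `trajectory_experiment`, `few_presentations_experiment`,
#'   `noise_experiment`, or `xor_experiment` object.
#' @param dir Output directory (created if missing).
#' @return The summary list, invisibly.
#' @export
report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ver <- as.character(utils::packageVersion("spikelearn"))
  summary <- list(package_version = ver, timestamp = format(Sys.time()))
  if (inherits(run, "trajectory_experiment")) {
    utils::write.csv(run$curves, file.path(dir, "mse_curve.csv"),
                     row.names = FALSE)
    for (r in seq_along(run$fits)) {
      f <- run$fits[[r]]
      yhat <- predict(f)
      utils::write.csv(cbind(t = seq_len(ncol(yhat)), t(yhat)),
                       file.path(dir, sprintf("output_r%d.csv", r)),
                       row.names = FALSE)
      saveRDS(coef(f, "all"), file.path(dir, sprintf("weights_r%d.rds", r)))
    }
    summary$final_mse <- mean(run$final_mse)
    summary$final_mse_by_realization <- run$final_mse
    summary$seed <- run$seed
  } else if (inherits(run, "few_presentations_experiment")) {
    utils::write.csv(run$counts, file.path(dir, "presentations.csv"),
                     row.names = FALSE)
    utils::write.csv(run$curves, file.path(dir, "mse_curve.csv"),
                     row.names = FALSE)
    agg <- stats::aggregate(presentations ~ schedule, data = run$counts,
                            FUN = function(z) mean(z, na.rm = TRUE),
                            na.action = stats::na.pass)
    summary$mean_presentations <- stats::setNames(as.list(agg$presentations),
                                                  agg$schedule)
    summary$seed <- run$seed
  } else if (inherits(run, "noise_experiment")) {
    utils::write.csv(as.data.frame(run), file.path(dir, "robustness.csv"),
                     row.names = FALSE)
    summary$noise_ratios <- run$noise_ratio
    summary$mse_mean <- run$mse_mean
  } else if (inherits(run, "xor_experiment")) {
    for (mu in 1:4)
      utils::write.csv(cbind(t = seq_len(ncol(run$outputs[[mu]])),
                             y = t(run$outputs[[mu]])),
                       file.path(dir, sprintf("xor_output_%d.csv", mu)),
                       row.names = FALSE)
    saveRDS(list(J = run$J, J_out = run$J_out),
            file.path(dir, "weights.rds"))
    summary$accuracy <- run$accuracy
    summary$success <- run$success
    summary$seed <- run$seed
  } else {
    warning("unrecognised run object: writing a partial report")
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
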