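#' Default pipeline configuration
#'
#' A single nested configuration drives the four pipeline stages (simulate,
#' train, project, validate); it can be written to / read from YAML and
#' individual fields overridden programmatically or from the command line.
#'
#' @param out_dir Directory all stages read from and write to.
#' @param seed Master seed; each stage derives its own stream from it.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = "lucsim_run", seed = 7) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    landscape = list(grid_rows = 100, grid_cols = 100, cell_size = 100,
                     n_classes = 6, n_steps = 4, change_rate = 0.05,
                     window_cells = 7),
    model = list(engine = "multinom", hidden_sizes = c(64, 48, 32, 24, 16),
                 dropout_rate = 0.2, validation_split = 0.2,
                 max_epochs = 60, patience = 10, batch_size = 256,
                 smote_k = 5),
    project = list(n_steps = 3, tolerance = NULL, max_iter = 1000,
                   scenario_tag = "BASE"),
    validate = list(reference = NULL, predicted = NULL)
  )
}

#' Read a YAML pipeline configuration
#'
#' Missing fields fall back to [default_config()]; unknown top-level fields
#' are reported with their paths.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  merge_cfg <- function(d, c) {
    for (nm in names(c)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(c[[nm]])) {
        merge_cfg(d[[nm]], c[[nm]])
      } else c[[nm]]
    }
    d
  }
  merge_cfg(def, cfg)
}

log_msg <- function(...) message(sprintf("[lucsim %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))

#' Pipeline stage: simulate
#'
#' Generates the synthetic landscape of the configuration and writes the
#' complete runnable fixture (rasters, point CSV, demand CSV, transition
#' CSVs) to `out_dir/fixture`.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly, the fixture directory.
#' @export
pipeline_simulate <- function(config = default_config()) {
  lc <- config$landscape
  cfg <- landscape_config(grid_rows = lc$grid_rows, grid_cols = lc$grid_cols,
                          cell_size = lc$cell_size, n_classes = lc$n_classes,
                          n_steps = lc$n_steps, change_rate = lc$change_rate,
                          window_cells = lc$window_cells, seed = config$seed)
  fix_dir <- file.path(config$out_dir, "fixture")
  log_msg("simulate: writing fixture to %s", fix_dir)
  write_fixture(cfg, fix_dir, n_future = config$project$n_steps)
  invisible(fix_dir)
}

read_fixture <- function(config) {
  fix_dir <- file.path(config$out_dir, "fixture")
  cb_tab <- utils::read.csv(file.path(fix_dir, "codebook.csv"))
  cb <- class_codebook(cb_tab$id, cb_tab$name, static = cb_tab$static)
  files <- sort(list.files(fix_dir, pattern = "^lulc_t[0-9]+\\.asc$",
                           full.names = TRUE))
  maps <- lapply(files, read_map, codebook = cb)
  stack <- read_stack(file.path(fix_dir, "predictors"))
  list(dir = fix_dir, codebook = cb, maps = maps, stack = stack)
}

#' Pipeline stage: train
#'
#' Trains the suitability model on the fixture's observed series and persists
#' it (with its embedded feature schema and standardisation parameters) to
#' `out_dir/model.rds`, plus the training history as CSV.
#'
#' @param config Configuration list.
#' @return Invisibly, the fitted `suitability_model`.
#' @export
pipeline_train <- function(config = default_config()) {
  fix <- read_fixture(config)
  mc <- config$model
  spec <- model_spec(hidden_sizes = mc$hidden_sizes,
                     dropout_rate = mc$dropout_rate,
                     validation_split = mc$validation_split,
                     max_epochs = mc$max_epochs, patience = mc$patience,
                     batch_size = mc$batch_size, engine = mc$engine,
                     seed = config$seed)
  log_msg("train: engine %s on %d observed maps", mc$engine, length(fix$maps))
  model <- train_suitability(fix$maps, fix$stack, fix$codebook, spec,
                             window_cells = config$landscape$window_cells,
                             smote_k = mc$smote_k, seed = config$seed)
  saveRDS(model, file.path(config$out_dir, "model.rds"))
  utils::write.csv(model$history, file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)
  invisible(model)
}

#' Pipeline stage: project
#'
#' Loads the fixture, the persisted model, the demand CSV and one transition
#' CSV per period, runs the forecast and writes one raster per step
#' (`LULC_<step>_<tag>.asc`) plus convergence diagnostics.
#'
#' @param config Configuration list.
#' @return Invisibly, the [run_forecast()] output.
#' @export
pipeline_project <- function(config = default_config()) {
  fix <- read_fixture(config)
  model_path <- file.path(config$out_dir, "model.rds")
  if (!file.exists(model_path)) stop("no trained model at ", model_path,
                                     "; run pipeline_train() first")
  model <- readRDS(model_path)
  n_steps <- config$project$n_steps
  n_obs <- length(fix$maps)
  dyn_total <- sum(observed_prevalence(fix$maps[[n_obs]]))
  sched <- read_demand_csv(file.path(fix$dir, "demand.csv"), dyn_total,
                           observed = c(rep(TRUE, n_obs),
                                        rep(FALSE, n_steps)))
  rules <- lapply(seq_len(n_steps), function(p) {
    path <- file.path(fix$dir, sprintf("transitions_p%d.csv", p))
    if (!file.exists(path)) stop("missing transition file for period ", p,
                                 ": ", path)
    load_transition_matrix(path, sprintf("period%d", p), fix$codebook)
  })
  log_msg("project: %d steps, %d dynamic cells", n_steps, dyn_total)
  fc <- run_forecast(model, fix$maps[(n_obs - 2):n_obs], fix$stack, sched,
                     rules, n_steps = n_steps,
                     window_cells = config$landscape$window_cells,
                     tolerance = config$project$tolerance,
                     max_iter = config$project$max_iter)
  for (s in seq_len(n_steps)) {
    write_map(fc$maps[[s]],
              file.path(config$out_dir,
                        sprintf("LULC_t%d_%s.asc", n_obs + s,
                                config$project$scenario_tag)))
  }
  diag <- do.call(rbind, lapply(seq_len(n_steps), function(s) {
    r <- fc$results[[s]]
    data.frame(step = s, iterations = r$iterations, converged = r$converged,
               max_abs_deviation = max(abs(r$deviation)))
  }))
  utils::write.csv(diag, file.path(config$out_dir, "allocation_diagnostics.csv"),
                   row.names = FALSE)
  audit <- demand_audit(fix$maps[[1]], sched, fc$maps)
  utils::write.csv(cbind(step = rownames(audit), as.data.frame(audit)),
                   file.path(config$out_dir, "demand_audit.csv"),
                   row.names = FALSE)
  invisible(fc)
}

#' Pipeline stage: validate
#'
#' Compares two categorical rasters and writes the metrics report
#' (`metrics_summary.csv`, `metrics_classes.csv`).
#'
#' @param config Configuration list; `config$validate$reference` and
#'   `config$validate$predicted` are raster paths (default: the fixture's
#'   last observed map vs the first projected map).
#' @return Invisibly, the `metrics_report`.
#' @export
pipeline_validate <- function(config = default_config()) {
  fix <- read_fixture(config)
  v <- config$validate
  ref_path <- v$reference
  prd_path <- v$predicted
  if (is.null(ref_path)) {
    ref_path <- file.path(fix$dir, sprintf("lulc_t%d.asc", length(fix$maps)))
  }
  if (is.null(prd_path)) {
    prd_path <- file.path(config$out_dir,
                          sprintf("LULC_t%d_%s.asc", length(fix$maps) + 1,
                                  config$project$scenario_tag))
  }
  ref <- read_map(ref_path, fix$codebook)
  prd <- read_map(prd_path, fix$codebook, expect_grid = ref$grid)
  rep <- metrics_report(ref, prd)
  write_metrics_csv(rep, file.path(config$out_dir, "metrics"))
  log_msg("validate: overall accuracy %.3f", rep$overall["oa"])
  invisible(rep)
}
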