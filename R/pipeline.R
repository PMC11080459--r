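#' Pipeline configuration
#'
#' Assembles the full configuration of a simulation + analysis experiment,
#' with the study defaults: 49-pixel target barcode over 1400-1800 cm^-1,
#' model grid 1300-1800 cm^-1 at 2 cm^-1, 247 items per class, 70/30
#' stratified split, 160 training epochs with dropout 0.2, and a 3-cycle
#' alternating UV/VIS LED protocol (4 min 30 s on, 15 min off) sampled at
#' one frame per 64 s. Every output artifact embeds `config_hash()` of the
#' generating configuration.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param experiment Experiment name (used in artifact file names).
#' @param ... Overrides of the nested defaults (supply whole sublists, e.g.
#'   `dataset = list(n_per_class = 50, contrast = 1)` entries are merged
#'   into the defaults).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, experiment = "metabarcode", ...) {
  cfg <- list(
    experiment = experiment,
    seed = as.integer(seed),
    grid = list(start = 1300, stop = 1800, step = 2),
    barcode = list(n_pixels = 49, resonance_range = c(1400, 1800),
                   Q = 100, amplitude = 0.85),
    layout_seed = 0,
    dataset = list(n_per_class = 247, contrast = 1, block_px = 16),
    noise = list(additive_sigma = 0.01, drift_amplitude = 0.02,
                 drift_timescale_s = 600),
    kinetics = list(k_uv = 0.02, k_vis = 0.02, pss_uv = 0.9, pss_vis = 0.1),
    protocol = list(lead_in_s = 960, n_cycles = 3, on_s = 270, off_s = 900,
                    first_led = "UV", frame_period_s = 64),
    train = list(epochs = 160, dropout = 0.2, lr = 1e-3, batch_size = 32,
                 split_fraction = 0.7),
    ig = list(n_steps = 128, max_items = 64),
    sim = list(block_px = 4)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Configuration hash
#' @param config A [pipeline_config()].
#' @return Character hash identifying the configuration.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

## derived stage seeds (well below 2^31)
stage_seed <- function(config, offset) {
  (config$seed * 1000L + offset) %% 2147483647L
}

cfg_objects <- function(config) {
  grid <- spectral_grid(config$grid$start, config$grid$stop, config$grid$step)
  barcode <- build_target_barcode(config$barcode$n_pixels,
                                  config$barcode$resonance_range,
                                  Q = config$barcode$Q,
                                  amplitude = config$barcode$amplitude)
  layout <- double_and_randomize(barcode, seed = config$layout_seed)
  noise <- noise_model(config$noise$additive_sigma,
                       config$noise$drift_amplitude,
                       config$noise$drift_timescale_s)
  kin <- kinetics_params(config$kinetics$k_uv, config$kinetics$k_vis,
                         config$kinetics$pss_uv, config$kinetics$pss_vis)
  prot <- switch_protocol(config$protocol$lead_in_s, config$protocol$n_cycles,
                          config$protocol$on_s, config$protocol$off_s,
                          config$protocol$first_led,
                          config$protocol$frame_period_s)
  list(grid = grid, barcode = barcode, layout = layout, noise = noise,
       kinetics = kin, protocol = prot)
}

run_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  el <- as.numeric(Sys.time() - t0, units = "secs")
  rec <- list(stage = name, seconds = round(el, 2))
  if (!is.null(log)) {
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log,
        append = TRUE)
  }
  message(sprintf("[%s] %.1f s", name, el))
  res
}

#' Simulate and write the raw experiment artifacts
#'
#' Generates the layout, the switching trajectory, and one hyperspectral
#' cube per frame (64 s of simulated time each), writing the cubes, the
#' layout JSON, the ground-truth trajectory CSV and an event log to
#' `out_dir`. Byte-identical outputs for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the trajectory, layout and file paths.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir = tempfile("sim")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ob <- cfg_objects(config)
  log <- file.path(out_dir, "stages.jsonl")
  traj <- run_stage("trajectory", log, {
    switching_trajectory(ob$protocol, ob$kinetics,
                         initial = membrane_state(config$kinetics$pss_vis))
  })
  cubes <- run_stage("simulate_cubes", log, {
    simulate_cube_series(ob$layout, traj, noise = ob$noise, grid = ob$grid,
                         seed = stage_seed(config, 1L),
                         block_px = config$sim$block_px,
                         background = d2o_background(ob$grid))
  })
  paths <- run_stage("write_artifacts", log, {
    layout_path <- file.path(out_dir, "layout.json")
    write_layout(ob$layout, layout_path)
    traj_path <- file.path(out_dir, "trajectory.csv")
    tr <- traj
    tr$config_hash <- config_hash(config)
    utils::write.csv(tr, traj_path, row.names = FALSE)
    cube_paths <- vapply(seq_along(cubes), function(i) {
      p <- file.path(out_dir, sprintf("cube_%04d.rds", i))
      save_cube(cubes[[i]], p)
      p
    }, "")
    events_path <- file.path(out_dir, "events.json")
    jsonlite::write_json(list(config_hash = config_hash(config),
                              events = ob$protocol$events),
                         events_path, auto_unbox = TRUE, digits = NA)
    list(layout = layout_path, trajectory = traj_path, cubes = cube_paths,
         events = events_path)
  })
  invisible(list(trajectory = traj, layout = ob$layout, paths = paths,
                 config_hash = config_hash(config)))
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on synthetic data: generate the labeled
#' dataset, stratified split, train the original 6-layer CNN, compute
#' integrated-gradients metapixel importances on validation items, select
#' the top metapixel, train the pruned 4-layer CNN on that metapixel's
#' spectra, evaluate both models, and classify a simulated LED-switching
#' time series frame by frame.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for JSON/CSV artifacts (reports,
#'   importances, time-series predictions); `NULL` writes nothing.
#' @return A list report: `eval_original`, `eval_pruned` (confusion +
#'   accuracy), `importance`, `selected` (index, design_id, nu0),
#'   `timeseries` (per-frame predictions with exclusion flags and ground
#'   truth), `trajectory`, `config`, `config_hash`.
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(out_dir, "stages.jsonl")
  }
  ob <- cfg_objects(config)
  ds <- run_stage("generate_dataset", log, {
    generate_labeled_dataset(config$dataset$n_per_class,
                             contrast = config$dataset$contrast,
                             barcode = ob$barcode, noise = ob$noise,
                             grid = ob$grid, kinetics = ob$kinetics,
                             seed = stage_seed(config, 2L),
                             block_px = config$dataset$block_px)
  })
  sp <- run_stage("split", log, {
    split_dataset(ds, config$train$split_fraction,
                  seed = stage_seed(config, 3L))
  })
  m_orig <- run_stage("train_original", log, {
    spec <- cnn_spec("original", n_channels = dim(ds$x)[2],
                     input_length = dim(ds$x)[3])
    train_cnn(build_cnn(spec, seed = stage_seed(config, 4L)),
              sp$train$x, sp$train$labels,
              epochs = config$train$epochs, dropout = config$train$dropout,
              lr = config$train$lr, batch_size = config$train$batch_size,
              seed = stage_seed(config, 5L))
  })
  eval_orig <- run_stage("evaluate_original", log, {
    evaluate_cnn(m_orig, sp$validation$x, sp$validation$labels)
  })
  importance <- run_stage("attribute", log, {
    n_use <- min(config$ig$max_items, dim(sp$validation$x)[1])
    metapixel_importance(m_orig, sp$validation$x[seq_len(n_use), , , drop = FALSE],
                         n_steps = config$ig$n_steps)
  })
  selected <- run_stage("select", log, {
    idx <- select_top_metapixels(importance, ds$nu0, k = 1)
    list(index = idx, design_id = idx, nu0 = ds$nu0[idx])
  })
  m_pruned <- run_stage("train_pruned", log, {
    spec <- cnn_spec("pruned", input_length = dim(ds$x)[3])
    train_cnn(build_cnn(spec, seed = stage_seed(config, 6L)),
              sp$train$x[, selected$index, ], sp$train$labels,
              epochs = config$train$epochs, dropout = config$train$dropout,
              lr = config$train$lr, batch_size = config$train$batch_size,
              seed = stage_seed(config, 7L))
  })
  eval_pruned <- run_stage("evaluate_pruned", log, {
    evaluate_cnn(m_pruned, sp$validation$x[, selected$index, ],
                 sp$validation$labels)
  })
  traj <- run_stage("trajectory", log, {
    switching_trajectory(ob$protocol, ob$kinetics,
                         initial = membrane_state(config$kinetics$pss_vis))
  })
  timeseries <- run_stage("classify_timeseries", log, {
    frames <- generate_frame_spectra(
      traj, ob$barcode$designs[selected$index], noise = ob$noise,
      grid = ob$grid, seed = stage_seed(config, 8L),
      block_px = config$dataset$block_px)
    ts <- classify_timeseries(m_pruned, frames[, 1, ], time_s = traj$time_s,
                              excluded = excluded_frames(traj$time_s, ob$protocol))
    ts$truth <- label_state(traj$cis_fraction)
    ts
  })
  report <- list(eval_original = eval_orig, eval_pruned = eval_pruned,
                 importance = importance, selected = selected,
                 timeseries = timeseries, trajectory = traj,
                 models = list(original = m_orig, pruned = m_pruned),
                 split = list(train_idx = sp$train$idx,
                              validation_idx = sp$validation$idx),
                 config = config, config_hash = config_hash(config))
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(config_hash = report$config_hash,
           accuracy_original = eval_orig$accuracy,
           confusion_original = eval_orig$confusion,
           accuracy_pruned = eval_pruned$accuracy,
           confusion_pruned = eval_pruned$confusion,
           selected = selected),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(metapixel = seq_along(importance),
                                nu0 = ds$nu0, importance = importance,
                                config_hash = report$config_hash),
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
    utils::write.csv(cbind(timeseries, config_hash = report$config_hash),
                     file.path(out_dir, "timeseries.csv"), row.names = FALSE)
  }
  report
}

#' Detect state transitions in a classified time series
#'
#' Scans the non-excluded frames in time order and reports every change of
#' the predicted label between consecutive kept frames.
#'
#' @param timeseries Output of [classify_timeseries()] (needs `time_s`,
#'   `label`, `excluded`).
#' @return Data.frame with `time_before`, `time_after` (kept frames around
#'   the change), `from`, `to`.
#' @export
detect_transitions <- function(timeseries) {
  kept <- timeseries[!timeseries$excluded, , drop = FALSE]
  kept <- kept[order(kept$time_s), , drop = FALSE]
  if (nrow(kept) < 2) {
    return(data.frame(time_before = numeric(0), time_after = numeric(0),
                      from = character(0), to = character(0)))
  }
  ch <- which(kept$label[-1] != kept$label[-nrow(kept)])
  data.frame(time_before = kept$time_s[ch], time_after = kept$time_s[ch + 1],
             from = as.character(kept$label[ch]),
             to = as.character(kept$label[ch + 1]))
}
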