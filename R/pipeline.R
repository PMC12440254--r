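## End-to-end pipeline: simulate -> interrogate -> PCFF report ->
## split -> preprocess -> train -> evaluate, with every artifact stamped
## with the run-config hash and master seed.

#' Full run configuration
#'
#' All randomness in a run flows from `seed`: trial simulation, the
#' train/val/test split, weight initialization, shuffling and dropout all
#' use sub-seeds derived from it.
#'
#' @param task_id Classification task (see [vessel_conditions()]).
#' @param n_per_condition Trials per condition.
#' @param fs Sampling rate (Hz).
#' @param seed Master seed.
#' @param sensor An `fbg_sensor_model`.
#' @param wavelength_noise_sd Interrogator readout noise (nm).
#' @param preprocess A `preprocess_config`.
#' @param model A `model_config` (its `n_classes` must match the task; use
#'   `NULL` to derive it automatically).
#' @param training A `train_config`.
#' @param out_dir Output directory for artifacts.
#' @param ... Preset overrides forwarded to [generate_dataset()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(task_id, n_per_condition = 80, fs = 100, seed = 1,
                       sensor = fbg_sensor_model(),
                       wavelength_noise_sd = 0,
                       preprocess = preprocess_config(),
                       model = NULL, training = train_config(),
                       out_dir = tempfile("pulsegrip_run_"), ...) {
  n_classes <- nrow(vessel_conditions(task_id)) # validates task_id
  if (is.null(model)) model <- model_config(n_classes = n_classes)
  if (model$n_classes != n_classes)
    stop("run_config: model has ", model$n_classes, " classes but task '",
         task_id, "' has ", n_classes)
  structure(list(task_id = task_id,
                 n_per_condition = as.integer(n_per_condition),
                 fs = fs, seed = as.integer(seed), sensor = sensor,
                 wavelength_noise_sd = wavelength_noise_sd,
                 preprocess = preprocess, model = model,
                 training = training, out_dir = out_dir,
                 preset_overrides = list(...)),
            class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every artifact so
#' mismatched intermediates can be refused.
#'
#' @param config A `run_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  ser <- jsonlite::toJSON(unclass(rapply(unclass(config), unclass,
                                         how = "replace")),
                          auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(ser), tmp)
  unname(tools::md5sum(tmp))
}

.stage_msg <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[pulsegrip] %-12s %6.1f s", stage,
                    as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Simulates the task's dataset, renders and demodulates it through the
#' FBG sensor model, writes the PCFF group-comparison report, splits
#' 6:2:2, preprocesses, trains the CNN-LSTM and evaluates the held-out
#' test split. A second run with the same config reproduces every numeric
#' output.
#'
#' @param config A `run_config`.
#' @param quiet Suppress per-stage timing on stderr.
#' @return List with `eval` (the test-split `eval_report`), `pcff_report`,
#'   `history`, `paths` (artifact files), `hash`. Artifacts written:
#'   `manifest.json`, `pcff_report.csv`, `history.csv`, `checkpoint.rds`,
#'   `eval.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed [config ", hash, "]: ",
           conditionMessage(e), call. = FALSE))
    .stage_msg(quiet, name, t0)
    r
  }

  dataset <- stage("simulate", do.call(generate_dataset, c(
    list(task_id = config$task_id,
         n_per_condition = config$n_per_condition, fs = config$fs,
         seed = derive_seed(config$seed, 0, salt = 1)),
    config$preset_overrides)))

  # sensor round trip: force -> wavelength shift -> force
  dataset$sequences <- stage("interrogate", lapply(
    seq_along(dataset$sequences), function(i) {
      tr <- interrogate(dataset$sequences[[i]], config$sensor,
                        wavelength_noise_sd = config$wavelength_noise_sd,
                        seed = derive_seed(config$seed, i, salt = 2))
      trace_to_force(tr, config$sensor)
    }))

  pcff_tab <- stage("pcff", dataset_pcff(dataset,
                                         config = config$preprocess))
  report <- pcff_report(pcff_tab)
  write_pcff_report(report, file.path(config$out_dir, "pcff_report.csv"))

  dataset <- stage("split", split_dataset(
    dataset, ratios = config$preprocess$split_ratios,
    seed = derive_seed(config$seed, 0, salt = 3)))
  manifest_dataset <- dataset
  manifest_dataset$sequences <- list() # manifest only, keep it light
  manifest <- list(config_hash = hash, seed = config$seed,
                   task_id = config$task_id,
                   class_names = dataset$class_names,
                   labels = dataset$labels, split = dataset$split)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  prepped <- stage("preprocess", preprocess_dataset(dataset,
                                                    config$preprocess))

  model <- build_model(config$model, seed = derive_seed(config$seed, 0,
                                                        salt = 4))
  tc <- config$training
  tc$seed <- derive_seed(config$seed, 0, salt = 5)
  fit <- stage("train", train(model, prepped, tc, quiet = quiet))
  utils::write.csv(cbind(fit$history, config_hash = hash),
                   file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)
  saveRDS(list(config_hash = hash, seed = config$seed,
               state = .model_state(model), model_config = config$model),
          file.path(config$out_dir, "checkpoint.rds"))

  ev <- stage("evaluate", evaluate_task(model, prepped, split = "test"))
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed, n_test = ev$n_test,
         confusion = ev$confusion,
         per_class_precision = ev$per_class_precision,
         macro_precision = ev$macro_precision,
         class_names = ev$class_names),
    file.path(config$out_dir, "eval.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  list(eval = ev, pcff_report = report, history = fit$history,
       best_epoch = fit$best_epoch, hash = hash,
       paths = file.path(config$out_dir,
                         c("manifest.json", "pcff_report.csv",
                           "history.csv", "checkpoint.rds", "eval.json")))
}

#' Load a checkpoint written by [run_pipeline()]
#'
#' Refuses a checkpoint whose embedded config hash does not match the
#' given config.
#'
#' @param path Path to `checkpoint.rds`.
#' @param config The `run_config` the checkpoint must belong to (optional).
#' @return A `cnn_lstm_model` with the stored weights.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config) && !identical(ck$config_hash, config_hash(config)))
    stop("load_checkpoint: checkpoint hash ", ck$config_hash,
         " does not match config hash ", config_hash(config))
  model <- build_model(ck$model_config, seed = 1)
  .model_restore(model, ck$state)
  model
}
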