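## Pulsatile grip-force waveform generator.
##
## Each roller pass of the peristaltic pump expels fluid rapidly, so the
## gripping-force waveform has a steep ascending phase peaking at maximum
## fluid pressure followed by a slower decay. We model one period with a
## gamma-like asymmetric pulse p(u) = (u/r)^k * exp(k*(1 - u/r)), u in
## [0, 1), which rises over the fraction r of the period and peaks at 1.
## The template is median-centered and renormalized to unit peak so the
## static clamp force is exactly the median of a noiseless trial and the
## peak sits exactly `pulse_amplitude` above it.

.pulse_shape_raw <- function(u, rise_frac, shape) {
  (u / rise_frac)^shape * exp(shape * (1 - u / rise_frac))
}

.pulse_median_cache <- new.env(parent = emptyenv())

.pulse_template_median <- function(rise_frac, shape) {
  # median of the raw template over one period, on a fixed dense grid
  key <- paste(rise_frac, shape)
  hit <- .pulse_median_cache[[key]]
  if (!is.null(hit)) return(hit)
  u <- (seq_len(8192) - 0.5) / 8192
  m <- stats::median(.pulse_shape_raw(u, rise_frac, shape))
  .pulse_median_cache[[key]] <- m
  m
}

#' Evaluate the unit-peak pulsation template
#'
#' Periodic asymmetric pulse with a fast rise (fraction `rise_frac` of the
#' period) and slower decay, median-centered over one period and scaled to
#' unit peak. Phase `u` is in periods; any real values are wrapped.
#'
#' @param u Phase in periods (numeric vector).
#' @param rise_frac Fraction of the period occupied by the ascending phase.
#' @param shape Sharpness of the pulse (larger = narrower).
#' @return Numeric vector of template values with maximum 1.
#' @export
pulse_template <- function(u, rise_frac = 0.3, shape = 4) {
  m <- .pulse_template_median(rise_frac, shape)
  (.pulse_shape_raw(u %% 1, rise_frac, shape) - m) / (1 - m)
}

#' Simulate one pulsatile gripping trial
#'
#' Generates `baseline_force + a * pulse_template(rate * t + phase) + noise`
#' where the per-trial amplitude `a` is drawn with mean
#' `spec$pulse_amplitude` and coefficient of variation `spec$amplitude_cv`,
#' the phase is uniform over one period, and the noise is white Gaussian
#' with sd `spec$noise_sd`. Fully deterministic for a fixed seed.
#'
#' @param spec A `vessel_model_spec` (see [make_preset()]).
#' @param fs Sampling rate (Hz); must resolve each pulse
#'   (`fs >= 10 * pulse_rate / 60`).
#' @param seed Integer seed for the trial.
#' @param rise_frac,shape Pulse template parameters (see [pulse_template()]).
#' @return A `force_signal` of `round(hold_duration * fs)` samples.
#' @export
simulate_grip_trial <- function(spec, fs = 100, seed = 1,
                                rise_frac = 0.3, shape = 4) {
  stopifnot(inherits(spec, "vessel_model_spec"))
  if (fs < 10 * spec$pulse_rate / 60)
    stop("simulate_grip_trial: fs = ", fs, " Hz is too low to resolve ",
         spec$pulse_rate, " pulses/min; need fs >= ",
         10 * spec$pulse_rate / 60, " Hz")
  n <- round(spec$hold_duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    phase <- stats::runif(1)
    a <- spec$pulse_amplitude * (1 + spec$amplitude_cv * stats::rnorm(1))
    a <- max(a, 0.05 * spec$pulse_amplitude) # keep amplitude positive
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    x <- spec$baseline_force +
      a * pulse_template(t * spec$pulse_rate / 60 + phase, rise_frac, shape) +
      noise
    force_signal(x, fs = fs)
  })
}

#' Generate a labeled synthetic dataset for a classification task
#'
#' One trial per repetition per condition of the named model, labels
#' assigned by condition order (class index 0, 1, ...). Per-trial seeds are
#' derived deterministically from the master seed, so the dataset is
#' reproducible bit-for-bit.
#'
#' @param task_id Model id naming the classification task (see
#'   [vessel_conditions()]).
#' @param n_per_condition Trials per condition (the study protocol uses 80).
#' @param fs Sampling rate (Hz).
#' @param seed Master seed.
#' @param ... Preset overrides forwarded to [make_preset()] (e.g.
#'   `amplitude_cv = 0`, `noise_sd = 0`).
#' @return A `grip_dataset`: list with `sequences` (list of
#'   `force_signal`), `labels` (0-based integer class per sequence),
#'   `class_names`, `split` (NULL until [split_dataset()] runs), `seed`,
#'   `task_id`, `fs`.
#' @export
generate_dataset <- function(task_id, n_per_condition, fs = 100, seed = 1,
                             ...) {
  if (n_per_condition < 1) stop("generate_dataset: n_per_condition must be >= 1")
  tab <- vessel_conditions(task_id)
  sequences <- vector("list", nrow(tab) * n_per_condition)
  labels <- integer(length(sequences))
  trial <- 0L
  for (ci in seq_len(nrow(tab))) {
    spec <- make_preset(task_id, tab$condition_label[ci], ...)
    for (r in seq_len(n_per_condition)) {
      trial <- trial + 1L
      sequences[[trial]] <- simulate_grip_trial(
        spec, fs = fs, seed = derive_seed(seed, trial))
      labels[trial] <- tab$class_index[ci]
    }
  }
  grip_dataset(sequences, labels, class_names = tab$condition_label,
               seed = seed, task_id = task_id, fs = fs)
}

#' Construct a labeled dataset of force sequences
#'
#' @param sequences List of `force_signal` objects.
#' @param labels Integer class labels, 0-based, one per sequence.
#' @param class_names Character vector; `class_names[label + 1]` names each
#'   class.
#' @param split Optional character vector in `{"train","val","test"}` per
#'   sequence.
#' @param seed Seed the dataset was generated with (metadata).
#' @param task_id,fs Metadata.
#' @return A `grip_dataset`.
#' @export
grip_dataset <- function(sequences, labels, class_names, split = NULL,
                         seed = NA_integer_, task_id = NA_character_,
                         fs = NA_real_) {
  labels <- as.integer(labels)
  if (length(labels) != length(sequences))
    stop("grip_dataset: labels and sequences lengths differ")
  if (length(labels) && (min(labels) < 0L || max(labels) >= length(class_names)))
    stop("grip_dataset: labels must be 0-based and < number of class_names")
  if (!is.null(split)) {
    if (length(split) != length(sequences))
      stop("grip_dataset: split length mismatch")
    if (!all(split %in% c("train", "val", "test")))
      stop("grip_dataset: split values must be train/val/test")
  }
  structure(list(sequences = sequences, labels = labels,
                 class_names = class_names, split = split, seed = seed,
                 task_id = task_id, fs = fs),
            class = "grip_dataset")
}

#' @export
print.grip_dataset <- function(x, ...) {
  cat(sprintf("<grip_dataset> %s: %d sequences, %d classes (%s)%s\n",
              x$task_id, length(x$sequences), length(x$class_names),
              paste(x$class_names, collapse = ", "),
              if (is.null(x$split)) "" else sprintf(
                ", split %d/%d/%d", sum(x$split == "train"),
                sum(x$split == "val"), sum(x$split == "test"))))
  invisible(x)
}

#' Write a dataset to disk as CSV sequences plus a JSON manifest
#'
#' Each sequence goes to `seq_<i>.csv` (`time_s,force_n`); the manifest
#' lists file, label, class name, split and the dataset seed.
#'
#' @param dataset A `grip_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("seq_%04d.csv", seq_along(dataset$sequences))
  for (i in seq_along(dataset$sequences))
    write_force_csv(dataset$sequences[[i]], file.path(dir, files[i]))
  manifest <- list(
    task_id = dataset$task_id, seed = dataset$seed, fs = dataset$fs,
    class_names = dataset$class_names,
    sequences = data.frame(
      file = files, label = dataset$labels,
      class_name = dataset$class_names[dataset$labels + 1L],
      split = if (is.null(dataset$split)) NA_character_ else dataset$split))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.json` and sequence CSVs.
#' @return A `grip_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  seqs <- lapply(file.path(dir, manifest$sequences$file), read_force_csv)
  split <- manifest$sequences$split
  if (all(is.na(split))) split <- NULL
  grip_dataset(seqs, manifest$sequences$label,
               class_names = manifest$class_names, split = split,
               seed = manifest$seed, task_id = manifest$task_id,
               fs = manifest$fs)
}
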