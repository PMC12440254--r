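## Signal-chain preprocessing: wavelet denoise -> Z-score -> moving-average
## smoothing, plus the stratified 6:2:2 train/validation/test split.

#' Preprocessing configuration
#'
#' @param wavelet_family Wavelet for denoising (only `"db4"`).
#' @param decomposition_level Decomposition depth; >= 1. The default of 2
#'   keeps every thresholded detail band above `fs / 8` (12.5 Hz at the
#'   default 100 Hz), well clear of the ~1.5 Hz pulse and its meaningful
#'   harmonics, so soft thresholding removes sensor noise without shrinking
#'   the pulse peaks it is meant to preserve.
#' @param threshold_rule Only `"universal"` (`sigma * sqrt(2 log n)`).
#' @param smoothing_window Moving-average width; odd, >= 1.
#' @param split_ratios Train/validation/test proportions.
#' @param split_seed Seed for the stratified split.
#' @param normalization `"pooled"` scales every sequence with mean/sd
#'   pooled over the training split (preserves between-trial amplitude
#'   differences, the feature that separates the classes);
#'   `"per_sequence"` applies [zscore()] to each sequence independently.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(wavelet_family = "db4",
                              decomposition_level = 2,
                              threshold_rule = "universal",
                              smoothing_window = 3,
                              split_ratios = c(6, 2, 2),
                              split_seed = 1,
                              normalization = c("pooled", "per_sequence")) {
  normalization <- match.arg(normalization)
  if (!identical(threshold_rule, "universal"))
    stop("preprocess_config: threshold_rule must be 'universal'")
  if (decomposition_level < 1)
    stop("preprocess_config: decomposition_level must be >= 1")
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("preprocess_config: smoothing_window must be odd and >= 1")
  if (length(split_ratios) != 3 || any(split_ratios <= 0))
    stop("preprocess_config: split_ratios must be 3 positive numbers")
  structure(list(wavelet_family = wavelet_family,
                 decomposition_level = as.integer(decomposition_level),
                 threshold_rule = threshold_rule,
                 smoothing_window = as.integer(smoothing_window),
                 split_ratios = split_ratios,
                 split_seed = as.integer(split_seed),
                 normalization = normalization),
            class = "preprocess_config")
}

#' Z-score a signal
#'
#' Centers to mean 0 and scales to unit standard deviation (sample sd,
#' i.e. divide by `n - 1`; `c(1, 2, 3)` maps to `c(-1, 0, 1)`).
#'
#' @param signal A `force_signal` or numeric vector with positive sd.
#' @return The standardized signal, same type as the input.
#' @export
zscore <- function(signal) {
  x <- if (inherits(signal, "force_signal")) signal$samples else
    as.numeric(signal)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zscore: signal is constant (sd = 0); cannot standardize")
  y <- (x - mean(x)) / s
  if (inherits(signal, "force_signal"))
    force_signal(y, fs = signal$fs, t0 = signal$t0)
  else y
}

#' Centered moving-average smoothing
#'
#' Mean over a centered window; at the edges the window shrinks to the
#' available samples, so the length is preserved and no values are
#' fabricated.
#'
#' @param signal A `force_signal` or numeric vector.
#' @param window Odd window width, `<= length(signal)`.
#' @return Smoothed signal, same type and length as the input.
#' @export
moving_average <- function(signal, window = 3) {
  x <- if (inherits(signal, "force_signal")) signal$samples else
    as.numeric(signal)
  if (window %% 2 == 0) stop("moving_average: window must be odd")
  if (window > length(x))
    stop("moving_average: window exceeds signal length")
  n <- length(x)
  h <- (window - 1) / 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  y <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  if (inherits(signal, "force_signal"))
    force_signal(y, fs = signal$fs, t0 = signal$t0)
  else y
}

#' Stratified train/validation/test split
#'
#' Within each class, `round(n * r_train)` sequences go to training,
#' `round(n * r_val)` to validation and the remainder to test, assigned by
#' a seeded random permutation. Splits are disjoint, exhaustive, and
#' deterministic per seed.
#'
#' @param dataset A `grip_dataset`.
#' @param ratios Three positive numbers (normalized internally).
#' @param seed Seed for the per-class permutations.
#' @return The dataset with its `split` field populated.
#' @export
split_dataset <- function(dataset, ratios = c(6, 2, 2), seed = 1) {
  stopifnot(inherits(dataset, "grip_dataset"))
  if (length(ratios) != 3 || any(ratios <= 0))
    stop("split_dataset: ratios must be 3 positive numbers")
  r <- ratios / sum(ratios)
  split <- character(length(dataset$labels))
  with_seed(seed, {
    for (cls in sort(unique(dataset$labels))) {
      idx <- which(dataset$labels == cls)
      n <- length(idx)
      if (n < 3)
        stop("split_dataset: class ", dataset$class_names[cls + 1L],
             " has only ", n, " sequences; need >= 3")
      n_train <- round(n * r[1])
      n_val <- round(n * r[2])
      if (n_train + n_val >= n) n_val <- max(n - n_train - 1, 1)
      perm <- sample(idx)
      split[perm[seq_len(n_train)]] <- "train"
      split[perm[n_train + seq_len(n_val)]] <- "val"
      split[perm[(n_train + n_val + 1):n]] <- "test"
    }
  })
  dataset$split <- split
  dataset
}

#' Preprocess every sequence of a dataset
#'
#' Fixed chain per sequence: wavelet denoise, then Z-score normalization,
#' then moving-average smoothing. With `normalization = "pooled"` (the
#' default) the centering/scaling constants are the mean and sd pooled
#' over the training-split sequences (over all sequences if no split is
#' assigned), so amplitude differences between trials survive; with
#' `"per_sequence"` each sequence is standardized on its own.
#'
#' @param dataset A `grip_dataset` (ideally already split).
#' @param config A `preprocess_config`.
#' @return The dataset with preprocessed sequences; the pooled constants
#'   are stored in attributes `norm_mean` / `norm_sd`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "grip_dataset"))
  denoised <- lapply(dataset$sequences, wavelet_denoise, config = config)
  if (config$normalization == "pooled") {
    ref <- if (!is.null(dataset$split)) which(dataset$split == "train")
    else seq_along(denoised)
    pooled <- unlist(lapply(denoised[ref], `[[`, "samples"))
    mu <- mean(pooled)
    sdev <- stats::sd(pooled)
    if (!is.finite(sdev) || sdev == 0)
      stop("preprocess_dataset: pooled sd is zero; cannot standardize")
    normed <- lapply(denoised, function(s)
      force_signal((s$samples - mu) / sdev, fs = s$fs, t0 = s$t0))
  } else {
    normed <- lapply(denoised, zscore)
    mu <- NA_real_
    sdev <- NA_real_
  }
  out <- lapply(normed, moving_average, window = config$smoothing_window)
  dataset$sequences <- out
  attr(dataset, "norm_mean") <- mu
  attr(dataset, "norm_sd") <- sdev
  attr(dataset, "preprocess_config") <- config
  dataset
}
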