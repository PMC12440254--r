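## Confusion matrices and precision on held-out test splits. Window-level
## predictions are aggregated to trial level by majority vote before
## scoring (ties broken by the summed class scores).

#' Confusion matrix from 0-based labels
#'
#' @param true,predicted Integer labels in `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return An `n_classes` x `n_classes` count matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  if (length(true) != length(predicted))
    stop("confusion_matrix: label vectors differ in length")
  true <- as.integer(true)
  predicted <- as.integer(predicted)
  if (length(true) &&
      (min(true, predicted) < 0L || max(true, predicted) >= n_classes))
    stop("confusion_matrix: labels out of range [0, ", n_classes, ")")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               predicted = 0:(n_classes - 1)))
  counts <- tabulate(true * n_classes + predicted + 1L,
                     nbins = n_classes * n_classes)
  cm[] <- matrix(counts, n_classes, n_classes, byrow = TRUE)
  cm
}

#' Per-class and macro precision from a confusion matrix
#'
#' Per-class precision is `100 * TP_c / column-sum_c` (percent). Classes
#' never predicted (empty column) have undefined precision; they are
#' flagged and excluded from the macro mean.
#'
#' @param confusion Square count matrix, rows = true class.
#' @return List with `per_class` (percent, `NA` where undefined),
#'   `macro` (percent), `undefined_classes` (0-based indices).
#' @export
precision_score <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop("precision_score: confusion must be a square matrix")
  col_tot <- colSums(confusion)
  per <- ifelse(col_tot > 0, 100 * diag(confusion) / col_tot, NA_real_)
  if (all(is.na(per)))
    stop("precision_score: no class was ever predicted")
  list(per_class = unname(per),
       macro = mean(per, na.rm = TRUE),
       undefined_classes = which(is.na(per)) - 1L)
}

# majority vote over a trial's windows; ties -> argmax of summed scores
.vote_trials <- function(scores, window_trial, n_classes) {
  trials <- sort(unique(window_trial))
  pred <- integer(length(trials))
  for (k in seq_along(trials)) {
    rows <- which(window_trial == trials[k])
    votes <- tabulate(max.col(scores[rows, , drop = FALSE], "first"),
                      nbins = n_classes)
    top <- which(votes == max(votes))
    if (length(top) == 1L) pred[k] <- top - 1L
    else {
      sums <- colSums(scores[rows, , drop = FALSE])
      sums[-top] <- -Inf
      pred[k] <- which.max(sums) - 1L
    }
  }
  list(trials = trials, pred = pred)
}

#' Evaluate a trained model on one split of a dataset
#'
#' Deterministic (evaluation mode): windows the split's sequences,
#' predicts per-window scores, majority-votes them up to trial level and
#' scores the trial-level confusion matrix.
#'
#' @param model A trained `cnn_lstm_model`.
#' @param dataset The preprocessed, split `grip_dataset` used in training.
#' @param split Which split to score (default `"test"`).
#' @return An object of class `eval_report`: `confusion`,
#'   `per_class_precision` (%), `macro_precision` (%), `n_test`,
#'   `class_names`, `predictions` (per-trial data frame).
#' @export
evaluate_task <- function(model, dataset, split = "test") {
  stopifnot(inherits(model, "cnn_lstm_model"),
            inherits(dataset, "grip_dataset"))
  n_classes <- model$config$n_classes
  if (length(dataset$class_names) != n_classes)
    stop("evaluate_task: model has ", n_classes, " classes but dataset has ",
         length(dataset$class_names))
  wins <- make_windows(dataset, model$config$input_length)
  keep <- if (is.null(wins$split)) seq_along(wins$labels)
  else which(wins$split == split)
  if (!length(keep)) stop("evaluate_task: split '", split, "' is empty")
  scores <- predict_scores(model, wins$x[keep, , , drop = FALSE])
  voted <- .vote_trials(scores, wins$trial[keep], n_classes)
  true <- dataset$labels[voted$trials]
  cm <- confusion_matrix(true, voted$pred, n_classes)
  pr <- precision_score(cm)
  structure(list(confusion = cm, per_class_precision = pr$per_class,
                 macro_precision = pr$macro,
                 undefined_classes = pr$undefined_classes,
                 n_test = length(true), class_names = dataset$class_names,
                 predictions = data.frame(trial = voted$trials,
                                          true = true, pred = voted$pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, macro precision %.2f%%\n", x$n_test,
              x$macro_precision))
  cat("per-class precision (%):",
      paste(sprintf("%s %.1f", x$class_names,
                    x$per_class_precision), collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Nearest-class-mean classifier on per-trial mean PCFF
#'
#' A deliberately simple amplitude-threshold reference: class centroids of
#' mean PCFF are fit on the training split and each test trial is assigned
#' to the nearest centroid. For two classes this is a threshold at the
#' midpoint of the class means. Serves as an attainability check for the
#' neural classifier on amplitude-separable tasks.
#'
#' @param pcff_table Per-trial table from [dataset_pcff()] on the raw
#'   dataset.
#' @param dataset The same `grip_dataset`, with a split assigned.
#' @param split Split to score (default `"test"`).
#' @return An `eval_report`.
#' @export
pcff_threshold_classifier <- function(pcff_table, dataset, split = "test") {
  stopifnot(inherits(dataset, "grip_dataset"))
  if (is.null(dataset$split))
    stop("pcff_threshold_classifier: dataset has no split")
  n_classes <- length(dataset$class_names)
  tr <- dataset$split == "train"
  centroids <- vapply(0:(n_classes - 1), function(cls)
    mean(pcff_table$mean_pcff[tr & dataset$labels == cls]), numeric(1))
  te <- which(dataset$split == split)
  pred <- vapply(te, function(i)
    which.min(abs(pcff_table$mean_pcff[i] - centroids)) - 1L, integer(1))
  cm <- confusion_matrix(dataset$labels[te], pred, n_classes)
  pr <- precision_score(cm)
  structure(list(confusion = cm, per_class_precision = pr$per_class,
                 macro_precision = pr$macro,
                 undefined_classes = pr$undefined_classes,
                 n_test = length(te), class_names = dataset$class_names,
                 predictions = data.frame(trial = te,
                                          true = dataset$labels[te],
                                          pred = pred)),
            class = "eval_report")
}
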