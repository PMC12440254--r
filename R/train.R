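## Training recipe: stochastic gradient descent with Nesterov momentum,
## cosine annealing with restarts (base learning rate doubled at each
## restart, capped), binary cross-entropy loss, batch size 128.

#' Training configuration
#'
#' @param base_lr Initial learning rate (0.002).
#' @param momentum Nesterov momentum (0.9).
#' @param decay_steps Optimizer steps per cosine cycle (50).
#' @param alpha Floor of the cosine schedule, as a fraction of the cycle's
#'   base learning rate (0).
#' @param restart_lr_mult Base learning-rate multiplier applied at each
#'   restart (2).
#' @param max_restarts Restarts after which the base rate is frozen
#'   (unbounded doubling would diverge).
#' @param batch_size Minibatch size (128); a training set smaller than
#'   this is taken as a single full batch.
#' @param max_epochs Maximum epochs (100), with best-validation
#'   checkpointing.
#' @param patience Early-stopping patience in epochs without a validation
#'   loss improvement; `Inf` disables early stopping.
#' @param grad_clip Global gradient-norm clip; `Inf` disables.
#' @param seed Seed for shuffling and dropout.
#' @param loss `"bce"` or `"softmax_ce"` (must match the model's).
#' @return An object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.002, momentum = 0.9, decay_steps = 50,
                         alpha = 0, restart_lr_mult = 2, max_restarts = 4,
                         batch_size = 128, max_epochs = 100, patience = 10,
                         grad_clip = 5, seed = 1,
                         loss = c("bce", "softmax_ce")) {
  loss <- match.arg(loss)
  if (base_lr <= 0) stop("train_config: base_lr must be > 0")
  if (momentum < 0 || momentum >= 1)
    stop("train_config: momentum must be in [0, 1)")
  if (decay_steps < 1) stop("train_config: decay_steps must be >= 1")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  structure(list(base_lr = base_lr, momentum = momentum,
                 decay_steps = as.integer(decay_steps), alpha = alpha,
                 restart_lr_mult = restart_lr_mult,
                 max_restarts = as.integer(max_restarts),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 grad_clip = grad_clip, seed = as.integer(seed),
                 loss = loss),
            class = "train_config")
}

#' Cosine-annealing-with-restarts learning rate
#'
#' Within cycle `k` (each `decay_steps` optimizer steps long, boundaries
#' belonging to the ending cycle) the rate follows a half cosine from the
#' cycle's base `b_k = base_lr * restart_lr_mult^k` down to `alpha * b_k`.
#' The base is frozen after `max_restarts` restarts. With the defaults:
#' step 0 gives 0.002, step 50 gives 0, and cycle 1 restarts from 0.004.
#'
#' @param step Optimizer step(s), >= 0 (vectorized).
#' @param config A `train_config`.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(step, config = train_config()) {
  if (any(step < 0)) stop("lr_schedule: step must be >= 0")
  T_ <- config$decay_steps
  k <- pmax(0, (step - 1) %/% T_)
  k_eff <- pmin(k, config$max_restarts)
  t_in <- step - k * T_
  b <- config$base_lr * config$restart_lr_mult^k_eff
  floor_ <- config$alpha * b
  floor_ + (b - floor_) * 0.5 * (1 + cos(pi * t_in / T_))
}

#' Binary cross-entropy loss
#'
#' Mean over samples and classes of `-(y log s + (1 - y) log(1 - s))`,
#' with scores clipped to `[eps, 1 - eps]`, `eps = 1e-7`.
#'
#' @param scores Matrix (or vector) of scores in \[0, 1\].
#' @param targets One-hot (or binary) targets of the same shape.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(scores, targets) {
  if (length(scores) != length(targets))
    stop("bce_loss: scores and targets shapes differ")
  s <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  -mean(targets * log(s) + (1 - targets) * log(1 - s))
}

.softmax_ce_loss <- function(probs, targets) {
  p <- pmin(pmax(probs, 1e-12), 1)
  -mean(rowSums(targets * log(p)))
}

#' Tile a dataset's sequences into fixed-length model windows
#'
#' Each sequence is cut into `floor(n / input_length)` non-overlapping
#' windows sharing the trial's label and split assignment.
#'
#' @param dataset A (preprocessed) `grip_dataset`.
#' @param input_length Window length in samples.
#' @return List with `x` (array windows x input_length x 1), `labels`,
#'   `trial` (source sequence index), `split` (or NULL).
#' @export
make_windows <- function(dataset, input_length = 500) {
  stopifnot(inherits(dataset, "grip_dataset"))
  input_length <- as.integer(input_length)
  per <- vapply(dataset$sequences, function(s)
    length(s$samples) %/% input_length, integer(1))
  if (any(per < 1))
    stop("make_windows: some sequences are shorter than input_length = ",
         input_length)
  total <- sum(per)
  x <- array(NA_real_, c(total, input_length, 1L))
  labels <- integer(total)
  trial <- integer(total)
  w <- 0L
  for (i in seq_along(dataset$sequences)) {
    s <- dataset$sequences[[i]]$samples
    for (j in seq_len(per[i])) {
      w <- w + 1L
      x[w, , 1] <- s[((j - 1) * input_length + 1):(j * input_length)]
      labels[w] <- dataset$labels[i]
      trial[w] <- i
    }
  }
  split <- if (is.null(dataset$split)) NULL else dataset$split[trial]
  list(x = x, labels = labels, trial = trial, split = split)
}

.one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# Nesterov-momentum SGD step over all layer parameter environments,
# with optional global gradient-norm clipping
.sgd_step <- function(envs, velocities, lr, momentum, grad_clip) {
  if (is.finite(grad_clip)) {
    sq <- 0
    for (l in envs) for (g in l$grads) sq <- sq + sum(g^2)
    gnorm <- sqrt(sq)
    scale <- if (gnorm > grad_clip) grad_clip / gnorm else 1
  } else scale <- 1
  for (k in seq_along(envs)) {
    l <- envs[[k]]
    for (nm in names(l$grads)) {
      g <- l$grads[[nm]] * scale
      v <- momentum * velocities[[k]][[nm]] + g
      velocities[[k]][[nm]] <- v
      l$params[[nm]] <- l$params[[nm]] - lr * (g + momentum * v)
    }
  }
  velocities
}

#' Train the CNN-LSTM on a preprocessed, split dataset
#'
#' Seeded end to end (shuffling, dropout): two runs with the same model
#' seed and config produce identical loss traces. The scheduler is stepped
#' per optimizer step. The epoch with the lowest validation loss is kept
#' ("best checkpoint") and its weights are restored into the model at the
#' end; training stops early after `config$patience` epochs without
#' improvement.
#'
#' @param model A `cnn_lstm_model` from [build_model()].
#' @param dataset A preprocessed `grip_dataset` with train and val splits
#'   (see [preprocess_dataset()], [split_dataset()]).
#' @param config A `train_config`.
#' @param quiet Suppress per-epoch progress on stderr.
#' @return List with `model` (trained, best weights restored), `history`
#'   (data frame: epoch, train_loss, val_loss, lr), `best_epoch`,
#'   `n_steps`.
#' @export
train <- function(model, dataset, config = train_config(), quiet = TRUE) {
  stopifnot(inherits(model, "cnn_lstm_model"),
            inherits(dataset, "grip_dataset"),
            inherits(config, "train_config"))
  if (is.null(dataset$split))
    stop("train: dataset has no split; run split_dataset() first")
  if (config$loss != model$config$loss)
    stop("train: loss mismatch between train_config and model_config")
  wins <- make_windows(dataset, model$config$input_length)
  tr <- which(wins$split == "train")
  va <- which(wins$split == "val")
  if (!length(tr) || !length(va))
    stop("train: empty train or val split")
  n_classes <- model$config$n_classes
  Xtr <- wins$x[tr, , , drop = FALSE]
  Ytr <- .one_hot(wins$labels[tr], n_classes)
  Xva <- wins$x[va, , , drop = FALSE]
  Yva <- .one_hot(wins$labels[va], n_classes)
  n_tr <- length(tr)
  bs <- if (n_tr < config$batch_size) n_tr else config$batch_size
  envs <- .model_layer_envs(model)
  velocities <- lapply(envs, function(l)
    lapply(l$params, function(p) array(0, dim(p) %||% length(p))))
  loss_fn <- if (config$loss == "bce") bce_loss else .softmax_ce_loss
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best_val <- Inf
  best_state <- NULL
  best_epoch <- 0L
  step <- 0L
  stale <- 0L
  with_seed(derive_seed(config$seed, 0, salt = 7), {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(n_tr)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1, n_tr, by = bs)) {
        idx <- perm[start:min(start + bs - 1, n_tr)]
        xb <- Xtr[idx, , , drop = FALSE]
        yb <- Ytr[idx, , drop = FALSE]
        lr <- lr_schedule(step, config)
        scores <- model_forward(model, xb, train = TRUE)
        loss <- loss_fn(scores, yb)
        if (!is.finite(loss))
          stop("train: non-finite loss at epoch ", epoch, ", step ", step,
               " (lr = ", signif(lr, 3), "); training aborted")
        dlogits <- (scores - yb) / length(yb) # grad wrt logits, both losses
        if (config$loss == "softmax_ce")
          dlogits <- (scores - yb) / nrow(yb)
        .model_backward(model, dlogits)
        velocities <- .sgd_step(envs, velocities, lr, config$momentum,
                                config$grad_clip)
        step <- step + 1L
        epoch_loss <- epoch_loss + loss
        n_batches <- n_batches + 1L
      }
      val_scores <- predict_scores(model, Xva)
      val_loss <- loss_fn(val_scores, Yva)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss / n_batches,
        val_loss = val_loss, lr = lr_schedule(step, config)))
      if (!quiet)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        epoch_loss / n_batches, val_loss))
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_state <- .model_state(model)
        best_epoch <- epoch
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })
  if (!is.null(best_state)) .model_restore(model, best_state)
  list(model = model, history = history, best_epoch = best_epoch,
       n_steps = step)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
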