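## Dual-path CNN-LSTM classifier for 1-D force sequences.
##
## CNN path: [conv + batch-norm] -> [bottleneck + max-pool] ->
## [bottleneck + dropout] -> [bottleneck + dropout] -> global average
## pooling over time. Each bottleneck is a residual unit whose trunk and
## branch both run 1x1 (channel reduce) -> 3x3 -> 1x1 (channel expand)
## convolutions; the two are summed and passed through ReLU.
## LSTM path: LSTM(64) -> dropout -> batch-norm -> LSTM(20) -> dropout,
## keeping the final hidden state. The two path outputs are concatenated
## into a fully connected layer of width n_classes; per-class sigmoid
## scores (binary cross-entropy compatible) are the default output, with
## softmax available via the loss configuration.

#' CNN-LSTM model configuration
#'
#' @param input_length Window length in samples fed to the network (5 s at
#'   100 Hz by default); >= 32.
#' @param n_classes Number of classes; >= 2.
#' @param cnn_stem_channels Channels of the stem convolution.
#' @param stem_kernel Kernel width of the stem convolution.
#' @param bottleneck_channels Integer triple (reduce, inner, expand); the
#'   expand width must match `cnn_stem_channels`.
#' @param pool_size Max-pool width after the first bottleneck.
#' @param dropout_cnn,dropout_lstm Dropout probabilities in \[0, 1).
#' @param lstm_hidden_1 Hidden width of the first LSTM layer (64).
#' @param lstm_out Output width of the second LSTM layer (20).
#' @param third_lstm Insert an optional intermediate LSTM layer of width
#'   `lstm_hidden_1` (off by default; the two-layer path is the reference
#'   configuration).
#' @param loss `"bce"` for per-class sigmoid outputs with binary
#'   cross-entropy, `"softmax_ce"` for a softmax alternative.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 500, n_classes = 2,
                         cnn_stem_channels = 32, stem_kernel = 7,
                         bottleneck_channels = c(16, 16, 32),
                         pool_size = 2, dropout_cnn = 0.2,
                         lstm_hidden_1 = 64, lstm_out = 20,
                         dropout_lstm = 0.3, third_lstm = FALSE,
                         loss = c("bce", "softmax_ce")) {
  loss <- match.arg(loss)
  if (input_length < 32)
    stop("model_config: input_length must be >= 32 (got ", input_length,
         "); the pooling stack needs room")
  if (n_classes < 2) stop("model_config: n_classes must be >= 2")
  if (length(bottleneck_channels) != 3)
    stop("model_config: bottleneck_channels must be (reduce, inner, expand)")
  if (bottleneck_channels[3] != cnn_stem_channels)
    stop("model_config: bottleneck expand width (", bottleneck_channels[3],
         ") must equal cnn_stem_channels (", cnn_stem_channels, ")")
  if (dropout_cnn < 0 || dropout_cnn >= 1 || dropout_lstm < 0 ||
      dropout_lstm >= 1)
    stop("model_config: dropout probabilities must be in [0, 1)")
  structure(list(input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 cnn_stem_channels = as.integer(cnn_stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 pool_size = as.integer(pool_size),
                 dropout_cnn = dropout_cnn,
                 lstm_hidden_1 = as.integer(lstm_hidden_1),
                 lstm_out = as.integer(lstm_out),
                 dropout_lstm = dropout_lstm,
                 third_lstm = isTRUE(third_lstm), loss = loss),
            class = "model_config")
}

.new_bottleneck <- function(channels, bn_ch) {
  r <- bn_ch[1]; inner <- bn_ch[2]; expand <- bn_ch[3]
  list(trunk = list(nn_conv1d(channels, r, 1), nn_relu(),
                    nn_conv1d(r, inner, 3), nn_relu(),
                    nn_conv1d(inner, expand, 1)),
       branch = list(nn_conv1d(channels, r, 1), nn_relu(),
                     nn_conv1d(r, inner, 3), nn_relu(),
                     nn_conv1d(inner, expand, 1)),
       out_relu = nn_relu())
}

.seq_forward <- function(layers, x, train) {
  for (l in layers) x <- nn_forward(l, x, train)
  x
}
.seq_backward <- function(layers, dout) {
  for (l in rev(layers)) dout <- nn_backward(l, dout)
  dout
}

#' Forward pass through one bottleneck residual block
#'
#' Trunk and branch each apply 1x1 -> ReLU -> 3x3 -> ReLU -> 1x1
#' convolutions (stride 1, symmetric padding, so the temporal length is
#' preserved); their outputs are summed and passed through a final ReLU.
#'
#' @param x Input array of dim (batch, time, channels).
#' @param block A bottleneck block from a built model (see
#'   [build_model()]), or from `pulsegrip:::.new_bottleneck()`.
#' @param train Logical; caches gradients when TRUE.
#' @return Output array with the same batch and time dimensions.
#' @export
bottleneck_forward <- function(x, block, train = FALSE) {
  trunk <- .seq_forward(block$trunk, x, train)
  branch <- .seq_forward(block$branch, x, train)
  nn_forward(block$out_relu, trunk + branch, train)
}

.bottleneck_backward <- function(block, dout) {
  ds <- nn_backward(block$out_relu, dout)
  .seq_backward(block$trunk, ds) + .seq_backward(block$branch, ds)
}

#' Build the dual-path CNN-LSTM model
#'
#' Parameter initialization is drawn under the given seed, so an identical
#' (config, seed) pair yields identical weights; the parameter count is a
#' pure function of the config alone.
#'
#' @param config A `model_config`.
#' @param seed Seed for weight initialization.
#' @return An object of class `cnn_lstm_model` (a mutable environment).
#' @export
build_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  if (config$input_length %/% config$pool_size < 1)
    stop("build_model: input_length ", config$input_length,
         " too short for pool size ", config$pool_size,
         "; need at least ", config$pool_size * 1L)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$seed <- seed
  with_seed(seed, {
    ch <- config$cnn_stem_channels
    bc <- config$bottleneck_channels
    m$stem_conv <- nn_conv1d(1, ch, config$stem_kernel)
    m$stem_bn <- nn_bn(ch)
    m$stem_relu <- nn_relu()
    m$block1 <- .new_bottleneck(ch, bc)
    m$pool <- nn_maxpool(config$pool_size)
    m$block2 <- .new_bottleneck(ch, bc)
    m$drop2 <- nn_dropout(config$dropout_cnn)
    m$block3 <- .new_bottleneck(ch, bc)
    m$drop3 <- nn_dropout(config$dropout_cnn)
    m$gap <- nn_gap()
    m$lstm1 <- nn_lstm(1, config$lstm_hidden_1, return_sequences = TRUE)
    m$ldrop1 <- nn_dropout(config$dropout_lstm)
    m$lstm_bn <- nn_bn(config$lstm_hidden_1)
    if (config$third_lstm) {
      m$lstm_mid <- nn_lstm(config$lstm_hidden_1, config$lstm_hidden_1,
                            return_sequences = TRUE)
      m$ldrop_mid <- nn_dropout(config$dropout_lstm)
    }
    m$lstm2 <- nn_lstm(config$lstm_hidden_1, config$lstm_out,
                       return_sequences = FALSE)
    m$ldrop2 <- nn_dropout(config$dropout_lstm)
    m$head <- nn_dense(ch + config$lstm_out, config$n_classes)
  })
  class(m) <- "cnn_lstm_model"
  m
}

.model_layer_envs <- function(m) {
  blocks <- function(b) c(b$trunk, b$branch, list(b$out_relu))
  ls <- c(list(m$stem_conv, m$stem_bn, m$stem_relu), blocks(m$block1),
          list(m$pool), blocks(m$block2), list(m$drop2), blocks(m$block3),
          list(m$drop3, m$gap, m$lstm1, m$ldrop1, m$lstm_bn))
  if (m$config$third_lstm) ls <- c(ls, list(m$lstm_mid, m$ldrop_mid))
  c(ls, list(m$lstm2, m$ldrop2, m$head))
}

#' Number of trainable parameters
#' @param model A `cnn_lstm_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(.model_layer_envs(model), .layer_n_params, integer(1)))
}

#' Layer-by-layer summary of a built model
#'
#' @param model A `cnn_lstm_model`.
#' @return List with a `layers` data frame (name, type, parameter count),
#'   `path_widths` (CNN-path and LSTM-path output widths feeding the
#'   fully connected layer) and `total_params`.
#' @export
network_spec <- function(model) {
  envs <- .model_layer_envs(model)
  df <- data.frame(
    type = vapply(envs, function(l) l$type, character(1)),
    n_params = vapply(envs, .layer_n_params, integer(1)))
  list(layers = df,
       path_widths = c(cnn = model$config$cnn_stem_channels,
                       lstm = model$config$lstm_out),
       fc_input_width = model$config$cnn_stem_channels +
         model$config$lstm_out,
       n_classes = model$config$n_classes,
       total_params = sum(df$n_params))
}

#' Forward pass: class scores for a batch of windows
#'
#' @param model A `cnn_lstm_model`.
#' @param x Array of dim (batch, input_length, 1), a matrix
#'   (batch, input_length), or a single numeric window.
#' @param train Logical; TRUE enables dropout/batch-statistics and caches
#'   for backprop. Evaluation mode (`FALSE`) is deterministic.
#' @return Matrix (batch, n_classes) of per-class scores in \[0, 1\]
#'   (sigmoid, or softmax under the `softmax_ce` loss). The pre-activation
#'   logits are kept on the model for the training step.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (dim(x)[2] != model$config$input_length)
    stop("model_forward: window length ", dim(x)[2],
         " does not match input_length ", model$config$input_length)
  h <- nn_forward(model$stem_conv, x, train)
  h <- nn_forward(model$stem_bn, h, train)
  h <- nn_forward(model$stem_relu, h, train)
  h <- bottleneck_forward(h, model$block1, train)
  h <- nn_forward(model$pool, h, train)
  h <- bottleneck_forward(h, model$block2, train)
  h <- nn_forward(model$drop2, h, train)
  h <- bottleneck_forward(h, model$block3, train)
  h <- nn_forward(model$drop3, h, train)
  cnn_out <- nn_forward(model$gap, h, train)
  g <- nn_forward(model$lstm1, x, train)
  g <- nn_forward(model$ldrop1, g, train)
  g <- nn_forward(model$lstm_bn, g, train)
  if (model$config$third_lstm) {
    g <- nn_forward(model$lstm_mid, g, train)
    g <- nn_forward(model$ldrop_mid, g, train)
  }
  g <- nn_forward(model$lstm2, g, train)
  lstm_out <- nn_forward(model$ldrop2, g, train)
  feats <- cbind(cnn_out, lstm_out)
  logits <- nn_forward(model$head, feats, train)
  model$logits <- logits
  if (model$config$loss == "bce") .sigmoid(logits)
  else {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  }
}

# backward pass from d(loss)/d(logits); mirrors model_forward
.model_backward <- function(model, dlogits) {
  dfeats <- nn_backward(model$head, dlogits)
  ch <- model$config$cnn_stem_channels
  dcnn <- dfeats[, seq_len(ch), drop = FALSE]
  dlstm <- dfeats[, ch + seq_len(model$config$lstm_out), drop = FALSE]
  dg <- nn_backward(model$ldrop2, dlstm)
  dg <- nn_backward(model$lstm2, dg)
  if (model$config$third_lstm) {
    dg <- nn_backward(model$ldrop_mid, dg)
    dg <- nn_backward(model$lstm_mid, dg)
  }
  dg <- nn_backward(model$lstm_bn, dg)
  dg <- nn_backward(model$ldrop1, dg)
  dx_lstm <- nn_backward(model$lstm1, dg)
  dh <- nn_backward(model$gap, dcnn)
  dh <- nn_backward(model$drop3, dh)
  dh <- .bottleneck_backward(model$block3, dh)
  dh <- nn_backward(model$drop2, dh)
  dh <- .bottleneck_backward(model$block2, dh)
  dh <- nn_backward(model$pool, dh)
  dh <- .bottleneck_backward(model$block1, dh)
  dh <- nn_backward(model$stem_relu, dh)
  dh <- nn_backward(model$stem_bn, dh)
  dx_cnn <- nn_backward(model$stem_conv, dh)
  dx_cnn + dx_lstm
}

#' Predict class scores in evaluation mode, chunked over the batch
#'
#' @param model A `cnn_lstm_model`.
#' @param x Array (batch, input_length, 1) or matrix.
#' @param chunk Maximum rows per forward pass.
#' @return Matrix (batch, n_classes) of scores.
#' @export
predict_scores <- function(model, x, chunk = 256) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[1]
  out <- matrix(NA_real_, N, model$config$n_classes)
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    out[idx, ] <- model_forward(model, x[idx, , , drop = FALSE],
                                train = FALSE)
  }
  out
}

#' @export
print.cnn_lstm_model <- function(x, ...) {
  cat(sprintf(paste0("<cnn_lstm_model> input %d, %d classes, %d parameters ",
                     "(CNN path %d + LSTM path %d -> FC)\n"),
              x$config$input_length, x$config$n_classes, n_params(x),
              x$config$cnn_stem_channels, x$config$lstm_out))
  invisible(x)
}

# deep-copy / restore of all parameters and batch-norm running stats
.model_state <- function(model) {
  envs <- .model_layer_envs(model)
  lapply(envs, function(l) {
    st <- list(params = l$params)
    if (l$type == "bn") {
      st$run_mean <- l$run_mean
      st$run_var <- l$run_var
    }
    st
  })
}
.model_restore <- function(model, state) {
  envs <- .model_layer_envs(model)
  for (k in seq_along(envs)) {
    envs[[k]]$params <- state[[k]]$params
    if (envs[[k]]$type == "bn") {
      envs[[k]]$run_mean <- state[[k]]$run_mean
      envs[[k]]$run_var <- state[[k]]$run_var
    }
  }
  invisible(model)
}
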