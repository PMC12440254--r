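# Shared fixtures: small signals and model configs kept deliberately tiny
# so the unit suite stays fast.

noiseless_preset <- function(model_id = "porcine_I",
                             condition_label = "artery") {
  make_preset(model_id, condition_label, amplitude_cv = 0, noise_sd = 0)
}

# a clean pulse-train force signal at the study's pump setting
clean_trial <- function(seed = 1, fs = 100, ...) {
  simulate_grip_trial(noiseless_preset(...), fs = fs, seed = seed)
}

# tiny CNN-LSTM config for structural / gradient tests
tiny_model_config <- function(n_classes = 2, input_length = 32,
                              lstm_out = 4, ...) {
  model_config(input_length = input_length, n_classes = n_classes,
               cnn_stem_channels = 6, stem_kernel = 5,
               bottleneck_channels = c(3, 3, 6), dropout_cnn = 0,
               dropout_lstm = 0, lstm_hidden_1 = 5, lstm_out = lstm_out, ...)
}

# count strict local maxima of a sampled signal (independent oracle for
# peak counts)
count_local_maxima <- function(x) {
  n <- length(x)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n])
}
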