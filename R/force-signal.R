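#' Construct a uniformly sampled force signal
#'
#' A `force_signal` holds a gripping-force time series in newtons together
#' with its sampling rate. It is the common currency passed between the
#' simulator, the FBG sensor model, the preprocessing chain and the PCFF
#' extractor.
#'
#' @param samples Numeric vector of forces (N); all finite, length >= 2.
#' @param fs Sampling rate in Hz; > 0.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `force_signal` with fields `samples`, `fs`,
#'   `t0`.
#' @export
force_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("force_signal: need at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("force_signal: all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("force_signal: fs must be a single positive number")
  structure(list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "force_signal")
}

#' @export
print.force_signal <- function(x, ...) {
  cat(sprintf("<force_signal> %d samples @ %g Hz (%.2f s), range [%.4g, %.4g] N\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.force_signal <- function(x) length(x$samples)

#' Sample times of a force signal
#' @param signal A `force_signal`.
#' @return Numeric vector of times in seconds.
#' @export
signal_times <- function(signal) {
  signal$t0 + (seq_along(signal$samples) - 1) / signal$fs
}

#' @export
as.data.frame.force_signal <- function(x, ...) {
  data.frame(time_s = signal_times(x), force_n = x$samples)
}

#' Write a force signal as two-column CSV
#'
#' Column header is `time_s,force_n`.
#'
#' @param signal A `force_signal`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(signal, path) {
  utils::write.csv(as.data.frame(signal), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a force signal from two-column CSV
#'
#' @param path CSV file with columns `time_s` and `force_n` written by
#'   [write_force_csv()] (or equivalent). The sampling rate is recovered
#'   from the median time step.
#' @return A `force_signal`.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force_n") %in% names(df)))
    stop("read_force_csv: expected columns 'time_s' and 'force_n' in ", path)
  dt <- stats::median(diff(df$time_s))
  if (!is.finite(dt) || dt <= 0)
    stop("read_force_csv: non-increasing time column in ", path)
  force_signal(df$force_n, fs = 1 / dt, t0 = df$time_s[1])
}
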