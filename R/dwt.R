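## Multilevel discrete wavelet transform with periodized boundary handling,
## plus soft-threshold denoising.
##
## Daubechies db4 (8-tap) orthonormal decomposition low-pass filter; the
## high-pass partner is its quadrature mirror g[k] = (-1)^k h[L-1-k].
## Orthonormality gives perfect reconstruction and energy preservation,
## both of which are enforced by the test suite.

.db4_lo <- c(-0.010597401785069032, 0.0328830116668852,
             0.030841381835560764, -0.18703481171909309,
             -0.027983769416859854, 0.6308807679298589,
             0.7148465705529157, 0.2303778133088965)

.wavelet_filters <- function(wavelet_family = "db4") {
  if (!identical(wavelet_family, "db4"))
    stop("wavelet filters: only 'db4' is available, got '",
         wavelet_family, "'")
  lo <- .db4_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(lo = lo, hi = hi, length = L)
}

# one analysis step with circular (periodized) extension; n must be even
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  half <- n / 2
  base <- 2 * (seq_len(half) - 1) # 0-based start of each window
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_len(L)) {
    xi <- x[(base + (k - 1)) %% n + 1]
    a <- a + lo[k] * xi
    d <- d + hi[k] * xi
  }
  list(a = a, d = d)
}

# one synthesis step (transpose of the analysis operator)
.idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2 * half
  L <- length(lo)
  x <- numeric(n)
  base <- 2 * (seq_len(half) - 1)
  for (k in seq_len(L)) {
    idx <- (base + (k - 1)) %% n + 1
    contrib <- lo[k] * a + hi[k] * d
    # scatter-add; idx values are distinct within one tap when L <= n
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Maximum useful decomposition level
#'
#' Deepest level at which the (db4, 8-tap) filter still fits the signal,
#' `floor(log2(n / (filter_length - 1)))`.
#'
#' @param n Signal length.
#' @param wavelet_family Wavelet name (only `"db4"`).
#' @return Integer level (0 if the signal is too short for even one level).
#' @export
dwt_max_level <- function(n, wavelet_family = "db4") {
  L <- .wavelet_filters(wavelet_family)$length
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

#' Multilevel periodized wavelet decomposition
#'
#' Odd-length signals at any level are extended by repeating the final
#' sample before the periodized filtering, and the pre-extension length is
#' recorded so [waverec()] restores the exact original length.
#'
#' @param x Numeric vector.
#' @param level Number of decomposition levels; >= 1.
#' @param wavelet_family Wavelet name (only `"db4"`).
#' @return List with `approx` (coarsest approximation), `details` (list of
#'   detail bands, finest first), `lengths` (pre-extension length at each
#'   level) and `level`.
#' @export
wavedec <- function(x, level = 4, wavelet_family = "db4") {
  if (level < 1) stop("wavedec: level must be >= 1")
  maxlev <- dwt_max_level(length(x), wavelet_family)
  if (level > maxlev)
    stop("wavedec: signal of length ", length(x), " supports at most ",
         maxlev, " levels (requested ", level, ")")
  f <- .wavelet_filters(wavelet_family)
  details <- vector("list", level)
  lengths <- integer(level)
  cur <- as.numeric(x)
  for (j in seq_len(level)) {
    lengths[j] <- length(cur)
    if (length(cur) %% 2 == 1) cur <- c(cur, cur[length(cur)])
    s <- .dwt_step(cur, f$lo, f$hi)
    details[[j]] <- s$d
    cur <- s$a
  }
  list(approx = cur, details = details, lengths = lengths, level = level,
       wavelet_family = wavelet_family)
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' Inverse of [wavedec()]; with untouched coefficients the round trip
#' reproduces the input to floating-point accuracy.
#'
#' @param dec Decomposition as returned by [wavedec()].
#' @return Numeric vector of the original length.
#' @export
waverec <- function(dec) {
  f <- .wavelet_filters(dec$wavelet_family)
  cur <- dec$approx
  for (j in rev(seq_len(dec$level))) {
    cur <- .idwt_step(cur, dec$details[[j]], f$lo, f$hi)
    cur <- cur[seq_len(dec$lengths[j])] # undo odd-length extension
  }
  cur
}

#' Soft thresholding
#'
#' Shrinks coefficients toward zero by `threshold` and zeroes those below
#' it: `sign(w) * max(|w| - threshold, 0)`.
#'
#' @param w Numeric vector of coefficients.
#' @param threshold Non-negative threshold.
#' @return Thresholded coefficients.
#' @export
soft_threshold <- function(w, threshold) {
  if (threshold < 0) stop("soft_threshold: threshold must be >= 0")
  sign(w) * pmax(abs(w) - threshold, 0)
}

#' Wavelet soft-threshold denoising
#'
#' Multilevel db4 decomposition; every detail band is soft-thresholded with
#' the universal threshold `sigma * sqrt(2 * log(n))`, where `sigma` is the
#' robust noise scale `median(|d1|) / 0.6745` estimated from the finest
#' detail band; the signal is then reconstructed. Output length equals
#' input length.
#'
#' @param signal A `force_signal` (or numeric vector).
#' @param config A `preprocess_config` (see [preprocess_config()]); its
#'   `wavelet_family` and `decomposition_level` fields are used.
#' @return Denoised signal of the same type and length as the input.
#' @export
wavelet_denoise <- function(signal, config = preprocess_config()) {
  x <- if (inherits(signal, "force_signal")) signal$samples else
    as.numeric(signal)
  dec <- wavedec(x, level = config$decomposition_level,
                 wavelet_family = config$wavelet_family)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, soft_threshold, threshold = thr)
  y <- waverec(dec)
  if (inherits(signal, "force_signal"))
    force_signal(y, fs = signal$fs, t0 = signal$t0)
  else y
}
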