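## Peak clamping force fluctuation (PCFF) analysis.
##
## During a steady clamp the pulsatile component of the gripping force
## rises once per pump roller pass; the height of each pulse peak above the
## static clamp level is the PCFF, and the spacing between peaks gives the
## pulse frequency.

#' Detect pulsation peaks
#'
#' Local maxima filtered by topographic prominence (at least
#' `prominence_frac` of the signal's total range) and by a minimum
#' separation of half the expected pulse period. When two candidates fall
#' closer than the minimum separation the higher one wins.
#'
#' @param signal A `force_signal`.
#' @param expected_rate_bpm Expected pulse rate (pulses/min), sets the
#'   minimum peak separation `0.5 * (60 / rate) * fs` samples.
#' @param prominence_frac Minimum prominence as a fraction of
#'   `max(signal) - min(signal)`.
#' @return Integer vector of peak sample indices (possibly empty),
#'   strictly increasing.
#' @export
detect_peaks <- function(signal, expected_rate_bpm = 90,
                         prominence_frac = 0.3) {
  stopifnot(inherits(signal, "force_signal"))
  x <- signal$samples
  n <- length(x)
  # strict local maxima
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  rng <- max(x) - min(x)
  if (rng <= 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    # walk outwards until a higher sample; prominence = height above the
    # higher of the two valley minima. A side whose walk runs off the
    # signal edge without meeting a higher sample is open (the pulse is
    # truncated there) and does not cap the prominence; the global
    # maximum, open on both sides, is measured against the deeper valley.
    lmin <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    l_open <- j < 1L
    rmin <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    r_open <- j > n
    base <- if (l_open && r_open) min(lmin, rmin)
    else if (l_open) rmin
    else if (r_open) lmin
    else max(lmin, rmin)
    x[i] - base
  }, numeric(1))
  cand <- cand[prom >= prominence_frac * rng]
  if (!length(cand)) return(integer(0))
  # enforce minimum separation, keeping higher peaks first
  min_sep <- 0.5 * (60 / expected_rate_bpm) * signal$fs
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

#' Summarize pulsation peaks into PCFF statistics
#'
#' The static clamp component is estimated as the median of the whole
#' signal (robust to the asymmetric pulse shape); each peak's PCFF is its
#' force above that baseline. The pulse rate comes from the median
#' inter-peak interval (robust to a single missed peak) and is `NA` when
#' fewer than two peaks are available.
#'
#' @param signal A `force_signal`.
#' @param peaks Integer peak indices from [detect_peaks()]; >= 1 peak.
#' @return An object of class `pulse_summary` with fields `peak_indices`,
#'   `peak_forces`, `baseline`, `pcff_values`, `mean_pcff`,
#'   `pulse_rate_bpm`.
#' @export
compute_pcff <- function(signal, peaks) {
  stopifnot(inherits(signal, "force_signal"))
  peaks <- as.integer(peaks)
  if (!length(peaks))
    stop("compute_pcff: no peaks detected; cannot compute PCFF")
  if (is.unsorted(peaks, strictly = TRUE))
    stop("compute_pcff: peak indices must be strictly increasing")
  baseline <- stats::median(signal$samples)
  peak_forces <- signal$samples[peaks]
  pcff <- peak_forces - baseline
  rate <- if (length(peaks) >= 2) pulse_frequency(peaks, signal$fs)
  else NA_real_
  structure(list(peak_indices = peaks, peak_forces = peak_forces,
                 baseline = baseline, pcff_values = pcff,
                 mean_pcff = mean(pcff), pulse_rate_bpm = rate),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat(sprintf(
    "<pulse_summary> %d peaks, baseline %.4f N, mean PCFF %.4f N, rate %s\n",
    length(x$peak_indices), x$baseline, x$mean_pcff,
    if (is.na(x$pulse_rate_bpm)) "NA"
    else sprintf("%.1f/min", x$pulse_rate_bpm)))
  invisible(x)
}

#' Pulse frequency from inter-peak spacing
#'
#' @param peaks Integer peak indices; >= 2.
#' @param fs Sampling rate (Hz).
#' @return Pulses per minute, `60 * fs / median(diff(peaks))`.
#' @export
pulse_frequency <- function(peaks, fs) {
  if (length(peaks) < 2)
    stop("pulse_frequency: need at least 2 peaks, got ", length(peaks))
  60 * fs / stats::median(diff(as.numeric(peaks)))
}

#' Extract a PCFF summary from a raw force signal
#'
#' Convenience chain used throughout the pipeline: optional wavelet
#' denoising and moving-average smoothing (amplitude-preserving stages
#' only; no Z-scoring, since PCFF is reported in newtons), then peak
#' detection and PCFF summarization.
#'
#' @param signal A raw `force_signal`.
#' @param config A `preprocess_config` (denoise level / smoothing width).
#' @param expected_rate_bpm,prominence_frac Passed to [detect_peaks()].
#' @param denoise,smooth Logical switches for the two cleaning stages.
#' @return A `pulse_summary`.
#' @export
extract_pcff <- function(signal, config = preprocess_config(),
                         expected_rate_bpm = 90, prominence_frac = 0.3,
                         denoise = TRUE, smooth = TRUE) {
  s <- signal
  if (denoise) s <- wavelet_denoise(s, config)
  if (smooth) s <- moving_average(s, window = config$smoothing_window)
  peaks <- detect_peaks(s, expected_rate_bpm = expected_rate_bpm,
                        prominence_frac = prominence_frac)
  compute_pcff(s, peaks)
}

#' Per-trial PCFF table for a dataset
#'
#' @param dataset A `grip_dataset` of raw force sequences.
#' @param ... Passed to [extract_pcff()].
#' @return Data frame with one row per trial: `trial`, `label`,
#'   `condition`, `mean_pcff`, `pulse_rate_bpm`, `n_peaks`.
#' @export
dataset_pcff <- function(dataset, ...) {
  stopifnot(inherits(dataset, "grip_dataset"))
  rows <- lapply(seq_along(dataset$sequences), function(i) {
    ps <- extract_pcff(dataset$sequences[[i]], ...)
    data.frame(trial = i, label = dataset$labels[i],
               condition = dataset$class_names[dataset$labels[i] + 1L],
               mean_pcff = ps$mean_pcff,
               pulse_rate_bpm = ps$pulse_rate_bpm,
               n_peaks = length(ps$peak_indices))
  })
  do.call(rbind, rows)
}

#' Adaptive two-or-more-group comparison
#'
#' For two groups: independent-sample t-test (pooled variance) when both
#' groups pass Shapiro-Wilk normality at `normality_alpha` and an F-test
#' finds equal variances; otherwise the Mann-Whitney U test. For three or
#' more groups: the Kruskal-Wallis test.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 3.
#' @param normality_alpha Screening level for Shapiro-Wilk (and the
#'   variance F-test).
#' @return An object of class `group_comparison` with fields `test_name`
#'   (one of `"t"`, `"mann_whitney"`, `"kruskal_wallis"`), `statistic`,
#'   `p_value`, `significant` (at alpha = 0.05).
#' @export
compare_groups <- function(groups, normality_alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("compare_groups: need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 3))
    stop("compare_groups: every group needs n >= 3 (got ",
         paste(sizes, collapse = ", "), ")")
  if (length(groups) >= 3) {
    ht <- stats::kruskal.test(groups)
    res <- list(test_name = "kruskal_wallis",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    g1 <- groups[[1]]
    g2 <- groups[[2]]
    normal <- tryCatch(
      stats::shapiro.test(g1)$p.value > normality_alpha &&
        stats::shapiro.test(g2)$p.value > normality_alpha,
      error = function(e) FALSE) # e.g. zero-variance group
    eqvar <- normal && stats::var.test(g1, g2)$p.value > normality_alpha
    if (normal && eqvar) {
      ht <- stats::t.test(g1, g2, var.equal = TRUE)
      res <- list(test_name = "t", statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    } else {
      ht <- stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
      res <- list(test_name = "mann_whitney",
                  statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  }
  res$significant <- res$p_value < 0.05
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.3g%s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

.sig_marker <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Group-comparison report for a dataset's PCFF values
#'
#' Mirrors the structure of the study's per-model tables: one row per
#' condition with its n and mean PCFF, plus all pairwise comparisons with
#' significance markers (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param pcff_table Output of [dataset_pcff()].
#' @param ... Passed to [compare_groups()].
#' @return List with data frames `conditions` and `pairwise`.
#' @export
pcff_report <- function(pcff_table, ...) {
  conds <- unique(pcff_table$condition)
  groups <- lapply(conds, function(cc)
    pcff_table$mean_pcff[pcff_table$condition == cc])
  names(groups) <- conds
  cond_df <- data.frame(condition = conds, n = lengths(groups),
                        mean_pcff = vapply(groups, mean, numeric(1)))
  pairs <- utils::combn(seq_along(conds), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    cmp <- compare_groups(groups[c(i, j)], ...)
    data.frame(group_1 = conds[i], group_2 = conds[j],
               test = cmp$test_name, statistic = cmp$statistic,
               p_value = cmp$p_value, marker = .sig_marker(cmp$p_value))
  })
  list(conditions = cond_df, pairwise = do.call(rbind, pw))
}

#' Write a PCFF report to CSV
#'
#' @param report Output of [pcff_report()].
#' @param path Output CSV path (conditions block, blank line, pairwise
#'   block).
#' @return `path`, invisibly.
#' @export
write_pcff_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(report$conditions, con, row.names = FALSE, quote = FALSE)
  writeLines("", con)
  utils::write.csv(report$pairwise, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
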