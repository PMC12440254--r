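# Peak detection, PCFF statistics, pulse frequency and group comparisons.

test_that("flat signals yield no peaks and single pulses exactly one", {
  flat <- force_signal(rep(0.5, 300), fs = 100)
  expect_length(detect_peaks(flat), 0)
  # one isolated pulse
  t <- (0:299) / 100
  one <- force_signal(0.5 + 0.1 * exp(-(t - 1.5)^2 / 0.01), fs = 100)
  pk <- detect_peaks(one, expected_rate_bpm = 90)
  expect_length(pk, 1)
  expect_equal(pk, which.max(one$samples))
})

test_that("a noiseless 90/min trial yields the oracle's 22-23 peaks", {
  for (seed in 1:10) {
    s <- clean_trial(seed)
    expected <- count_local_maxima(s$samples)
    pk <- detect_peaks(s)
    expect_equal(length(pk), expected)
    expect_true(expected %in% c(22, 23))
  }
})

test_that("PCFF recovers the preset amplitude on noiseless trials", {
  for (cond in c("artery", "vein")) {
    spec <- noiseless_preset("porcine_I", cond)
    s <- simulate_grip_trial(spec, fs = 100, seed = 8)
    ps <- compute_pcff(s, detect_peaks(s))
    expect_equal(ps$mean_pcff, spec$pulse_amplitude, tolerance = 0.02)
  }
})

test_that("pulse summary fields satisfy their invariants", {
  s <- clean_trial(3)
  ps <- compute_pcff(s, detect_peaks(s))
  expect_equal(ps$pcff_values, ps$peak_forces - ps$baseline)
  expect_equal(ps$mean_pcff, mean(ps$pcff_values))
  expect_false(is.unsorted(ps$peak_indices, strictly = TRUE))
  expect_gt(ps$pulse_rate_bpm, 0)
  expect_error(compute_pcff(s, integer(0)), "no peaks")
  expect_error(compute_pcff(s, c(10L, 5L)), "strictly increasing")
})

test_that("mean PCFF is invariant to constant offsets and scales with gain", {
  s <- clean_trial(5)
  ps <- compute_pcff(s, detect_peaks(s))
  shifted <- force_signal(s$samples + 2.7, fs = s$fs)
  ps_shift <- compute_pcff(shifted, detect_peaks(shifted))
  expect_equal(ps_shift$mean_pcff, ps$mean_pcff, tolerance = 1e-10)
  # scale the fluctuating component by 3
  base <- median(s$samples)
  scaled <- force_signal(base + 3 * (s$samples - base), fs = s$fs)
  ps_scaled <- compute_pcff(scaled, detect_peaks(scaled))
  expect_equal(ps_scaled$mean_pcff, 3 * ps$mean_pcff, tolerance = 1e-6)
})

test_that("pulse frequency comes from the median inter-peak spacing", {
  expect_equal(pulse_frequency(c(1, 101, 201, 301), fs = 100), 60)
  expect_error(pulse_frequency(5L, fs = 100), "at least 2")
  # peaks 1 s apart at any rate give 60/min
  s <- clean_trial(7)
  f <- pulse_frequency(detect_peaks(s), s$fs)
  expect_equal(f, 90, tolerance = 0.03)
})

test_that("extract_pcff recovers preset amplitudes through the full chain", {
  spec <- make_preset("porcine_I", "artery", amplitude_cv = 0)
  vals <- vapply(1:10, function(sd)
    extract_pcff(simulate_grip_trial(spec, 100, sd))$mean_pcff, numeric(1))
  expect_equal(mean(vals), 0.047, tolerance = 0.05)
})

test_that("compare_groups routes to the prescribed test family", {
  set.seed(10)
  g1 <- rnorm(30)
  # identical groups are never significant
  same <- compare_groups(list(g1, g1))
  expect_false(same$significant)
  # three groups use Kruskal-Wallis
  k3 <- compare_groups(list(rnorm(20), rnorm(20), rnorm(20)))
  expect_equal(k3$test_name, "kruskal_wallis")
  # grossly non-normal two-group data falls back to Mann-Whitney
  mw <- compare_groups(list(rexp(40)^3, rexp(40)^3 + 2))
  expect_equal(mw$test_name, "mann_whitney")
  # normal equal-variance two-group data uses the t-test
  tt <- compare_groups(list(rnorm(40), rnorm(40, 1)))
  expect_equal(tt$test_name, "t")
  expect_true(tt$p_value >= 0 && tt$p_value <= 1)
  expect_error(compare_groups(list(rnorm(2), rnorm(10))), "n >= 3")
  expect_error(compare_groups(list(rnorm(10))), "at least 2")
})

test_that("preset artery/vein groups separate at p < 0.001 at n = 80", {
  d <- generate_dataset("porcine_I", 80, 100, 77)
  tab <- dataset_pcff(d, denoise = FALSE)
  cmp <- compare_groups(split(tab$mean_pcff, tab$label))
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$significant)
})

test_that("the report carries condition means and marked pairwise tests", {
  d <- generate_dataset("phantom_III", 10, 100, 15)
  tab <- dataset_pcff(d, denoise = FALSE)
  rep <- pcff_report(tab)
  expect_equal(nrow(rep$conditions), 3)
  expect_equal(nrow(rep$pairwise), 3)
  expect_true(all(rep$pairwise$p_value >= 0 & rep$pairwise$p_value <= 1))
  expect_true(all(rep$pairwise$marker %in% c("", "*", "**", "***")))
  path <- tempfile(fileext = ".csv")
  write_pcff_report(rep, path)
  expect_true(file.exists(path))
  unlink(path)
})
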