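# Synthetic pulsatile-trial generator: presets, determinism, waveform
# contracts.

test_that("presets carry the group-mean PCFF of each condition", {
  expect_equal(make_preset("porcine_I", "artery")$pulse_amplitude, 0.047)
  expect_equal(make_preset("porcine_I", "vein")$pulse_amplitude, 0.022)
  expect_equal(make_preset("phantom_II", "0.5mm")$pulse_amplitude, 0.223)
  expect_equal(make_preset("phantom_I", "20A")$pulse_amplitude, 0.162)
  expect_equal(make_preset("porcine_III", "muscle")$pulse_amplitude, 0.032)
  p <- make_preset("porcine_II", "2.0mm")
  expect_equal(p$pulse_rate, 90)
  expect_equal(p$hold_duration, 15)
  expect_equal(p$amplitude_cv, 0.15)
  expect_equal(p$noise_sd, 0.003)
})

test_that("unknown models and conditions raise lookup errors listing options", {
  expect_error(make_preset("phantom_I", "99A"), "valid: 20A, 30A, 40A")
  expect_error(make_preset("bovine_I", "artery"), "unknown model_id")
  expect_error(vessel_conditions("nope"), "valid")
})

test_that("spec invariants are enforced at construction", {
  expect_error(vessel_model_spec("x", "y", pulse_amplitude = 0), "pulse_amplitude")
  expect_error(vessel_model_spec("x", "y", 0.1, amplitude_cv = 1), "amplitude_cv")
  expect_error(vessel_model_spec("x", "y", 0.1, noise_sd = -1), "noise_sd")
  expect_error(vessel_model_spec("x", "y", 0.1, hold_duration = 0), "hold_duration")
})

test_that("a 15 s trial at 100 Hz has 1500 samples", {
  s <- simulate_grip_trial(make_preset("porcine_I", "artery"), fs = 100,
                           seed = 1)
  expect_length(s$samples, 1500)
  expect_equal(s$fs, 100)
})

test_that("sampling below 10x the pulse rate is rejected", {
  expect_error(simulate_grip_trial(make_preset("porcine_I", "artery"),
                                   fs = 10, seed = 1), "too low")
})

test_that("noiseless trials peak exactly pulse_amplitude above the baseline", {
  for (seed in 1:5) {
    s <- clean_trial(seed)
    expect_equal(max(s$samples) - 0.5, 0.047, tolerance = 1e-3)
    # clamp baseline is the median by construction of the template
    expect_equal(median(s$samples), 0.5, tolerance = 2e-3)
  }
})

test_that("a noiseless 90/min train over 15 s has 22 or 23 pulse maxima", {
  counts <- vapply(1:20, function(seed)
    count_local_maxima(clean_trial(seed)$samples), numeric(1))
  expect_true(all(counts %in% c(22, 23)))
  expect_true(length(unique(counts)) == 2) # both phases occur
})

test_that("trials are bit-for-bit reproducible for a fixed seed", {
  spec <- make_preset("phantom_III", "20A")
  a <- simulate_grip_trial(spec, fs = 100, seed = 99)
  b <- simulate_grip_trial(spec, fs = 100, seed = 99)
  expect_identical(a$samples, b$samples)
  c <- simulate_grip_trial(spec, fs = 100, seed = 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("the pulse template has unit peak and zero median", {
  u <- (0:9999) / 10000
  q <- pulse_template(u)
  expect_equal(max(q), 1, tolerance = 1e-4)
  expect_equal(median(q), 0, tolerance = 1e-3)
})

test_that("generate_dataset yields n_per_condition trials per condition", {
  d <- generate_dataset("porcine_I", 3, 100, 42)
  expect_length(d$sequences, 6)
  expect_equal(sort(unique(d$labels)), c(0L, 1L))
  expect_equal(as.vector(table(d$labels)), c(3L, 3L))
  expect_equal(d$class_names, c("artery", "vein"))
  d3 <- generate_dataset("phantom_III", 2, 100, 42)
  expect_length(d3$sequences, 6)
  expect_equal(length(d3$class_names), 3)
  dm <- generate_dataset("porcine_I", 1, 100, 0)
  expect_equal(dm$labels, c(0L, 1L))
  expect_error(generate_dataset("no_such_task", 3, 100, 1), "valid")
})

test_that("datasets are reproducible and trials mutually distinct", {
  d1 <- generate_dataset("porcine_I", 2, 100, 11)
  d2 <- generate_dataset("porcine_I", 2, 100, 11)
  for (i in seq_along(d1$sequences))
    expect_identical(d1$sequences[[i]]$samples, d2$sequences[[i]]$samples)
  expect_false(identical(d1$sequences[[1]]$samples,
                         d1$sequences[[2]]$samples))
})

test_that("dataset round-trips through CSV + manifest on disk", {
  d <- generate_dataset("porcine_III", 3, 100, 5)
  d <- split_dataset(d, seed = 1)
  dir <- tempfile("ds_")
  write_dataset(d, dir)
  r <- read_dataset(dir)
  expect_equal(r$labels, d$labels)
  expect_equal(r$class_names, d$class_names)
  expect_equal(r$split, d$split)
  for (i in seq_along(d$sequences))
    expect_equal(r$sequences[[i]]$samples, d$sequences[[i]]$samples,
                 tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
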