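# Wavelet denoising, Z-score, moving average and the stratified split.

test_that("wavelet decomposition reconstructs perfectly and preserves energy", {
  set.seed(4)
  for (n in c(64, 777, 1500)) {
    x <- rnorm(n)
    lev <- min(4, dwt_max_level(n))
    dec <- wavedec(x, level = lev)
    expect_equal(waverec(dec), x, tolerance = 1e-8)
    # orthonormality preserves energy exactly when no level needs the
    # odd-length extension
    if (n %% 2^lev == 0) {
      energy <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
      expect_equal(energy, sum(x^2), tolerance = 1e-10)
    }
  }
})

test_that("requesting too deep a decomposition names the maximum level", {
  expect_error(wavedec(rnorm(32), level = 10), "at most")
  expect_equal(dwt_max_level(1500), 7L)
  expect_equal(dwt_max_level(4), 0L)
})

test_that("soft thresholding shrinks toward zero and zeroes small values", {
  expect_equal(soft_threshold(c(-3, -0.5, 0, 0.5, 3), 1),
               c(-2, 0, 0, 0, 2))
  expect_error(soft_threshold(1, -1), ">= 0")
})

test_that("denoising an all-zero signal returns all zeros", {
  s <- force_signal(rep(0, 256), fs = 100)
  out <- wavelet_denoise(s)
  expect_equal(out$samples, rep(0, 256))
  expect_length(out$samples, 256)
})

test_that("a clean pulse train passes through the denoiser nearly unchanged", {
  s <- clean_trial(seed = 2)
  out <- wavelet_denoise(s)
  rmse <- sqrt(mean((out$samples - s$samples)^2))
  expect_lt(rmse, 0.02 * 0.047) # < 2% of the pulse amplitude
})

test_that("denoising removes most injected white noise", {
  s <- clean_trial(seed = 3)
  set.seed(30)
  noise <- rnorm(length(s$samples), 0, 0.01)
  noisy <- force_signal(s$samples + noise, fs = s$fs)
  out <- wavelet_denoise(noisy)
  residual <- out$samples - s$samples
  expect_lt(var(residual) / var(noise), 1)
})

test_that("zscore standardizes with the sample-sd convention", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(6)
  x <- rnorm(200, 5, 3)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # re-standardizing an already-unit signal changes the sd negligibly
  expect_equal(sd(zscore(z)), sd(z), tolerance = 1e-10)
  expect_error(zscore(c(5, 5, 5)), "constant")
})

test_that("moving average uses shrunk windows at the edges", {
  expect_equal(moving_average(c(1, 1, 1), 3), c(1, 1, 1))
  expect_equal(moving_average(c(0, 3, 0), 3), c(1.5, 1.0, 1.5))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 21), "exceeds")
  # interior matches a plain centered mean
  y <- moving_average(x, 5)
  expect_equal(y[3:18], vapply(3:18, function(i) mean(x[(i - 2):(i + 2)]),
                               numeric(1)))
})

test_that("the 6:2:2 split is stratified, disjoint, exhaustive, deterministic", {
  d <- generate_dataset("phantom_III", 80, 100, 21)
  s1 <- split_dataset(d, c(6, 2, 2), seed = 9)
  expect_equal(sum(s1$split == "train"), 144)
  expect_equal(sum(s1$split == "val"), 48)
  expect_equal(sum(s1$split == "test"), 48)
  # stratification: exact counts within each class
  for (cls in 0:2) {
    sub <- s1$split[s1$labels == cls]
    expect_equal(as.vector(table(factor(sub, c("train", "val", "test")))),
                 c(48, 16, 16))
  }
  s2 <- split_dataset(d, c(6, 2, 2), seed = 9)
  expect_identical(s1$split, s2$split)
  s3 <- split_dataset(d, c(6, 2, 2), seed = 10)
  expect_false(identical(s1$split, s3$split))
})

test_that("a 10-sequence class splits 6/2/2 and tiny classes error", {
  d <- generate_dataset("porcine_I", 10, 100, 3)
  s <- split_dataset(d, seed = 1)
  for (cls in 0:1) {
    sub <- s$split[s$labels == cls]
    expect_equal(as.vector(table(factor(sub, c("train", "val", "test")))),
                 c(6, 2, 2))
  }
  tiny <- generate_dataset("porcine_I", 2, 100, 3)
  expect_error(split_dataset(tiny), "need >= 3")
})

test_that("split proportions stay within one sequence of 6:2:2 per class", {
  for (n in c(10, 11, 13, 27, 80)) {
    d <- generate_dataset("porcine_I", n, 100, 1)
    s <- split_dataset(d, seed = 2)
    for (cls in 0:1) {
      sub <- s$split[s$labels == cls]
      counts <- as.vector(table(factor(sub, c("train", "val", "test"))))
      expect_true(all(abs(counts - n * c(0.6, 0.2, 0.2)) <= 1),
                  label = paste("n =", n))
    }
  }
})

test_that("pooled preprocessing preserves amplitude ordering between trials", {
  d <- generate_dataset("porcine_I", 4, 100, 13)
  d <- split_dataset(d, seed = 1)
  pp <- preprocess_dataset(d, preprocess_config())
  # artery trials (label 0) should keep a larger fluctuation than veins
  spread <- vapply(pp$sequences, function(s) diff(range(s$samples)),
                   numeric(1))
  expect_gt(min(spread[d$labels == 0]), max(spread[d$labels == 1]) * 0.9)
  # per-sequence normalization erases that difference
  ps <- preprocess_dataset(d, preprocess_config(normalization = "per_sequence"))
  m <- vapply(ps$sequences, function(s) mean(s$samples), numeric(1))
  expect_equal(m, rep(0, 8), tolerance = 1e-3)
})
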