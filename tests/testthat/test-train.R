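# Optimization recipe: cosine schedule with doubling restarts, BCE loss,
# seeded SGD training.

test_that("the cosine schedule hits its anchor points", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.002)
  expect_equal(lr_schedule(25, cfg), 0.001) # cos(pi/2) = 0 -> half base
  expect_equal(lr_schedule(50, cfg), 0) # cycle end, alpha = 0
  # first step of cycle 1 follows a cosine from the doubled base
  expect_equal(lr_schedule(51, cfg),
               0.004 * 0.5 * (1 + cos(pi * 1 / 50)))
  expect_equal(lr_schedule(100, cfg), 0) # end of cycle 1
  expect_error(lr_schedule(-1, cfg), ">= 0")
})

test_that("the restart base doubles then freezes at max_restarts", {
  cfg <- train_config(max_restarts = 2)
  starts <- lr_schedule(c(1, 51, 101, 151, 201), cfg)
  bases <- c(0.002, 0.004, 0.008, 0.008, 0.008) # frozen after 2 restarts
  expect_equal(starts, bases * 0.5 * (1 + cos(pi / 50)))
})

test_that("the schedule is continuous within each cycle and floors at alpha", {
  cfg <- train_config(alpha = 0.1)
  lr <- lr_schedule(0:50, cfg)
  expect_true(all(diff(lr) < 0)) # monotone half-cosine
  expect_lt(max(abs(diff(lr))), 0.002 * pi / 50 * 1.01) # no jumps
  expect_equal(lr[51], 0.1 * 0.002) # alpha * base at the cycle end
})

test_that("bce_loss matches analytic values", {
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-9)
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  set.seed(8)
  s <- runif(40)
  expect_gte(bce_loss(s, round(s)), 0)
  expect_error(bce_loss(c(0.5, 0.5), 1), "shapes")
})

test_that("windowing tiles trials into labeled non-overlapping windows", {
  d <- generate_dataset("porcine_I", 2, 100, 9) # 4 x 1500 samples
  w <- make_windows(d, input_length = 500)
  expect_equal(dim(w$x), c(12, 500, 1))
  expect_equal(w$labels, rep(d$labels, each = 3))
  expect_equal(w$trial, rep(1:4, each = 3))
  expect_equal(w$x[5, , 1], d$sequences[[2]]$samples[501:1000])
  expect_error(make_windows(d, input_length = 2000), "shorter")
})

test_that("two seeded training runs produce identical histories", {
  d <- generate_dataset("porcine_I", 5, 100, 31)
  d <- split_dataset(d, seed = 1)
  pp <- preprocess_dataset(d)
  cfg <- tiny_model_config()
  run <- function() {
    m <- build_model(cfg, seed = 5)
    train(m, pp, train_config(max_epochs = 3, patience = Inf, seed = 5))
  }
  f1 <- run()
  f2 <- run()
  expect_equal(nrow(f1$history), 3)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_lte(f1$best_epoch, 3)
})

test_that("training reduces the loss on an easy separable task", {
  d <- generate_dataset("porcine_I", 10, 100, 17)
  d <- split_dataset(d, seed = 2)
  pp <- preprocess_dataset(d)
  m <- build_model(tiny_model_config(), seed = 3)
  fit <- train(m, pp, train_config(max_epochs = 12, patience = Inf, seed = 3))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(fit$history$epoch, 1:12)
})

test_that("training refuses an unsplit dataset or mismatched loss", {
  d <- generate_dataset("porcine_I", 4, 100, 2)
  pp <- preprocess_dataset(d)
  m <- build_model(tiny_model_config(), seed = 1)
  expect_error(train(m, pp, train_config()), "split")
  d2 <- split_dataset(d, seed = 1)
  pp2 <- preprocess_dataset(d2)
  expect_error(train(m, pp2, train_config(loss = "softmax_ce")),
               "loss mismatch")
})
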