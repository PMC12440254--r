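# CNN-LSTM architecture: shapes, determinism, bottleneck contract, and a
# finite-difference check of the whole backward pass.

test_that("the built model has the prescribed path widths and output", {
  m <- build_model(tiny_model_config(n_classes = 2), seed = 1)
  spec <- network_spec(m)
  expect_equal(spec$n_classes, 2)
  expect_equal(unname(spec$path_widths["lstm"]), 4)
  expect_equal(spec$fc_input_width, 6 + 4)
  # default config: LSTM path yields the 20-value temporal feature
  def <- build_model(model_config(n_classes = 3), seed = 1)
  expect_equal(unname(network_spec(def)$path_widths["lstm"]), 20)
  expect_equal(def$config$lstm_hidden_1, 64)
  x <- array(rnorm(2 * 32), c(2, 32, 1))
  s <- model_forward(m, x)
  expect_equal(dim(s), c(2L, 2L))
})

test_that("parameter count is a pure function of the configuration", {
  a <- build_model(tiny_model_config(), seed = 1)
  b <- build_model(tiny_model_config(), seed = 999)
  expect_equal(n_params(a), n_params(b))
  bigger <- build_model(tiny_model_config(lstm_out = 8), seed = 1)
  expect_gt(n_params(bigger), n_params(a))
  # identical (config, seed) gives identical weights
  c <- build_model(tiny_model_config(), seed = 1)
  expect_identical(a$head$params$W, c$head$params$W)
  expect_identical(a$lstm1$params$Wx, c$lstm1$params$Wx)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(model_config(input_length = 16), "input_length")
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(model_config(bottleneck_channels = c(4, 4, 8),
                            cnn_stem_channels = 16), "expand width")
  expect_error(model_config(dropout_cnn = 1), "dropout")
})

test_that("bottleneck blocks preserve length and satisfy the sum contract", {
  set.seed(2)
  blk <- pulsegrip:::.new_bottleneck(6, c(3, 3, 6))
  x <- array(rnorm(2 * 11 * 6), c(2, 11, 6))
  out <- bottleneck_forward(x, blk)
  expect_equal(dim(out), dim(x)) # stride 1, symmetric padding
  # all-zero weights give all-zero output
  z <- pulsegrip:::.new_bottleneck(6, c(3, 3, 6))
  for (l in c(z$trunk, z$branch))
    for (nm in names(l$params)) l$params[[nm]][] <- 0
  expect_equal(bottleneck_forward(x, z, train = FALSE),
               array(0, dim(x)))
  # zero trunk: output equals ReLU of the branch path alone, where the
  # branch is computed independently with plain matrix arithmetic
  half <- pulsegrip:::.new_bottleneck(6, c(3, 3, 6))
  for (l in half$trunk) for (nm in names(l$params)) l$params[[nm]][] <- 0
  got <- bottleneck_forward(x, half, train = FALSE)
  branch_manual <- x
  for (l in half$branch)
    branch_manual <- pulsegrip:::nn_forward(l, branch_manual, FALSE)
  expect_equal(got, pmax(branch_manual, 0) * 1, tolerance = 1e-12)
})

test_that("forward scores lie in [0, 1] and are batch invariant in eval mode", {
  m <- build_model(tiny_model_config(), seed = 3)
  set.seed(4)
  x <- array(rnorm(6 * 32), c(6, 32, 1))
  s <- model_forward(m, x)
  expect_true(all(s >= 0 & s <= 1))
  # the same item scored alone and inside a batch agrees
  s1 <- model_forward(m, x[3, , , drop = FALSE])
  expect_equal(as.vector(s1), as.vector(s[3, ]), tolerance = 1e-6)
  # eval-mode forward is deterministic
  expect_identical(model_forward(m, x), s)
  expect_error(model_forward(m, array(0, c(2, 31, 1))), "input_length")
})

test_that("analytic gradients match finite differences through both paths", {
  m <- build_model(tiny_model_config(), seed = 11)
  envs <- pulsegrip:::.model_layer_envs(m)
  # move every parameter off zero so no ReLU pre-activation sits exactly
  # on its kink (finite differences are meaningless at the kink)
  set.seed(5)
  for (l in envs)
    for (nm in names(l$params)) {
      d <- dim(l$params[[nm]])
      l$params[[nm]] <- l$params[[nm]] +
        array(rnorm(length(l$params[[nm]]), 0, 0.05),
              if (is.null(d)) length(l$params[[nm]]) else d)
    }
  N <- 4
  x <- array(rnorm(N * 32), c(N, 32, 1))
  y <- matrix(0, N, 2)
  y[cbind(1:N, sample(1:2, N, TRUE))] <- 1
  loss_at <- function() bce_loss(model_forward(m, x, train = TRUE), y)
  s <- model_forward(m, x, train = TRUE)
  dlogits <- (s - y) / length(y)
  pulsegrip:::.model_backward(m, dlogits)
  eps <- 1e-6
  for (k in seq_along(envs)) {
    l <- envs[[k]]
    for (nm in names(l$grads)) {
      p <- l$params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        o <- p[i]
        l$params[[nm]][i] <- o + eps
        lp <- loss_at()
        l$params[[nm]][i] <- o - eps
        lm <- loss_at()
        l$params[[nm]][i] <- o
        num <- (lp - lm) / (2 * eps)
        ana <- l$grads[[nm]][i]
        expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-7), 1e-3,
                  label = paste("grad", l$type, nm, i))
      }
    }
  }
})

test_that("untrained forward scores are reproducible for a fixed seed", {
  x <- array(rnorm(3 * 32), c(3, 32, 1))
  s1 <- model_forward(build_model(tiny_model_config(), seed = 21), x)
  s2 <- model_forward(build_model(tiny_model_config(), seed = 21), x)
  expect_identical(s1, s2)
})
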