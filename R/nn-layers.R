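## Minimal 1-D neural-network layer library (forward + backprop) in base R.
##
## Layers are mutable environments holding `params`, `grads` and the
## forward cache. Sequence tensors are arrays of dim (batch, time,
## channels); feature tensors are matrices (batch, features). All heavy
## operations are expressed as BLAS matrix products (convolutions via
## im2col). Stochastic pieces (initialization, dropout) draw from the
## ambient RNG stream, so callers seed them with `with_seed()`.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# column-wise add / multiply without sweep()'s aperm overhead
.add_cols <- function(x, b) x + rep(b, each = nrow(x))
.mul_cols <- function(x, v) x * rep(v, each = nrow(x))

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- list()
  e$grads <- list()
  class(e) <- "nn_layer"
  e
}

nn_dense <- function(n_in, n_out) {
  l <- new_layer("dense", n_in = n_in, n_out = n_out)
  l$params$W <- matrix(stats::rnorm(n_in * n_out) * sqrt(2 / n_in),
                       n_in, n_out)
  l$params$b <- numeric(n_out)
  l
}

nn_conv1d <- function(in_ch, out_ch, kernel) {
  l <- new_layer("conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel)
  fan_in <- kernel * in_ch
  l$params$W <- matrix(stats::rnorm(fan_in * out_ch) * sqrt(2 / fan_in),
                       fan_in, out_ch)
  l$params$b <- numeric(out_ch)
  l
}

nn_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", channels = channels, momentum = momentum, eps = eps)
  l$params$gamma <- rep(1, channels)
  l$params$beta <- rep(0, channels)
  l$run_mean <- rep(0, channels)
  l$run_var <- rep(1, channels)
  l
}

nn_relu <- function() new_layer("relu")

nn_maxpool <- function(size = 2) new_layer("maxpool", size = size)

nn_dropout <- function(p) new_layer("dropout", p = p)

nn_gap <- function() new_layer("gap")

nn_lstm <- function(n_in, n_hidden, return_sequences = FALSE) {
  l <- new_layer("lstm", n_in = n_in, n_hidden = n_hidden,
                 return_sequences = return_sequences)
  s <- 1 / sqrt(n_hidden)
  l$params$Wx <- matrix(stats::runif(n_in * 4 * n_hidden, -s, s),
                        n_in, 4 * n_hidden)
  l$params$Wh <- matrix(stats::runif(n_hidden * 4 * n_hidden, -s, s),
                        n_hidden, 4 * n_hidden)
  b <- numeric(4 * n_hidden)
  b[n_hidden + seq_len(n_hidden)] <- 1 # forget-gate bias
  l$params$b <- b
  l
}

# flatten (N, L, C) -> (N*L, C) and back
.flat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}
.unflat <- function(x, N, L) {
  dim(x) <- c(N, L, ncol(x))
  x
}

nn_forward <- function(layer, x, train = FALSE) {
  switch(
    layer$type,
    dense = {
      layer$cache_x <- x
      .add_cols(x %*% layer$params$W, layer$params$b)
    },
    conv1d = {
      d <- dim(x)
      N <- d[1]; L <- d[2]; C <- d[3]
      if (C != layer$in_ch)
        stop("conv1d: expected ", layer$in_ch, " channels, got ", C)
      k <- layer$kernel
      Xcol <- .cpp_im2col(.flat(x), N, L, k) # trailing ones column: bias
      layer$cache <- list(Xcol = Xcol, N = N, L = L, C = C)
      out <- Xcol %*% rbind(layer$params$W, layer$params$b)
      .unflat(out, N, L)
    },
    bn = {
      d <- dim(x)
      C <- d[length(d)]
      if (C != layer$channels)
        stop("bn: expected ", layer$channels, " channels, got ", C)
      xm <- x
      dim(xm) <- c(prod(d[-length(d)]), C)
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean +
          layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var +
          layer$momentum * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      inv_std <- 1 / sqrt(v + layer$eps)
      xhat <- .cpp_affine_cols(xm, inv_std, -mu * inv_std)
      out <- .cpp_affine_cols(xhat, layer$params$gamma, layer$params$beta)
      if (train) layer$cache <- list(xhat = xhat, inv_std = inv_std, dims = d)
      dim(out) <- d
      out
    },
    relu = {
      layer$cache_mask <- x > 0
      x * layer$cache_mask
    },
    maxpool = {
      d <- dim(x)
      N <- d[1]; L <- d[2]; C <- d[3]
      s <- layer$size
      Lo <- L %/% s
      xs <- x[, seq_len(Lo * s), , drop = FALSE]
      # element (n, l, c) with l = r + (q-1)*s maps to (n, r, q, c) under
      # column-major reshaping, so pooling reduces over the second axis
      dim(xs) <- c(N, s, Lo, C)
      out <- xs[, 1, , , drop = FALSE]
      arg <- array(1L, c(N, Lo, C))
      for (r in 2:s) {
        cand <- xs[, r, , , drop = FALSE]
        upd <- cand > out
        out[upd] <- cand[upd]
        arg[array(upd, c(N, Lo, C))] <- r
      }
      dim(out) <- c(N, Lo, C)
      layer$cache <- list(arg = arg, N = N, L = L, Lo = Lo, C = C)
      out
    },
    dropout = {
      if (train && layer$p > 0) {
        keep <- 1 - layer$p
        m <- array((stats::runif(length(x)) < keep) / keep, dim(x))
        layer$cache_mask <- m
        x * m
      } else {
        layer$cache_mask <- NULL
        x
      }
    },
    gap = {
      d <- dim(x)
      layer$cache <- list(N = d[1], L = d[2], C = d[3])
      xm <- aperm(x, c(2, 1, 3))
      dim(xm) <- c(d[2], d[1] * d[3])
      out <- colMeans(xm)
      dim(out) <- c(d[1], d[3])
      out
    },
    lstm = .lstm_forward(layer, x, train),
    stop("nn_forward: unknown layer type ", layer$type)
  )
}

nn_backward <- function(layer, dout) {
  switch(
    layer$type,
    dense = {
      layer$grads$W <- crossprod(layer$cache_x, dout)
      layer$grads$b <- colSums(dout)
      tcrossprod(dout, layer$params$W)
    },
    conv1d = {
      cc <- layer$cache
      N <- cc$N; L <- cc$L; C <- cc$C; k <- layer$kernel
      dflat <- dout
      dim(dflat) <- c(N * L, layer$out_ch)
      dWb <- crossprod(cc$Xcol, dflat)
      layer$grads$W <- dWb[-nrow(dWb), , drop = FALSE]
      layer$grads$b <- dWb[nrow(dWb), ]
      dXcol <- tcrossprod(dflat, layer$params$W)
      .unflat(.cpp_col2im(dXcol, N, L, k, C), N, L)
    },
    bn = {
      cc <- layer$cache
      d <- cc$dims
      dm <- dout
      dim(dm) <- dim(cc$xhat)
      M <- nrow(dm)
      layer$grads$gamma <- colSums(dm * cc$xhat)
      layer$grads$beta <- colSums(dm)
      dxhat <- .cpp_affine_cols(dm, layer$params$gamma,
                                numeric(ncol(dm)))
      m2 <- colMeans(dxhat * cc$xhat)
      dx <- .cpp_affine_cols(dxhat, cc$inv_std,
                             -colMeans(dxhat) * cc$inv_std) -
        .cpp_affine_cols(cc$xhat, m2 * cc$inv_std, numeric(ncol(dm)))
      dim(dx) <- d
      dx
    },
    relu = dout * layer$cache_mask,
    maxpool = {
      cc <- layer$cache
      s <- layer$size
      dxs <- array(0, c(cc$N, s, cc$Lo, cc$C))
      for (r in seq_len(s)) {
        sel <- cc$arg == r
        slot <- array(0, c(cc$N, cc$Lo, cc$C))
        slot[sel] <- dout[sel]
        dxs[, r, , ] <- slot
      }
      dim(dxs) <- c(cc$N, s * cc$Lo, cc$C)
      if (s * cc$Lo < cc$L) {
        dx <- array(0, c(cc$N, cc$L, cc$C))
        dx[, seq_len(s * cc$Lo), ] <- dxs
        dx
      } else dxs
    },
    dropout = {
      if (is.null(layer$cache_mask)) dout else dout * layer$cache_mask
    },
    gap = {
      cc <- layer$cache
      aperm(array(dout / cc$L, c(cc$N, cc$C, cc$L)), c(1, 3, 2))
    },
    lstm = .lstm_backward(layer, dout),
    stop("nn_backward: unknown layer type ", layer$type)
  )
}

.lstm_forward <- function(layer, x, train) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; D <- d[3]
  if (D != layer$n_in)
    stop("lstm: expected ", layer$n_in, " input features, got ", D)
  H <- layer$n_hidden
  Xf <- cbind(.flat(x), 1) # (N*L, D + 1); ones column carries the bias
  Xproj <- Xf %*% rbind(layer$params$Wx, layer$params$b)
  res <- .cpp_lstm_forward(Xproj, layer$params$Wh, N, L, H,
                           want_cache = train)
  if (train) {
    res$Xf <- Xf
    res$N <- N; res$L <- L
    layer$cache <- res
  }
  if (layer$return_sequences) .unflat(res$Hseq, N, L) else res$last_h
}

.lstm_backward <- function(layer, dout) {
  cc <- layer$cache
  N <- cc$N; L <- cc$L; H <- layer$n_hidden
  if (layer$return_sequences) {
    dim(dout) <- c(N * L, H)
  }
  res <- .cpp_lstm_backward(dout, cc$Hseq, cc$Gi, cc$Gf, cc$Gg, cc$Go,
                            cc$Tc, cc$Cs, layer$params$Wh, N, L, H,
                            seq_grad = layer$return_sequences)
  dWxb <- crossprod(cc$Xf, res$dZ)
  layer$grads$Wx <- dWxb[-nrow(dWxb), , drop = FALSE]
  layer$grads$Wh <- res$dWh
  layer$grads$b <- dWxb[nrow(dWxb), ]
  dx <- tcrossprod(res$dZ, layer$params$Wx)
  .unflat(dx, N, L)
}

# number of parameters in one layer
.layer_n_params <- function(layer) {
  sum(vapply(layer$params, length, integer(1)))
}
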