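# Internal neural-network primitives: SiLU, inverted dropout, dense layers,
# a size-preserving 2-D convolution expressed as a sum of shifted images, and
# non-overlapping max-pooling. All operate on whole batches (N x d matrices);
# each forward returns what its backward needs. Gradients with respect to the
# raw data input are never required (the first layer consumes data), so the
# convolution backward returns parameter gradients only.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.silu <- function(x) x * .sigmoid(x)

.silu_grad <- function(x) {
  s <- .sigmoid(x)
  s * (1 + x * (1 - s))
}

.dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - p
  mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) < keep) / keep
  list(out = x * mask, mask = mask)
}

.linear_forward <- function(x, W, b) {
  sweep(x %*% W, 2, b, "+")
}

.linear_backward <- function(x, W, dout, need_dx = TRUE) {
  list(dW = crossprod(x, dout),
       db = colSums(dout),
       dx = if (need_dx) tcrossprod(dout, W) else NULL)
}

# Geometry of the 1-D -> 2-D reshape and the conv/pool index maps for a given
# input dimension. The abundance vector is zero-padded to the smallest square
# side^2 and laid out row-major; `conv_idx[[j]]` maps each of the side^2
# output positions to its source position for kernel offset j (side^2 + 1 is
# a dummy zero column for positions falling outside the image), and
# `pool_idx[[m]]` maps each pooled position to its m-th window member.
.conv_geometry <- function(input_dim, kernel, pool) {
  stopifnot(kernel %% 2 == 1)
  side <- ceiling(sqrt(input_dim))
  half <- (kernel - 1L) %/% 2L
  grid <- expand.grid(c = seq_len(side), r = seq_len(side))  # row-major flat
  conv_idx <- vector("list", kernel * kernel)
  j <- 0L
  for (a in -half:half) {
    for (b in -half:half) {
      j <- j + 1L
      r <- grid$r + a
      c <- grid$c + b
      idx <- (r - 1L) * side + c
      idx[r < 1L | r > side | c < 1L | c > side] <- side * side + 1L
      conv_idx[[j]] <- idx
    }
  }
  pside <- side %/% pool
  if (pside < 1L)
    stop("pool window exceeds the image side; reduce pool_size")
  pgrid <- expand.grid(c = seq_len(pside), r = seq_len(pside))
  pool_idx <- vector("list", pool * pool)
  m <- 0L
  for (a in seq_len(pool) - 1L) {
    for (b in seq_len(pool) - 1L) {
      m <- m + 1L
      r <- (pgrid$r - 1L) * pool + 1L + a
      c <- (pgrid$c - 1L) * pool + 1L + b
      pool_idx[[m]] <- (r - 1L) * side + c
    }
  }
  list(side = side, pside = pside, conv_idx = conv_idx, pool_idx = pool_idx)
}

# x: N x input_dim batch. W: kernel^2 x channels, b: channels.
# Returns channel outputs (pre-activation) plus the shifted-image stack.
.conv_forward <- function(x, W, b, geom) {
  n <- nrow(x)
  sq <- geom$side^2
  img <- matrix(0, n, sq + 1L)  # last column stays zero (out-of-image)
  img[, seq_len(ncol(x))] <- x
  shifts <- lapply(geom$conv_idx, function(idx) img[, idx, drop = FALSE])
  channels <- vector("list", ncol(W))
  for (ch in seq_len(ncol(W))) {
    acc <- matrix(b[ch], n, sq)
    for (j in seq_along(shifts)) acc <- acc + shifts[[j]] * W[j, ch]
    channels[[ch]] <- acc
  }
  list(channels = channels, shifts = shifts)
}

.conv_backward <- function(cache, dchannels) {
  k2 <- length(cache$shifts)
  nc <- length(dchannels)
  dW <- matrix(0, k2, nc)
  db <- numeric(nc)
  for (ch in seq_len(nc)) {
    d <- dchannels[[ch]]
    db[ch] <- sum(d)
    for (j in seq_len(k2)) dW[j, ch] <- sum(cache$shifts[[j]] * d)
  }
  list(dW = dW, db = db)
}

# Per-channel max pooling over non-overlapping windows; records which window
# member won so the backward pass can route the gradient.
.pool_forward <- function(x, geom) {
  m1 <- x[, geom$pool_idx[[1L]], drop = FALSE]
  best <- m1
  arg <- matrix(1L, nrow(x), ncol(m1))
  for (m in seq_along(geom$pool_idx)[-1L]) {
    cand <- x[, geom$pool_idx[[m]], drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- m
  }
  list(out = best, arg = arg)
}

.pool_backward <- function(cache, dout, geom, input_cols) {
  dx <- matrix(0, nrow(dout), input_cols)
  for (m in seq_along(geom$pool_idx)) {
    contrib <- dout * (cache$arg == m)
    idx <- geom$pool_idx[[m]]
    dx[, idx] <- dx[, idx] + contrib
  }
  dx
}

# Adam with the standard bias correction; `state` carries first/second moment
# trees shaped like the parameter tree.
.adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
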