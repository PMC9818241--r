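# Minimal dense-tensor neural-network layers with explicit forward/backward
# passes. Feature maps are 4-D arrays in channel-first layout (C, H, W, N):
# with the channel index fastest, per-channel broadcasting is plain vector
# recycling and im2col lowers to a single indexed gather whose result is
# already GEMM-ready, so convolutions run as one BLAS matrix product each
# way. Only the pieces the pyramid detector needs are implemented: 2-D
# convolution (stride 1/2, kernel 1/3), batch normalization, ReLU, and
# nearest-neighbor 2x upsampling.

conv_init <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias_init = 0) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)),
                  cout, fan_in),
       b = rep(bias_init, cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout))
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  xp[, p + seq_len(d[2L]), p + seq_len(d[3L]), ] <- x
  xp
}

# Gather indices into one padded (C, Hp, Wp) volume, ordered so the gathered
# vector can be reinterpreted as a (C*k*k, H2*W2) matrix without copying:
# channel fastest, then kernel offset (row offset fastest), then output cell
# (output row fastest). Cached per geometry: the same few layer shapes recur
# every step.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(cin, hp, wp, k, stride, h2, w2) {
  key <- paste(cin, hp, wp, k, stride, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  di <- rep(seq_len(k) - 1L, times = k)
  dj <- rep(seq_len(k) - 1L, each = k)
  pt <- di * cin + dj * cin * hp                       # kernel-offset strides
  i0 <- (seq_len(h2) - 1L) * stride
  j0 <- (seq_len(w2) - 1L) * stride
  po <- rep(i0, times = w2) * cin + rep(j0, each = h2) * cin * hp
  idx <- rep(seq_len(cin), times = k * k * h2 * w2) +
    rep(rep(pt, each = cin), times = h2 * w2) +
    rep(po, each = cin * k * k)
  # rowsum() returns groups in sorted order; cache that order for col2im
  attr(idx, "ugrp") <- sort(unique(idx))
  .im2col_cache[[key]] <- idx
  idx
}

conv_forward <- function(layer, x, keep_ctx = TRUE) {
  d <- dim(x)
  cin <- d[1L]; h <- d[2L]; w <- d[3L]; n <- d[4L]
  stopifnot(cin == layer$cin)
  k <- layer$k; s <- layer$stride; p <- layer$pad
  h2 <- (h + 2L * p - k) %/% s + 1L
  w2 <- (w + 2L * p - k) %/% s + 1L
  if (k == 1L && s == 1L && p == 0L) {
    cmat <- x
    dim(cmat) <- c(cin, h * w * n)
    idx <- NULL
  } else {
    xp <- pad_hw(x, p)
    hp <- h + 2L * p; wp <- w + 2L * p
    idx <- im2col_index(cin, hp, wp, k, s, h2, w2)
    dim(xp) <- c(cin * hp * wp, n)
    cmat <- xp[idx, , drop = FALSE]
    dim(cmat) <- c(cin * k * k, h2 * w2 * n)
  }
  y <- layer$W %*% cmat + layer$b
  dim(y) <- c(layer$cout, h2, w2, n)
  ctx <- if (keep_ctx) list(cmat = cmat, idx = idx, in_dim = d, h2 = h2, w2 = w2)
  list(y = y, ctx = ctx)
}

conv_backward <- function(layer, ctx, dy) {
  k <- layer$k; s <- layer$stride; p <- layer$pad
  d <- ctx$in_dim
  cin <- d[1L]; n <- d[4L]
  h2 <- ctx$h2; w2 <- ctx$w2
  dym <- dy
  dim(dym) <- c(layer$cout, h2 * w2 * n)
  dW <- tcrossprod(dym, ctx$cmat)
  db <- rowSums(dym)
  dcmat <- crossprod(layer$W, dym)                # (cin*k*k, h2*w2*n)
  if (is.null(ctx$idx)) {
    dx <- dcmat
    dim(dx) <- d
  } else {
    hp <- d[2L] + 2L * p; wp <- d[3L] + 2L * p
    dim(dcmat) <- c(cin * k * k * h2 * w2, n)
    rs <- rowsum(dcmat, as.vector(ctx$idx))        # scatter-add (col2im)
    dxp <- matrix(0, cin * hp * wp, n)
    dxp[attr(ctx$idx, "ugrp"), ] <- rs
    dim(dxp) <- c(cin, hp, wp, n)
    dx <- if (p == 0L) dxp else
      dxp[, p + seq_len(d[2L]), p + seq_len(d[3L]), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

bn_init <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       running_mean = rep(0, ch), running_var = rep(1, ch),
       momentum = 0.1, eps = 1e-5, ch = as.integer(ch))
}

# per-channel sums exploit the channel-fastest layout
channel_sums <- function(a, ch) rowSums(matrix(a, ch, length(a) / ch))

bn_forward <- function(layer, x, training = TRUE) {
  ch <- dim(x)[1L]
  m <- length(x) / ch                              # samples per channel
  if (training) {
    mu <- channel_sums(x, ch) / m
    xc <- x - mu                                   # recycles down dim 1
    vr <- channel_sums(xc^2, ch) / m
    std <- sqrt(vr + layer$eps)
    xhat <- xc / std
    new_rm <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    new_rv <- (1 - layer$momentum) * layer$running_var + layer$momentum * vr
    ctx <- list(xhat = xhat, std = std, m = m, ch = ch)
  } else {
    std <- sqrt(layer$running_var + layer$eps)
    xhat <- (x - layer$running_mean) / std
    new_rm <- layer$running_mean; new_rv <- layer$running_var
    ctx <- NULL
  }
  y <- xhat * layer$gamma + layer$beta
  list(y = y, ctx = ctx, running_mean = new_rm, running_var = new_rv)
}

bn_backward <- function(layer, ctx, dy) {
  ch <- ctx$ch; m <- ctx$m
  dgamma <- channel_sums(dy * ctx$xhat, ch)
  dbeta <- channel_sums(dy, ch)
  dxhat <- dy * layer$gamma
  # standard batch-norm gradient
  dx <- (dxhat - channel_sums(dxhat, ch) / m -
           ctx$xhat * (channel_sums(dxhat * ctx$xhat, ch) / m)) / ctx$std
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, ctx = mask)
}

relu_backward <- function(ctx, dy) dy * ctx

upsample2x_forward <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2L]), each = 2L), rep(seq_len(d[3L]), each = 2L), ,
    drop = FALSE]
}

upsample2x_backward <- function(dy) {
  d <- dim(dy)
  a <- dy[, seq(1L, d[2L], 2L), , , drop = FALSE] +
    dy[, seq(2L, d[2L], 2L), , , drop = FALSE]
  a[, , seq(1L, d[3L], 2L), , drop = FALSE] +
    a[, , seq(2L, d[3L], 2L), , drop = FALSE]
}

# ---- parameter bookkeeping -------------------------------------------------

# flatten the model's trainable parameters into a named list of numeric
# objects; `assign_params` writes an identically-shaped list back
collect_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.null(l$W)) {
      out[[paste0(nm, ".W")]] <- l$W
      out[[paste0(nm, ".b")]] <- l$b
    } else if (!is.null(l$gamma)) {
      out[[paste0(nm, ".gamma")]] <- l$gamma
      out[[paste0(nm, ".beta")]] <- l$beta
    }
  }
  out
}

assign_params <- function(layers, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    layers[[parts[1L]]][[parts[2L]]] <- flat[[nm]]
  }
  layers
}

adam_init <- function(flat_params) {
  list(m = lapply(flat_params, function(p) p * 0),
       v = lapply(flat_params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat_params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 1e-6) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat_params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weight_decay * flat_params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat_params[[nm]] <- flat_params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = flat_params, state = state)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_grads <- function(grads, max_norm) {
  gn <- grad_global_norm(grads)
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  }
  grads
}

# accumulate gradient lists (same names/shapes)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
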