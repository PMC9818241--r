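#' Detector architecture configuration
#'
#' A residual bottom-up pathway, a feature-pyramid top-down pathway with
#' lateral skip connections, and three subnetworks (box regression plus two
#' classifications: joint identity 1-32 and erosion score 0-5) applied to
#' the p2 (stride 4) and p3 (stride 8) pyramid levels. Batch normalization
#' and ReLU follow every backbone convolution. The default channel widths
#' give a deliberately small network that trains on a CPU; widths are the
#' dials for scaling up.
#'
#' @param image_size square input side in pixels; must be divisible by 8.
#' @param backbone_channels channels after the stem and the two residual
#'   stages (strides 2, 4, 8).
#' @param fpn_channels pyramid channel width.
#' @param head_channels,head_depth width and number of trunk convolutions in
#'   the subnetworks; the two classification heads share their trunk.
#' @param n_joint_classes,n_erosion_classes class counts (32 joints, 6
#'   erosion scores).
#' @param anchor_scales,anchor_ratios per-cell anchor shapes.
#' @param anchor_base base anchor sides at scale 1 for p2 and p3
#'   (`NULL` = 4 x stride, i.e. 16 and 32 pixels).
#' @param prior_prob initial foreground probability used to bias the
#'   classification outputs (focal-loss initialization).
#' @return an object of class `model_config`.
#' @export
model_config <- function(image_size = 400L,
                         backbone_channels = c(8L, 16L, 32L),
                         fpn_channels = 32L,
                         head_channels = 32L, head_depth = 1L,
                         n_joint_classes = 32L, n_erosion_classes = 6L,
                         anchor_scales = 2^(c(0, 1, 2) / 3),
                         anchor_ratios = c(0.5, 1, 2),
                         anchor_base = NULL,
                         prior_prob = 0.01) {
  if (image_size %% 8L != 0L) stop("image_size must be divisible by 8")
  if (is.null(anchor_base)) anchor_base <- c(p2 = 16, p3 = 32)
  stopifnot(length(anchor_base) == 2L, all(anchor_base > 0))
  names(anchor_base) <- c("p2", "p3")
  structure(
    list(image_size = as.integer(image_size),
         backbone_channels = as.integer(backbone_channels),
         fpn_channels = as.integer(fpn_channels),
         head_channels = as.integer(head_channels),
         head_depth = as.integer(head_depth),
         n_joint_classes = as.integer(n_joint_classes),
         n_erosion_classes = as.integer(n_erosion_classes),
         anchor_scales = anchor_scales, anchor_ratios = anchor_ratios,
         anchor_base = anchor_base,
         levels = c("p2", "p3"), prior_prob = prior_prob),
    class = "model_config"
  )
}

#' Anchors for every pyramid level of a configured model
#'
#' @param config a [model_config()].
#' @return named list of [generate_anchors()] anchor sets (`p2`, `p3`).
#' @export
model_anchors <- function(config) {
  s <- config$image_size
  list(
    p2 = generate_anchors(c(s %/% 4L, s %/% 4L), "p2",
                          scales = config$anchor_scales,
                          ratios = config$anchor_ratios,
                          base_size = config$anchor_base[["p2"]]),
    p3 = generate_anchors(c(s %/% 8L, s %/% 8L), "p3",
                          scales = config$anchor_scales,
                          ratios = config$anchor_ratios,
                          base_size = config$anchor_base[["p3"]])
  )
}

#' Build a detector with freshly initialized weights
#'
#' Weights are He-initialized from the current RNG stream (`set.seed()`
#' first for reproducibility); classification output biases start at the
#' focal-loss prior so the untrained detector predicts background.
#'
#' @param config a [model_config()].
#' @return an object of class `detector`.
#' @export
build_detector <- function(config) {
  bc <- config$backbone_channels
  fc <- config$fpn_channels
  hc <- config$head_channels
  n_anchor <- length(config$anchor_scales) * length(config$anchor_ratios)
  cls_bias <- -log((1 - config$prior_prob) / config$prior_prob)

  layers <- list(
    stem = conv_init(3L, 1L, bc[1L], stride = 2L),
    stem_bn = bn_init(bc[1L]),
    b1_conv1 = conv_init(3L, bc[1L], bc[2L], stride = 2L),
    b1_bn1 = bn_init(bc[2L]),
    b1_conv2 = conv_init(3L, bc[2L], bc[2L]),
    b1_bn2 = bn_init(bc[2L]),
    b1_skip = conv_init(1L, bc[1L], bc[2L], stride = 2L, pad = 0L),
    b1_skipbn = bn_init(bc[2L]),
    b2_conv1 = conv_init(3L, bc[2L], bc[3L], stride = 2L),
    b2_bn1 = bn_init(bc[3L]),
    b2_conv2 = conv_init(3L, bc[3L], bc[3L]),
    b2_bn2 = bn_init(bc[3L]),
    b2_skip = conv_init(1L, bc[2L], bc[3L], stride = 2L, pad = 0L),
    b2_skipbn = bn_init(bc[3L]),
    lat2 = conv_init(1L, bc[2L], fc, pad = 0L),
    lat3 = conv_init(1L, bc[3L], fc, pad = 0L),
    smooth2 = conv_init(3L, fc, fc),
    smooth3 = conv_init(3L, fc, fc)
  )
  for (i in seq_len(config$head_depth)) {
    layers[[paste0("cls_trunk", i)]] <-
      conv_init(3L, if (i == 1L) fc else hc, hc)
    layers[[paste0("box_trunk", i)]] <-
      conv_init(3L, if (i == 1L) fc else hc, hc)
  }
  layers$out_joint <- conv_init(3L, hc, n_anchor * config$n_joint_classes,
                                bias_init = cls_bias)
  layers$out_erosion <- conv_init(3L, hc, n_anchor * config$n_erosion_classes,
                                  bias_init = cls_bias)
  layers$out_box <- conv_init(3L, hc, n_anchor * 4L)

  structure(list(config = config, layers = layers, n_anchor = n_anchor),
            class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  n_par <- sum(vapply(collect_params(x$layers), length, numeric(1)))
  cat(sprintf("<detector: %d x %d input, %d parameters, %d anchors/cell>\n",
              x$config$image_size, x$config$image_size, n_par, x$n_anchor))
  invisible(x)
}

# (A*C, H, W, N) head output -> (A*H*W, C, N) anchor-major logits matching
# generate_anchors() ordering (anchors contiguous per cell, cells row-fastest)
to_anchor_major <- function(y, n_classes, n_anchor) {
  d <- dim(y)
  hw <- d[2L] * d[3L]
  arr <- y
  dim(arr) <- c(n_classes, n_anchor, hw, d[4L])
  out <- aperm(arr, c(2L, 3L, 1L, 4L))
  dim(out) <- c(n_anchor * hw, n_classes, d[4L])
  out
}

from_anchor_major <- function(dlog, hw_dim, n_classes, n_anchor) {
  n <- dim(dlog)[3L]
  hw <- hw_dim[1L] * hw_dim[2L]
  arr <- dlog
  dim(arr) <- c(n_anchor, hw, n_classes, n)
  out <- aperm(arr, c(3L, 1L, 2L, 4L))
  dim(out) <- c(n_anchor * n_classes, hw_dim[1L], hw_dim[2L], n)
  out
}

res_block_forward <- function(layers, prefix, x, training, keep_ctx) {
  c1 <- conv_forward(layers[[paste0(prefix, "_conv1")]], x, keep_ctx)
  b1 <- bn_forward(layers[[paste0(prefix, "_bn1")]], c1$y, training)
  r1 <- relu_forward(b1$y)
  c2 <- conv_forward(layers[[paste0(prefix, "_conv2")]], r1$y, keep_ctx)
  b2 <- bn_forward(layers[[paste0(prefix, "_bn2")]], c2$y, training)
  sk <- conv_forward(layers[[paste0(prefix, "_skip")]], x, keep_ctx)
  sb <- bn_forward(layers[[paste0(prefix, "_skipbn")]], sk$y, training)
  out <- relu_forward(b2$y + sb$y)
  list(y = out$y,
       ctx = if (keep_ctx) list(c1 = c1$ctx, b1 = b1$ctx, r1 = r1$ctx,
                                c2 = c2$ctx, b2 = b2$ctx, sk = sk$ctx,
                                sb = sb$ctx, out = out$ctx),
       bn_updates = list(bn1 = b1[c("running_mean", "running_var")],
                         bn2 = b2[c("running_mean", "running_var")],
                         skipbn = sb[c("running_mean", "running_var")]))
}

res_block_backward <- function(layers, prefix, ctx, dy) {
  grads <- list()
  d <- relu_backward(ctx$out, dy)
  bb2 <- bn_backward(layers[[paste0(prefix, "_bn2")]], ctx$b2, d)
  grads[[paste0(prefix, "_bn2.gamma")]] <- bb2$dgamma
  grads[[paste0(prefix, "_bn2.beta")]] <- bb2$dbeta
  cb2 <- conv_backward(layers[[paste0(prefix, "_conv2")]], ctx$c2, bb2$dx)
  grads[[paste0(prefix, "_conv2.W")]] <- cb2$dW
  grads[[paste0(prefix, "_conv2.b")]] <- cb2$db
  dr1 <- relu_backward(ctx$r1, cb2$dx)
  bb1 <- bn_backward(layers[[paste0(prefix, "_bn1")]], ctx$b1, dr1)
  grads[[paste0(prefix, "_bn1.gamma")]] <- bb1$dgamma
  grads[[paste0(prefix, "_bn1.beta")]] <- bb1$dbeta
  cb1 <- conv_backward(layers[[paste0(prefix, "_conv1")]], ctx$c1, bb1$dx)
  grads[[paste0(prefix, "_conv1.W")]] <- cb1$dW
  grads[[paste0(prefix, "_conv1.b")]] <- cb1$db
  sb <- bn_backward(layers[[paste0(prefix, "_skipbn")]], ctx$sb, d)
  grads[[paste0(prefix, "_skipbn.gamma")]] <- sb$dgamma
  grads[[paste0(prefix, "_skipbn.beta")]] <- sb$dbeta
  sk <- conv_backward(layers[[paste0(prefix, "_skip")]], ctx$sk, sb$dx)
  grads[[paste0(prefix, "_skip.W")]] <- sk$dW
  grads[[paste0(prefix, "_skip.b")]] <- sk$db
  list(dx = cb1$dx + sk$dx, grads = grads)
}

head_forward <- function(model, f, training, keep_ctx) {
  layers <- model$layers
  cfg <- model$config
  ct <- f; cls_ctx <- list()
  for (i in seq_len(cfg$head_depth)) {
    cv <- conv_forward(layers[[paste0("cls_trunk", i)]], ct, keep_ctx)
    rl <- relu_forward(cv$y)
    cls_ctx[[i]] <- list(conv = cv$ctx, relu = rl$ctx)
    ct <- rl$y
  }
  bt <- f; box_ctx <- list()
  for (i in seq_len(cfg$head_depth)) {
    cv <- conv_forward(layers[[paste0("box_trunk", i)]], bt, keep_ctx)
    rl <- relu_forward(cv$y)
    box_ctx[[i]] <- list(conv = cv$ctx, relu = rl$ctx)
    bt <- rl$y
  }
  joint <- conv_forward(layers$out_joint, ct, keep_ctx)
  ero <- conv_forward(layers$out_erosion, ct, keep_ctx)
  box <- conv_forward(layers$out_box, bt, keep_ctx)
  hw <- dim(f)[2:3]
  list(
    joint = to_anchor_major(joint$y, cfg$n_joint_classes, model$n_anchor),
    erosion = to_anchor_major(ero$y, cfg$n_erosion_classes, model$n_anchor),
    box = to_anchor_major(box$y, 4L, model$n_anchor),
    ctx = if (keep_ctx) list(cls = cls_ctx, box = box_ctx,
                             out_joint = joint$ctx, out_erosion = ero$ctx,
                             out_box = box$ctx, hw = hw)
  )
}

head_backward <- function(model, ctx, d_joint, d_ero, d_box) {
  layers <- model$layers
  cfg <- model$config
  grads <- list()
  hw <- ctx$hw
  dj <- from_anchor_major(d_joint, hw, cfg$n_joint_classes, model$n_anchor)
  de <- from_anchor_major(d_ero, hw, cfg$n_erosion_classes, model$n_anchor)
  db <- from_anchor_major(d_box, hw, 4L, model$n_anchor)
  gj <- conv_backward(layers$out_joint, ctx$out_joint, dj)
  grads[["out_joint.W"]] <- gj$dW; grads[["out_joint.b"]] <- gj$db
  ge <- conv_backward(layers$out_erosion, ctx$out_erosion, de)
  grads[["out_erosion.W"]] <- ge$dW; grads[["out_erosion.b"]] <- ge$db
  gb <- conv_backward(layers$out_box, ctx$out_box, db)
  grads[["out_box.W"]] <- gb$dW; grads[["out_box.b"]] <- gb$db
  dct <- gj$dx + ge$dx
  for (i in rev(seq_len(cfg$head_depth))) {
    dct <- relu_backward(ctx$cls[[i]]$relu, dct)
    cv <- conv_backward(layers[[paste0("cls_trunk", i)]], ctx$cls[[i]]$conv, dct)
    grads[[paste0("cls_trunk", i, ".W")]] <- cv$dW
    grads[[paste0("cls_trunk", i, ".b")]] <- cv$db
    dct <- cv$dx
  }
  dbt <- gb$dx
  for (i in rev(seq_len(cfg$head_depth))) {
    dbt <- relu_backward(ctx$box[[i]]$relu, dbt)
    cv <- conv_backward(layers[[paste0("box_trunk", i)]], ctx$box[[i]]$conv, dbt)
    grads[[paste0("box_trunk", i, ".W")]] <- cv$dW
    grads[[paste0("box_trunk", i, ".b")]] <- cv$db
    dbt <- cv$dx
  }
  list(df = dct + dbt, grads = grads)
}

#' Run the detector forward
#'
#' @param model a [build_detector()] detector.
#' @param x input batch: array `(H, W, 1, N)` of z-scored images, a single
#'   `H x W` matrix, or the internal channel-first `(1, H, W, N)` layout.
#' @param training if `TRUE`, batch-norm uses batch statistics (and updates
#'   running statistics in the returned model) and the activations needed
#'   for the backward pass are cached.
#' @return list with `outputs` (per level: `joint`, `erosion`, `box` logits
#'   as `(n_anchors, n_classes, N)` arrays), `model` (running statistics
#'   possibly updated), and `ctx` (backward cache or `NULL`).
#' @export
detector_forward <- function(model, x, training = FALSE) {
  s <- model$config$image_size
  if (is.matrix(x)) {
    xx <- array(0, c(1L, nrow(x), ncol(x), 1L))
    xx[1L, , , 1L] <- x
    x <- xx
  } else if (length(dim(x)) == 4L && dim(x)[3L] == 1L && dim(x)[1L] != 1L) {
    x <- aperm(x, c(3L, 1L, 2L, 4L))   # (H, W, 1, N) -> channel-first
  }
  stopifnot(length(dim(x)) == 4L, dim(x)[1L] == 1L)
  if (dim(x)[2L] != s || dim(x)[3L] != s) {
    stop("input size does not match model_config image_size")
  }
  keep <- training
  layers <- model$layers

  st <- conv_forward(layers$stem, x, keep)
  sb <- bn_forward(layers$stem_bn, st$y, training)
  sr <- relu_forward(sb$y)
  r1 <- res_block_forward(layers, "b1", sr$y, training, keep)
  r2 <- res_block_forward(layers, "b2", r1$y, training, keep)
  l2 <- conv_forward(layers$lat2, r1$y, keep)
  l3 <- conv_forward(layers$lat3, r2$y, keep)
  td <- upsample2x_forward(l3$y)
  m2 <- l2$y + td
  p2 <- conv_forward(layers$smooth2, m2, keep)
  p3 <- conv_forward(layers$smooth3, l3$y, keep)
  h2 <- head_forward(model, p2$y, training, keep)
  h3 <- head_forward(model, p3$y, training, keep)

  if (training) {
    model$layers$stem_bn$running_mean <- sb$running_mean
    model$layers$stem_bn$running_var <- sb$running_var
    for (pre in c("b1", "b2")) {
      upd <- if (pre == "b1") r1$bn_updates else r2$bn_updates
      for (bn in names(upd)) {
        key <- paste0(pre, "_", bn)
        model$layers[[key]]$running_mean <- upd[[bn]]$running_mean
        model$layers[[key]]$running_var <- upd[[bn]]$running_var
      }
    }
  }
  outputs <- list(
    p2 = h2[c("joint", "erosion", "box")],
    p3 = h3[c("joint", "erosion", "box")]
  )
  ctx <- if (keep) list(stem = st$ctx, stem_bn = sb$ctx, stem_relu = sr$ctx,
                        b1 = r1$ctx, b2 = r2$ctx, lat2 = l2$ctx,
                        lat3 = l3$ctx, smooth2 = p2$ctx, smooth3 = p3$ctx,
                        head2 = h2$ctx, head3 = h3$ctx)
  list(outputs = outputs, model = model, ctx = ctx)
}

# d_outputs mirrors `outputs` of detector_forward; returns named gradients
detector_backward <- function(model, ctx, d_outputs) {
  layers <- model$layers
  hb2 <- head_backward(model, ctx$head2, d_outputs$p2$joint,
                       d_outputs$p2$erosion, d_outputs$p2$box)
  hb3 <- head_backward(model, ctx$head3, d_outputs$p3$joint,
                       d_outputs$p3$erosion, d_outputs$p3$box)
  grads <- add_grads(hb2$grads, hb3$grads)

  gs2 <- conv_backward(layers$smooth2, ctx$smooth2, hb2$df)
  grads[["smooth2.W"]] <- gs2$dW; grads[["smooth2.b"]] <- gs2$db
  gs3 <- conv_backward(layers$smooth3, ctx$smooth3, hb3$df)
  grads[["smooth3.W"]] <- gs3$dW; grads[["smooth3.b"]] <- gs3$db

  dl2 <- gs2$dx                       # gradient at lateral-2 output
  dl3 <- gs3$dx + upsample2x_backward(gs2$dx)
  gl2 <- conv_backward(layers$lat2, ctx$lat2, dl2)
  grads[["lat2.W"]] <- gl2$dW; grads[["lat2.b"]] <- gl2$db
  gl3 <- conv_backward(layers$lat3, ctx$lat3, dl3)
  grads[["lat3.W"]] <- gl3$dW; grads[["lat3.b"]] <- gl3$db

  rb2 <- res_block_backward(layers, "b2", ctx$b2, gl3$dx)
  grads <- add_grads(grads, rb2$grads)
  rb1 <- res_block_backward(layers, "b1", ctx$b1, rb2$dx + gl2$dx)
  grads <- add_grads(grads, rb1$grads)

  dsr <- relu_backward(ctx$stem_relu, rb1$dx)
  sbb <- bn_backward(layers$stem_bn, ctx$stem_bn, dsr)
  grads[["stem_bn.gamma"]] <- sbb$dgamma
  grads[["stem_bn.beta"]] <- sbb$dbeta
  stb <- conv_backward(layers$stem, ctx$stem, sbb$dx)
  grads[["stem.W"]] <- stb$dW; grads[["stem.b"]] <- stb$db
  grads
}
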