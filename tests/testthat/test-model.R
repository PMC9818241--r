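# a deliberately tiny detector used throughout: 40 x 40 input, p2 = 10 x 10,
# p3 = 5 x 5, one anchor shape per cell
tiny_model_config <- function() {
  model_config(image_size = 40L, backbone_channels = c(4L, 8L, 8L),
               fpn_channels = 8L, head_channels = 8L,
               anchor_scales = 1, anchor_ratios = 1)
}

test_that("forward output shapes follow the anchor lattice", {
  mcfg <- tiny_model_config()
  set.seed(71)
  model <- build_detector(mcfg)
  anchors <- model_anchors(mcfg)
  x <- array(rnorm(40 * 40 * 3), c(40, 40, 1, 3))
  fw <- detector_forward(model, x)
  expect_equal(dim(fw$outputs$p2$joint), c(nrow(anchors$p2$boxes), 32L, 3L))
  expect_equal(dim(fw$outputs$p2$erosion), c(nrow(anchors$p2$boxes), 6L, 3L))
  expect_equal(dim(fw$outputs$p3$box), c(nrow(anchors$p3$boxes), 4L, 3L))
  expect_true(all(vapply(fw$outputs, function(l) all(is.finite(unlist(l))),
                         logical(1))))
  # doubling the batch doubles the trailing dimension
  x6 <- array(rnorm(40 * 40 * 6), c(40, 40, 1, 6))
  expect_equal(dim(detector_forward(model, x6)$outputs$p2$joint)[3], 6L)
  expect_error(detector_forward(model, matrix(0, 48, 48)), "image_size")
})

test_that("evaluation-mode forward is deterministic and cache-free", {
  mcfg <- tiny_model_config()
  set.seed(72)
  model <- build_detector(mcfg)
  x <- array(rnorm(40 * 40 * 2), c(40, 40, 1, 2))
  f1 <- detector_forward(model, x, training = FALSE)
  f2 <- detector_forward(model, x, training = FALSE)
  expect_identical(f1$outputs, f2$outputs)
  expect_null(f1$ctx)
})

test_that("the end-to-end loss gradient matches finite differences", {
  mcfg <- tiny_model_config()
  set.seed(73)
  model <- build_detector(mcfg)
  anchors <- model_anchors(mcfg)
  ab <- rbind(anchors$p2$boxes, anchors$p3$boxes)
  nl <- c(nrow(anchors$p2$boxes), nrow(anchors$p3$boxes))
  gts <- joint_annotations(1:2, rbind(c(8, 8, 20, 20), c(24, 24, 36, 36)),
                           c(0L, 3L))
  m <- match_anchors(ab, gts, 0.3, 0.2)
  x <- array(rnorm(40 * 40), c(40, 40, 1, 1))
  lcfg <- loss_config()

  loss_at <- function(mod) {
    fw <- detector_forward(mod, x, training = TRUE)
    adaptanchor:::detector_loss(fw$outputs, list(m), lcfg, nl)$loss
  }
  fw <- detector_forward(model, x, training = TRUE)
  ls <- adaptanchor:::detector_loss(fw$outputs, list(m), lcfg, nl)
  grads <- adaptanchor:::detector_backward(model, fw$ctx, ls$d_outputs)

  eps <- 1e-5
  flat <- adaptanchor:::collect_params(model$layers)
  for (nm in c("stem.W", "b1_conv1.W", "b2_bn1.gamma", "lat2.W", "smooth3.b",
               "cls_trunk1.W", "out_erosion.b", "out_box.W", "b1_skip.W")) {
    k <- sample(length(flat[[nm]]), 1)
    for (sgn in c(1, -1)) {
      fl <- flat
      fl[[nm]][k] <- fl[[nm]][k] + sgn * eps
      mod <- model
      mod$layers <- adaptanchor:::assign_params(mod$layers, fl)
      if (sgn > 0) lp <- loss_at(mod) else lm <- loss_at(mod)
    }
    fd <- (lp - lm) / (2 * eps)
    expect_equal(grads[[nm]][k], fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("a batch with no usable anchors produces exactly zero loss", {
  mcfg <- tiny_model_config()
  set.seed(74)
  model <- build_detector(mcfg)
  anchors <- model_anchors(mcfg)
  nl <- c(nrow(anchors$p2$boxes), nrow(anchors$p3$boxes))
  x <- array(rnorm(40 * 40), c(40, 40, 1, 1))
  fw <- detector_forward(model, x, training = TRUE)
  # fabricate an all-ignore match: nothing contributes to any loss term
  m <- match_anchors(rbind(anchors$p2$boxes, anchors$p3$boxes),
                     joint_annotations(1L, c(4, 4, 12, 12), 1L), 0.1, 0.05)
  m$label[] <- "ignore"
  m$regression_target[] <- NA_real_
  ls <- adaptanchor:::detector_loss(fw$outputs, list(m), loss_config(), nl)
  expect_equal(ls$loss, 0)
  expect_equal(unname(ls$parts), c(0, 0, 0))
})

test_that("batch normalization tracks running statistics for eval mode", {
  set.seed(75)
  bn <- adaptanchor:::bn_init(3L)
  x <- array(rnorm(3 * 6 * 6 * 4, mean = 2, sd = 3), c(3, 6, 6, 4))
  out <- adaptanchor:::bn_forward(bn, x, training = TRUE)
  # batch-normalized output is standardized per channel
  y <- out$y
  expect_equal(as.numeric(adaptanchor:::channel_sums(y, 3L)) / (6 * 6 * 4),
               rep(0, 3), tolerance = 1e-9)
  bn$running_mean <- out$running_mean
  bn$running_var <- out$running_var
  ev <- adaptanchor:::bn_forward(bn, x, training = FALSE)
  expect_false(identical(ev$y, out$y))
  expect_true(all(is.finite(ev$y)))
})
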