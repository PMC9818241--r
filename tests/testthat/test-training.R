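tiny_setup <- function(seed = 90L, n_images = 2L) {
  gen <- generator_config(image_size = 40L, n_images = n_images,
                          joint_size_range = c(4, 8), noise_sd = 40,
                          seed = seed)
  items <- generate_dataset(gen)$items
  mcfg <- model_config(image_size = 40L, backbone_channels = c(4L, 8L, 8L),
                       fpn_channels = 8L, head_channels = 8L,
                       anchor_scales = 1, anchor_ratios = 1)
  list(items = items, mcfg = mcfg)
}

test_that("train_config validates its invariants", {
  expect_error(train_config(epochs = 10L,
                            schedule = adaptive_schedule(0.5, 0.4, 50L)),
               "adaptive_epochs")
  expect_error(train_config(epochs = 0L), "epochs")
  cfg <- train_config(epochs = 100L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$weight_decay, 1e-6)
  expect_equal(cfg$batch_size, 12L)
  expect_equal(cfg$oversample_factor, 4L)
  expect_equal(cfg$plateau_patience, 20L)
  expect_equal(cfg$plateau_factor, 0.1)
})

test_that("one epoch consumes oversample_factor passes over the data", {
  s <- tiny_setup(n_images = 3L)
  set.seed(91)
  model <- build_detector(s$mcfg)
  anchors <- model_anchors(s$mcfg)
  tcfg <- train_config(epochs = 4L, batch_size = 2L, oversample_factor = 4L,
                       schedule = adaptive_schedule(0.5, 0.4, 2L),
                       augment = NULL, seed = 91L)
  opt <- list(flat = adaptanchor:::collect_params(model$layers), lr = tcfg$lr)
  opt$state <- adaptanchor:::adam_init(opt$flat)
  ep <- run_epoch(model, s$items, 0L, tcfg, loss_config(), anchors, opt)
  expect_equal(ep$n_samples, 4L * 3L)
  expect_equal(ep$n_steps, 6L)
  expect_equal(unname(ep$thresholds), c(0, 0))   # ramp origin
  ep2 <- run_epoch(model, s$items, 2L, tcfg, loss_config(), anchors, opt)
  expect_equal(unname(ep2$thresholds), c(0.5, 0.4))  # clamped at end values
})

test_that("training history tracks the threshold schedule and best checkpoint", {
  s <- tiny_setup(n_images = 3L)
  splits <- list(train = s$items[1:2], validation = s$items[3])
  tcfg <- train_config(epochs = 4L, lr = 0.005, batch_size = 2L,
                       oversample_factor = 1L,
                       schedule = adaptive_schedule(0.5, 0.4, 2L),
                       augment = NULL, selection_metric = "accuracy",
                       seed = 92L)
  fit <- train(s$mcfg, tcfg, splits)
  h <- fit$history
  expect_equal(nrow(h), 4L)
  expect_equal(h$pos_iou, c(0, 0.25, 0.5, 0.5))
  expect_equal(h$neg_iou, c(0, 0.2, 0.4, 0.4))
  expect_true(all(is.finite(h$loss)))
  expect_s3_class(fit$checkpoint, "detector_checkpoint")
  # the kept checkpoint is the argmax of the selection metric
  expect_equal(max(h$val_accuracy),
               h$val_accuracy[fit$checkpoint$best_epoch + 1L])
  # adaptive positives shrink as thresholds rise on the same data
  expect_true(h$n_positive_mean[3] <= h$n_positive_mean[1])
})

test_that("training is reproducible under a fixed seed", {
  s <- tiny_setup(n_images = 3L)
  splits <- list(train = s$items[1:2], validation = s$items[3])
  tcfg <- train_config(epochs = 2L, batch_size = 2L, oversample_factor = 1L,
                       schedule = adaptive_schedule(0.5, 0.4, NULL),
                       seed = 93L)
  f1 <- train(s$mcfg, tcfg, splits)
  f2 <- train(s$mcfg, tcfg, splits)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-3)
})

test_that("the plateau rule divides the learning rate after stagnation", {
  s <- tiny_setup(n_images = 3L)
  splits <- list(train = s$items[1:2], validation = s$items[3])
  # an untrainable-in-3-epochs static run: validation mAP stays 0, so after
  # patience epochs without improvement the lr drops by the factor
  tcfg <- train_config(epochs = 5L, lr = 0.001, batch_size = 2L,
                       oversample_factor = 1L, plateau_patience = 1L,
                       plateau_cooldown = 10L, plateau_factor = 0.1,
                       schedule = adaptive_schedule(0.5, 0.4, NULL),
                       augment = NULL, seed = 94L)
  fit <- train(s$mcfg, tcfg, splits)
  expect_equal(fit$history$lr[5], 0.0001, tolerance = 1e-12)
})

test_that("a two-image overfit run collapses the training loss", {
  s <- tiny_setup(n_images = 2L)
  splits <- list(train = s$items, validation = s$items[1])
  tcfg <- train_config(epochs = 60L, lr = 0.005, batch_size = 2L,
                       oversample_factor = 1L,
                       schedule = adaptive_schedule(0.4, 0.3, 20L),
                       augment = NULL, seed = 95L)
  fit <- train(s$mcfg, tcfg, splits)
  h <- fit$history
  late <- mean(tail(h$loss, 5))
  expect_lt(late, 0.1 * h$loss[1])
})
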