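test_that("NMS keeps the strongest of overlapping boxes", {
  boxes <- rbind(c(0, 0, 10, 10), c(0.5, 0.5, 10.5, 10.5), c(50, 50, 60, 60))
  keep <- nms(boxes, c(0.9, 0.8, 0.7), iou_threshold = 0.5)
  expect_equal(keep, c(1L, 3L))
  # disjoint boxes all survive
  expect_length(nms(rbind(c(0, 0, 5, 5), c(20, 20, 25, 25)), c(0.5, 0.9)), 2L)
})

test_that("decoding thresholds, suppresses and caps detections", {
  anchors <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(40, 40, 50, 50))
  lg <- function(p) log(p / (1 - p))
  # one confident prediction, others below threshold -> passes through alone
  ero <- rbind(c(lg(0.9), rep(lg(0.01), 5)),
               c(lg(0.1), rep(lg(0.01), 5)),
               c(lg(0.2), rep(lg(0.01), 5)))
  joi <- matrix(lg(0.01), 3, 32); joi[, 4] <- lg(0.9)
  box <- matrix(0, 3, 4)
  d <- decode_detections(ero, joi, box, anchors, c(64, 64))
  expect_equal(nrow(d), 1L)
  expect_equal(d$erosion_score, 0L)
  expect_equal(d$joint_id, 4L)
  expect_equal(unlist(d[1, 1:4]), c(x_min = 0, y_min = 0, x_max = 10, y_max = 10))
  # two overlapping confident boxes -> NMS keeps the stronger
  ero2 <- rbind(c(lg(0.9), rep(lg(0.01), 5)),
                c(lg(0.8), rep(lg(0.01), 5)),
                c(lg(0.01), rep(lg(0.01), 5)))
  d2 <- decode_detections(ero2, joi, box, anchors, c(64, 64), nms_iou = 0.5)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$confidence, 0.9, tolerance = 1e-9)
  # all below threshold -> empty
  ero3 <- matrix(lg(0.05), 3, 6)
  expect_equal(nrow(decode_detections(ero3, joi, box, anchors, c(64, 64))), 0L)
})

test_that("the correct-detection rule requires location and exact score", {
  gt <- list(x_min = 0, y_min = 0, x_max = 10, y_max = 10, erosion_score = 2L)
  near <- list(x_min = 2, y_min = 0, x_max = 12, y_max = 10, erosion_score = 2L)
  expect_true(is_correct(near, gt))        # IoU = 8/12 >= 0.3, right score
  far <- list(x_min = 7, y_min = 7, x_max = 17, y_max = 17, erosion_score = 2L)
  expect_false(is_correct(far, gt))        # IoU 9/191 < 0.3
  wrong <- list(x_min = 0, y_min = 0, x_max = 10, y_max = 10, erosion_score = 3L)
  expect_false(is_correct(wrong, gt))      # perfect box, wrong score
})

perfect_detections <- function(gts, conf = 0.99) {
  data.frame(x_min = gts$x_min, y_min = gts$y_min, x_max = gts$x_max,
             y_max = gts$y_max, erosion_score = gts$erosion_score,
             joint_id = gts$joint_id, confidence = conf)
}

no_detections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), erosion_score = integer(0),
             joint_id = integer(0), confidence = numeric(0))
}

test_that("a perfect detector stub scores 1.0 everywhere", {
  gts <- toy_annotated_image(n_joints = 4L)$annotations
  rep <- score_detections(list(perfect_detections(gts)), list(gts))
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$map, 1)
  expect_equal(rep$mean_iou, 1)
  expect_equal(rep$conventional_ap, 1)
  present <- sort(unique(gts$erosion_score)) + 1L
  expect_equal(rep$confusion[present, present],
               diag(length(present)), ignore_attr = TRUE)
})

test_that("an empty detector stub scores 0 and fills the score-0 column", {
  gts <- toy_annotated_image(n_joints = 5L)$annotations
  gts$erosion_score <- c(1L, 2L, 3L, 4L, 5L)
  rep <- score_detections(list(no_detections()), list(gts))
  expect_equal(rep$accuracy, 0)
  expect_equal(rep$map, 0)
  expect_equal(rep$mean_iou, 0)
  expect_equal(unname(rep$confusion[2:6, 1]), rep(1, 5))  # missed -> predicted 0
})

test_that("accuracy counts correct detections over ground-truth joints", {
  gts <- joint_annotations(1:4, cbind((0:3) * 20, 0, (0:3) * 20 + 10, 10),
                           c(0L, 1L, 2L, 3L))
  dets <- perfect_detections(gts)
  dets$erosion_score[4] <- 5L                # one wrong score
  dets <- dets[-3, ]                         # one missed joint
  rep <- score_detections(list(dets), list(gts))
  expect_equal(rep$accuracy, 0.5)            # 2 of 4
  expect_equal(sum(rep$per_class_tp), 2)
  expect_equal(sum(rep$per_class_fp), 1)     # the wrong-score detection
})

test_that("per-class precision mAP follows the stated conventions", {
  tp <- stats::setNames(c(3, 1, 0, 0, 0, 0), 0:5)
  fp <- stats::setNames(c(1, 1, 0, 0, 0, 0), 0:5)
  expect_equal(map_eq3(tp, fp), 0.625)                   # (0.75 + 0.5) / 2
  # a GT class with zero detections drags the average down
  expect_equal(map_eq3(stats::setNames(c(4, 0, rep(0, 4)), 0:5),
                       stats::setNames(rep(0, 6), 0:5),
                       gt_classes = c(0, 1)), 0.5)
  # ... but classes absent from GT and detections are excluded
  expect_equal(map_eq3(stats::setNames(c(4, rep(0, 5)), 0:5),
                       stats::setNames(rep(0, 6), 0:5),
                       gt_classes = 0), 1)
  all_tp <- stats::setNames(rep(2, 6), 0:5)
  expect_equal(map_eq3(all_tp, stats::setNames(rep(0, 6), 0:5)), 1)
})

test_that("mean IoU averages matched pairs over all ground truths", {
  gts <- joint_annotations(1:2, rbind(c(0, 0, 10, 10), c(30, 30, 40, 40)),
                           c(0L, 0L))
  # one detection matched at IoU 0.6 (scores wrong so accuracy is 0), one missed
  d <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 6,
                  erosion_score = 5L, joint_id = 1L, confidence = 0.9)
  rep <- score_detections(list(d), list(gts))
  expect_equal(rep$mean_iou, 0.3)
  expect_equal(rep$accuracy, 0)
})

test_that("confusion matrix is row-normalized over true classes", {
  gts <- joint_annotations(1:6, cbind((0:5) * 20, 0, (0:5) * 20 + 10, 10), 0:5)
  dets <- perfect_detections(gts)
  dets$erosion_score <- rep(0L, 6)           # everything called score 0
  rep <- score_detections(list(dets), list(gts))
  expect_equal(unname(rep$confusion[, 1]), rep(1, 6))
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 6))
})

test_that("metrics are invariant to image and detection ordering", {
  set.seed(81)
  gts1 <- toy_annotated_image(n_joints = 4L, seed = 1L)$annotations
  gts2 <- toy_annotated_image(n_joints = 4L, seed = 2L)$annotations
  d1 <- perfect_detections(gts1); d1$erosion_score[1] <- 5L
  d2 <- perfect_detections(gts2)[-2, ]
  a <- score_detections(list(d1, d2), list(gts1, gts2))
  b <- score_detections(list(d2, d1), list(gts2, gts1))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$map, b$map)
  expect_equal(a$mean_iou, b$mean_iou)
  shuffled <- d1[sample(nrow(d1)), ]
  c2 <- score_detections(list(shuffled, d2), list(gts1, gts2))
  expect_equal(c2$accuracy, a$accuracy)
})

test_that("kendall tau handles the canonical rankings and bands", {
  expect_equal(kendall_tau(1:6, 1:6)$tau, 1)
  expect_equal(kendall_tau(1:6, 6:1)$tau, -1)
  r <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$tau, 4 / 6, tolerance = 1e-9)
  expect_equal(r$effect_band, "strong")
  expect_equal(kendall_tau(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))$effect_band,
               "medium")   # 7 concordant, 3 discordant -> tau = 0.4
  expect_equal(r$alpha_adjusted, 0.0083)
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(rep(1, 5), 1:5), "zero variance")
})

test_that("kendall tau matches an O(n^2) pair-counting oracle with ties", {
  set.seed(82)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(kendall_tau(x, y)$tau, pair_count_tau(x, y), tolerance = 1e-9)
  }
})

test_that("evaluate() on a trained-free detector returns a complete report", {
  mcfg <- model_config(image_size = 40L, backbone_channels = c(4L, 8L, 8L),
                       fpn_channels = 8L, head_channels = 8L,
                       anchor_scales = 1, anchor_ratios = 1)
  set.seed(83)
  model <- build_detector(mcfg)
  cfg <- generator_config(image_size = 40L, n_images = 2L,
                          joint_size_range = c(4, 8), noise_sd = 40, seed = 4L)
  items <- generate_dataset(cfg)$items
  rep <- evaluate(model, items)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_true(rep$map >= 0 && rep$map <= 1)
  expect_true(rep$mean_iou >= 0 && rep$mean_iou <= 1)
  expect_equal(nrow(rep$per_image), 2L)
  # self-consistency: aggregate equals mean of per-image records
  expect_equal(rep$accuracy, mean(rep$per_image$accuracy), tolerance = 1e-12)
  expect_equal(rep$mean_iou, mean(rep$per_image$mean_iou), tolerance = 1e-12)
})
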