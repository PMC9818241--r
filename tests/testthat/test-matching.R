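test_that("anchor lattices have the right counts, centers and spacing", {
  a <- generate_anchors(c(2L, 2L), "p2", scales = 1, ratios = 1)
  expect_equal(nrow(a$boxes), 4L)
  cx <- (a$boxes[, 1] + a$boxes[, 3]) / 2
  cy <- (a$boxes[, 2] + a$boxes[, 4]) / 2
  expect_setequal(cx, c(2, 6))     # stride 4, cell centers
  expect_setequal(cy, c(2, 6))
  expect_equal(sort(unique(diff(sort(unique(cx))))), 4)

  b <- generate_anchors(c(100L, 100L), "p2",
                        scales = 2^(c(0, 1, 2) / 3), ratios = c(0.5, 1, 2))
  expect_equal(nrow(b$boxes), 90000L)
  expect_true(all((b$boxes[, 3] - b$boxes[, 1]) > 0))
  p3 <- generate_anchors(c(10L, 10L), "p3", scales = 1, ratios = 1)
  expect_equal(p3$stride, 8L)
  expect_equal(unique((p3$boxes[, 3] + p3$boxes[, 1]) / 2)[1:2], c(4, 12))
  expect_error(generate_anchors(c(0L, 5L), "p2"), "positive")
})

test_that("threshold schedules ramp linearly and clamp at their end values", {
  s50 <- adaptive_schedule(0.5, 0.4, 50L)
  expect_equal(current_thresholds(s50, 50L), c(pos_iou = 0.5, neg_iou = 0.4))
  expect_equal(current_thresholds(s50, 0L), c(pos_iou = 0, neg_iou = 0))
  expect_equal(current_thresholds(s50, 500L), c(pos_iou = 0.5, neg_iou = 0.4))
  s100 <- adaptive_schedule(0.4, 0.3, 100L)
  expect_equal(current_thresholds(s100, 25L), c(pos_iou = 0.1, neg_iou = 0.075))
  static <- adaptive_schedule(0.5, 0.4, NULL)
  for (e in c(0L, 10L, 99L)) {
    expect_equal(current_thresholds(static, e), c(pos_iou = 0.5, neg_iou = 0.4))
  }
  # monotone nondecreasing, pos >= neg, continuous up to integer sampling
  th <- t(vapply(0:60, function(e) current_thresholds(s50, e), numeric(2)))
  expect_true(all(diff(th[, 1]) >= 0) && all(diff(th[, 2]) >= 0))
  expect_true(all(th[, 1] >= th[, 2]))
  expect_true(all(abs(diff(th[1:51, 1]) - 0.5 / 50) < 1e-12))
  expect_error(current_thresholds(s50, -1L), "nonnegative")
  expect_error(adaptive_schedule(0.3, 0.4, 50L), "end_neg_iou")
})

test_that("the geometric ramp is slower early but hits the same endpoint", {
  g <- adaptive_schedule(0.5, 0.4, 50L, ramp = "geometric")
  l <- adaptive_schedule(0.5, 0.4, 50L, ramp = "linear")
  expect_lt(current_thresholds(g, 25L)[["pos_iou"]],
            current_thresholds(l, 25L)[["pos_iou"]])
  expect_equal(current_thresholds(g, 50L), current_thresholds(l, 50L))
})

test_that("anchors are labeled positive/ignore/negative by their best IoU", {
  gt <- joint_annotations(1L, c(0, 0, 100, 100), 2L)
  anchors <- rbind(
    c(0, 0, 100, 60),   # IoU 0.6
    c(0, 0, 100, 45),   # IoU 0.45
    c(0, 0, 100, 30),   # IoU 0.30
    c(500, 500, 600, 600)  # IoU 0
  )
  m <- match_anchors(anchors, gt, 0.5, 0.4)
  expect_equal(as.character(m$label),
               c("positive", "ignore", "negative", "negative"))
  expect_equal(m$matched_gt[1], 1L)
  expect_equal(m$erosion_score[1], 2L)
  expect_equal(m$joint_id[1], 1L)
  # encoded regression target decodes back to the ground-truth box
  dec <- decode_boxes(anchors[1, , drop = FALSE],
                      m$regression_target[1, , drop = FALSE])
  expect_equal(unname(dec), unname(as_box_matrix(c(0, 0, 100, 100))),
               tolerance = 1e-9)

  # ramped-down thresholds make all overlapping anchors positive
  m2 <- match_anchors(anchors, gt, 0.25, 0.20)
  expect_equal(as.character(m2$label),
               c("positive", "positive", "positive", "negative"))
  expect_error(match_anchors(anchors, gt, 0.3, 0.4), "pos_iou")
})

test_that("matcher agrees with a brute-force oracle on random scenes", {
  set.seed(51)
  for (rep in 1:10) {
    anchors <- t(replicate(40, random_int_box(max_coord = 30, max_side = 12)))
    n_gt <- sample(1:4, 1)
    gts <- joint_annotations(
      seq_len(n_gt),
      t(replicate(n_gt, random_int_box(max_coord = 30, max_side = 12))),
      sample(0:5, n_gt, replace = TRUE)
    )
    thr <- sort(runif(2, 0, 0.6))
    m <- match_anchors(anchors, gts, thr[2], thr[1])
    expect_equal(as.character(m$label),
                 brute_force_match(as_box_matrix(anchors), gts, thr[2], thr[1]))
  }
})

test_that("positive-anchor count is monotone nonincreasing in pos_iou", {
  set.seed(52)
  anchors <- t(replicate(120, random_int_box(max_coord = 40, max_side = 14)))
  gts <- joint_annotations(1:5,
                           t(replicate(5, random_int_box(max_coord = 40, max_side = 14))),
                           sample(0:5, 5, replace = TRUE))
  counts <- vapply(seq(0.05, 0.95, by = 0.05), function(p) {
    sum(match_anchors(anchors, gts, p, min(p, 0.2))$label == "positive")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("best-anchor fallback keeps every overlapped object supervised", {
  set.seed(53)
  # small objects against the default-scale anchor lattice: none reaches 0.5
  anchors <- generate_anchors(c(24L, 24L), "p2")
  boxes <- cbind(10 + (0:5) * 12, 30, 16 + (0:5) * 12, 36)   # 6 px objects
  gts <- joint_annotations(1:6, boxes, rep(0L, 6))
  io <- iou_matrix(anchors$boxes, annotation_boxes(gts))
  expect_lt(max(io), 0.5)           # no threshold positives exist at 0.5
  m <- match_anchors(anchors, gts, 0.5, 0.4)
  got <- unique(m$matched_gt[m$label == "positive"])
  expect_setequal(got, 1:6)          # fallback still covers every object
  # under a ramped-down threshold every object has many positives
  m0 <- match_anchors(anchors, gts, 0.05, 0.04)
  expect_gt(sum(m0$label == "positive"), 6)
})
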