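# Independent brute-force oracles used to pin down the closed-form metrics.

# IoU by counting integer lattice pixels under the half-open convention:
# a box (x1, y1, x2, y2) with integer corners covers pixels x1..x2-1, y1..y2-1.
pixel_grid_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(a) + area(b) - inter)
}

random_int_box <- function(max_coord = 20L, max_side = 10L) {
  x1 <- sample.int(max_coord, 1L) - 1L
  y1 <- sample.int(max_coord, 1L) - 1L
  c(x1, y1, x1 + sample.int(max_side, 1L), y1 + sample.int(max_side, 1L))
}

# O(n^2) pair-counting Kendall tau-b with tie correction
pair_count_tau <- function(x, y) {
  n <- length(x)
  nc <- nd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  (nc - nd) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# Literal per-anchor matcher following the assignment rule, no vectorization
brute_force_match <- function(anchor_boxes, gts, pos_iou, neg_iou) {
  n <- nrow(anchor_boxes)
  gt_boxes <- as.matrix(gts[, c("x_min", "y_min", "x_max", "y_max")])
  label <- character(n)
  for (i in seq_len(n)) {
    ious <- vapply(seq_len(nrow(gt_boxes)), function(g) {
      iou(anchor_boxes[i, ], gt_boxes[g, ])
    }, numeric(1))
    best <- max(ious)
    label[i] <- if (best == 0) "negative"
      else if (best >= pos_iou) "positive"
      else if (best < neg_iou) "negative"
      else "ignore"
  }
  # best-anchor fallback
  for (g in seq_len(nrow(gt_boxes))) {
    ious <- vapply(seq_len(n), function(i) iou(anchor_boxes[i, ], gt_boxes[g, ]),
                   numeric(1))
    if (max(ious) > 0) label[which.max(ious)] <- "positive"
  }
  label
}

# small deterministic annotated image for I/O and geometry tests
toy_annotated_image <- function(size = 64L, n_joints = 4L, seed = 99L) {
  set.seed(seed)
  px <- matrix(runif(size * size, 0, 4096), size, size)
  step <- size / (n_joints + 1)
  centers <- step * seq_len(n_joints)
  boxes <- cbind(centers - 5, centers - 5, centers + 5, centers + 5)
  annotated_image(
    radiograph_image(px, source_id = "toy"),
    joint_annotations(seq_len(n_joints), boxes,
                      erosion_score = (seq_len(n_joints) - 1L) %% 6L),
    image_path = "toy.tiff", patient_id = "toy-patient"
  )
}
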