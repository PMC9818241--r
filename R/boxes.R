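#' Bounding-box utilities
#'
#' Boxes are numeric matrices with four columns `x_min, y_min, x_max, y_max`
#' in 0-based pixel coordinates (x rightward, y downward). Boxes are
#' half-open: a box covers the pixel lattice points `x_min <= x < x_max`,
#' `y_min <= y < y_max`, and its area is
#' `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param boxes numeric matrix (or coercible) with 4 columns.
#' @return a validated numeric matrix with the canonical column names.
#' @export
as_box_matrix <- function(boxes) {
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4L, byrow = TRUE)
  boxes <- as.matrix(boxes)
  storage.mode(boxes) <- "double"
  if (ncol(boxes) != 4L) stop("boxes must have 4 columns (x_min, y_min, x_max, y_max)")
  colnames(boxes) <- c("x_min", "y_min", "x_max", "y_max")
  if (any(!is.finite(boxes))) stop("boxes must be finite")
  boxes
}

box_widths <- function(boxes) boxes[, 3L] - boxes[, 1L]
box_heights <- function(boxes) boxes[, 4L] - boxes[, 2L]
box_areas <- function(boxes) box_widths(boxes) * box_heights(boxes)

stopifnot_valid_boxes <- function(boxes) {
  if (any(box_widths(boxes) <= 0) || any(box_heights(boxes) <= 0)) {
    stop("degenerate box: x_min < x_max and y_min < y_max required")
  }
  invisible(boxes)
}

#' Intersection over union of two boxes
#'
#' IoU = area of overlap / area of union under the half-open corner
#' convention. Disjoint boxes score 0; identical boxes score 1.
#'
#' @param box_a,box_b length-4 numeric vectors `(x_min, y_min, x_max, y_max)`.
#' @return a fraction in `[0, 1]`.
#' @export
iou <- function(box_a, box_b) {
  a <- as_box_matrix(box_a)
  b <- as_box_matrix(box_b)
  if (nrow(a) != 1L || nrow(b) != 1L) stop("iou() takes single boxes; see iou_matrix()")
  stopifnot_valid_boxes(a)
  stopifnot_valid_boxes(b)
  drop(iou_matrix(a, b))
}

#' Pairwise IoU matrix
#'
#' @param boxes_a n x 4 matrix; @param boxes_b m x 4 matrix.
#' @return n x m matrix of IoU values.
#' @export
iou_matrix <- function(boxes_a, boxes_b) {
  a <- as_box_matrix(boxes_a)
  b <- as_box_matrix(boxes_b)
  if (any(box_areas(a) <= 0) || any(box_areas(b) <= 0)) {
    stop("zero-area box passed to IoU")
  }
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1L], n, m), matrix(b[, 1L], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2L], n, m), matrix(b[, 2L], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3L], n, m), matrix(b[, 3L], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4L], n, m), matrix(b[, 4L], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  union <- outer(box_areas(a), box_areas(b), "+") - inter
  inter / union
}

#' Clip boxes to image bounds
#'
#' @param boxes n x 4 box matrix.
#' @param image_size `(height, width)` in pixels.
#' @return clipped box matrix (rows may become degenerate; callers filter).
#' @export
clip_boxes <- function(boxes, image_size) {
  b <- as_box_matrix(boxes)
  h <- image_size[1L]; w <- image_size[2L]
  b[, 1L] <- pmin(pmax(b[, 1L], 0), w)
  b[, 3L] <- pmin(pmax(b[, 3L], 0), w)
  b[, 2L] <- pmin(pmax(b[, 2L], 0), h)
  b[, 4L] <- pmin(pmax(b[, 4L], 0), h)
  b
}

#' Encode ground-truth boxes as anchor-relative regression targets
#'
#' Standard parameterization: `(dx, dy, dw, dh)` with
#' `dx = (cx_gt - cx_a) / w_a`, `dy = (cy_gt - cy_a) / h_a`,
#' `dw = log(w_gt / w_a)`, `dh = log(h_gt / h_a)`.
#'
#' @param anchors,gt_boxes matched n x 4 box matrices (row i of `gt_boxes`
#'   is the target for anchor row i).
#' @return n x 4 matrix of offsets.
#' @export
encode_boxes <- function(anchors, gt_boxes) {
  a <- as_box_matrix(anchors); g <- as_box_matrix(gt_boxes)
  if (nrow(a) != nrow(g)) stop("anchors and gt_boxes must be matched row-wise")
  wa <- box_widths(a); ha <- box_heights(a)
  wg <- box_widths(g); hg <- box_heights(g)
  cbind(
    dx = ((g[, 1L] + g[, 3L]) - (a[, 1L] + a[, 3L])) / (2 * wa),
    dy = ((g[, 2L] + g[, 4L]) - (a[, 2L] + a[, 4L])) / (2 * ha),
    dw = log(wg / wa),
    dh = log(hg / ha)
  )
}

#' Decode anchor-relative offsets back to corner boxes
#'
#' Inverse of [encode_boxes()].
#'
#' @param anchors n x 4 anchor matrix; @param deltas n x 4 offset matrix.
#' @return n x 4 box matrix.
#' @export
decode_boxes <- function(anchors, deltas) {
  a <- as_box_matrix(anchors)
  d <- as.matrix(deltas)
  wa <- box_widths(a); ha <- box_heights(a)
  cx <- (a[, 1L] + a[, 3L]) / 2 + d[, 1L] * wa
  cy <- (a[, 2L] + a[, 4L]) / 2 + d[, 2L] * ha
  # cap the log-scale terms so a wild early-training prediction cannot
  # produce Inf-sized boxes
  w <- wa * exp(pmin(d[, 3L], 6))
  h <- ha * exp(pmin(d[, 4L], 6))
  as_box_matrix(cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2))
}
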