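#' Generate an anchor lattice for one pyramid level
#'
#' One anchor group per feature-map cell, centered on the cell center in
#' input-image coordinates. Defaults cover 8-24 px objects at 400 x 400:
#' base size 16 at p2 (stride 4) and 32 at p3 (stride 8), scales
#' `2^(0, 1/3, 2/3)` and aspect ratios 0.5/1/2.
#'
#' @param feature_shape `(height, width)` of the level's feature map.
#' @param level `"p2"` or `"p3"`.
#' @param scales multiplicative size scales.
#' @param ratios aspect ratios (height / width).
#' @param base_size anchor side at scale 1; default 4 x stride.
#' @return an object of class `anchor_set`: list with `boxes` (n x 4
#'   matrix), `level`, `stride`, `scales`, `ratios`, `feature_shape`.
#' @export
generate_anchors <- function(feature_shape, level = c("p2", "p3"),
                             scales = 2^(c(0, 1, 2) / 3),
                             ratios = c(0.5, 1, 2),
                             base_size = NULL) {
  level <- match.arg(level)
  fh <- as.integer(feature_shape[1L]); fw <- as.integer(feature_shape[2L])
  if (fh < 1L || fw < 1L) stop("feature_shape must be positive")
  stride <- if (level == "p2") 4L else 8L
  if (is.null(base_size)) base_size <- 4 * stride

  # per-cell anchor shapes: area = (base * scale)^2, aspect = h / w
  shapes <- expand.grid(scale = scales, ratio = ratios)
  ws <- base_size * shapes$scale / sqrt(shapes$ratio)
  hs <- base_size * shapes$scale * sqrt(shapes$ratio)

  cx <- (rep(seq_len(fw), each = fh) - 0.5) * stride
  cy <- (rep(seq_len(fh), times = fw) - 0.5) * stride
  k <- length(ws)
  n_cells <- fh * fw
  cxr <- rep(cx, each = k); cyr <- rep(cy, each = k)
  wr <- rep(ws, times = n_cells); hr <- rep(hs, times = n_cells)
  boxes <- cbind(cxr - wr / 2, cyr - hr / 2, cxr + wr / 2, cyr + hr / 2)
  structure(
    list(boxes = as_box_matrix(boxes), level = level, stride = stride,
         scales = scales, ratios = ratios, feature_shape = c(fh, fw)),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set %s: %d anchors (%d x %d cells, stride %d, %d per cell)>\n",
              x$level, nrow(x$boxes), x$feature_shape[1L], x$feature_shape[2L],
              x$stride, length(x$scales) * length(x$ratios)))
  invisible(x)
}

#' Adaptive IoU-threshold schedule
#'
#' During anchor assignment, anchors are labeled positive above `pos_iou`
#' and negative below `neg_iou`. With a static schedule those thresholds
#' are fixed for the whole training; small objects then overlap almost no
#' anchor above a high positive threshold, negatives predominate, and the
#' loss is trivially minimized by predicting background everywhere. The
#' adaptive schedule instead ramps both thresholds from 0 at epoch 0 up to
#' their end values at `adaptive_epochs`, clamping there for the rest of
#' training: early epochs hand the detector abundant positives, later
#' epochs tighten localization.
#'
#' @param end_pos_iou,end_neg_iou end (maximum) thresholds, with
#'   `0 <= end_neg_iou < end_pos_iou <= 1`.
#' @param adaptive_epochs integer ramp length in epochs, or `NULL`/`NA` for
#'   a static schedule.
#' @param ramp `"linear"` (default) or `"geometric"` shape of the ramp.
#' @return an object of class `adaptive_schedule` with fields
#'   `end_pos_iou`, `end_neg_iou`, `delta` (their gap), `adaptive_epochs`,
#'   `ramp`.
#' @export
adaptive_schedule <- function(end_pos_iou, end_neg_iou, adaptive_epochs = NULL,
                              ramp = c("linear", "geometric")) {
  if (!(end_neg_iou >= 0 && end_neg_iou < end_pos_iou && end_pos_iou <= 1)) {
    stop("need 0 <= end_neg_iou < end_pos_iou <= 1")
  }
  if (length(adaptive_epochs) && is.na(adaptive_epochs)) adaptive_epochs <- NULL
  if (!is.null(adaptive_epochs)) {
    adaptive_epochs <- as.integer(adaptive_epochs)
    if (adaptive_epochs < 1L) stop("adaptive_epochs must be a positive integer")
  }
  structure(
    list(end_pos_iou = end_pos_iou, end_neg_iou = end_neg_iou,
         delta = end_pos_iou - end_neg_iou,
         adaptive_epochs = adaptive_epochs, ramp = match.arg(ramp)),
    class = "adaptive_schedule"
  )
}

#' @export
print.adaptive_schedule <- function(x, ...) {
  mode <- if (is.null(x$adaptive_epochs)) "static" else
    sprintf("adaptive over %d epochs (%s ramp)", x$adaptive_epochs, x$ramp)
  cat(sprintf("<adaptive_schedule %.2f/%.2f, %s>\n",
              x$end_pos_iou, x$end_neg_iou, mode))
  invisible(x)
}

#' Thresholds in force at a given epoch
#'
#' Static schedules return the end thresholds at every epoch. Adaptive
#' schedules return `end * epoch / adaptive_epochs` (linear ramp; the
#' geometric ramp uses `end * (epoch / adaptive_epochs)^2`), clamped at the
#' end values from `epoch >= adaptive_epochs` on. Both thresholds ramp with
#' the same profile, so their gap keeps its shape; the positive threshold
#' never falls below the negative one.
#'
#' @param schedule an [adaptive_schedule()].
#' @param current_epoch nonnegative integer (0 = first epoch).
#' @return named numeric vector `c(pos_iou, neg_iou)`.
#' @export
current_thresholds <- function(schedule, current_epoch) {
  stopifnot(inherits(schedule, "adaptive_schedule"))
  if (current_epoch < 0) stop("current_epoch must be nonnegative")
  if (is.null(schedule$adaptive_epochs)) {
    return(c(pos_iou = schedule$end_pos_iou, neg_iou = schedule$end_neg_iou))
  }
  frac <- min(current_epoch / schedule$adaptive_epochs, 1)
  if (schedule$ramp == "geometric") frac <- frac^2
  c(pos_iou = schedule$end_pos_iou * frac,
    neg_iou = schedule$end_neg_iou * frac)
}

#' Assign anchors to ground-truth joints by IoU thresholds
#'
#' Each anchor takes its best-IoU ground truth: label positive if that IoU
#' is at least `pos_iou` (and strictly positive), negative if below
#' `neg_iou`, ignore otherwise. Additionally each ground truth's single
#' highest-IoU anchor is forced positive whenever the overlap is nonzero
#' (best-anchor fallback), so no overlapped object is left entirely
#' unsupervised even under a high static threshold. Positives carry encoded
#' regression targets and both classification targets.
#'
#' @param anchors an [anchor_set()][generate_anchors] or plain n x 4 box
#'   matrix.
#' @param gts a [joint_annotations()] data frame.
#' @param pos_iou,neg_iou thresholds with `pos_iou >= neg_iou`.
#' @return an object of class `match_result`: list with `label` (factor
#'   positive/negative/ignore per anchor), `matched_gt` (index or NA),
#'   `regression_target` (n x 4, NA for non-positives), `joint_id`,
#'   `erosion_score` (per-anchor targets, NA for non-positives),
#'   `best_iou`.
#' @export
match_anchors <- function(anchors, gts, pos_iou, neg_iou) {
  if (pos_iou < neg_iou) stop("pos_iou must be >= neg_iou")
  boxes <- if (inherits(anchors, "anchor_set")) anchors$boxes else as_box_matrix(anchors)
  n <- nrow(boxes)
  gts <- validate_annotations(gts)
  m <- nrow(gts)

  label <- rep("negative", n)
  matched <- rep(NA_integer_, n)
  best_iou <- rep(0, n)
  if (m > 0L) {
    io <- iou_matrix(boxes, annotation_boxes(gts))
    best <- max.col(io, ties.method = "first")
    best_iou <- io[cbind(seq_len(n), best)]
    matched <- ifelse(best_iou > 0, best, NA_integer_)
    label[best_iou >= neg_iou] <- "ignore"
    label[best_iou >= pos_iou & best_iou > 0] <- "positive"
    label[best_iou == 0] <- "negative"
    # best-anchor fallback: every overlapped GT keeps at least one positive
    for (g in seq_len(m)) {
      top <- which.max(io[, g])
      if (io[top, g] > 0) {
        label[top] <- "positive"
        matched[top] <- g
        best_iou[top] <- io[top, g]
      }
    }
  }
  pos <- which(label == "positive")
  reg <- matrix(NA_real_, n, 4L)
  joint_id <- rep(NA_integer_, n)
  erosion <- rep(NA_integer_, n)
  if (length(pos)) {
    gt_idx <- matched[pos]
    reg[pos, ] <- encode_boxes(boxes[pos, , drop = FALSE],
                               annotation_boxes(gts)[gt_idx, , drop = FALSE])
    joint_id[pos] <- gts$joint_id[gt_idx]
    erosion[pos] <- gts$erosion_score[gt_idx]
  }
  structure(
    list(label = factor(label, levels = c("positive", "negative", "ignore")),
         matched_gt = matched, regression_target = reg,
         joint_id = joint_id, erosion_score = erosion, best_iou = best_iou,
         pos_iou = pos_iou, neg_iou = neg_iou),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<match_result @ %.3f/%.3f: %d positive, %d negative, %d ignore>\n",
              x$pos_iou, x$neg_iou, tab[["positive"]], tab[["negative"]],
              tab[["ignore"]]))
  invisible(x)
}
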