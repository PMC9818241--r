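#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 box matrix.
#' @param scores length-n confidences.
#' @param iou_threshold suppression threshold.
#' @return integer indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  boxes <- as_box_matrix(boxes)
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (!length(ord)) break
    ious <- iou_matrix(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])
    ord <- ord[ious[1L, ] <= iou_threshold]
  }
  keep
}

#' Decode raw detector outputs into detections for one image
#'
#' Applies the predicted box offsets to the anchors, converts logits to
#' sigmoid probabilities (detection confidence = the erosion head's best
#' class probability), drops low-confidence anchors, runs class-agnostic
#' NMS, and keeps the `top_k` strongest detections.
#'
#' @param erosion_logits,joint_logits,box_deltas `(n_anchors, n_classes)`
#'   matrices for one image.
#' @param anchor_boxes n_anchors x 4 matrix (levels concatenated).
#' @param image_size `(height, width)` for box clipping.
#' @param score_threshold minimum confidence (default 0.3).
#' @param nms_iou NMS threshold (default 0.5).
#' @param top_k maximum detections kept per image (default 64).
#' @return data frame of detections: box corners, `erosion_score`,
#'   `joint_id`, `confidence`.
#' @export
decode_detections <- function(erosion_logits, joint_logits, box_deltas,
                              anchor_boxes, image_size,
                              score_threshold = 0.3, nms_iou = 0.5,
                              top_k = 64L) {
  p_ero <- 1 / (1 + exp(-erosion_logits))
  conf <- apply(p_ero, 1L, max)
  cand <- which(conf >= score_threshold)
  empty <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      erosion_score = integer(0), joint_id = integer(0),
                      confidence = numeric(0))
  if (!length(cand)) return(empty)
  boxes <- decode_boxes(anchor_boxes[cand, , drop = FALSE],
                        box_deltas[cand, , drop = FALSE])
  boxes <- clip_boxes(boxes, image_size)
  ok <- box_widths(boxes) > 1e-6 & box_heights(boxes) > 1e-6
  cand <- cand[ok]; boxes <- boxes[ok, , drop = FALSE]
  if (!length(cand)) return(empty)
  keep <- nms(boxes, conf[cand], nms_iou)
  keep <- keep[seq_len(min(length(keep), top_k))]
  sel <- cand[keep]
  data.frame(
    x_min = boxes[keep, 1L], y_min = boxes[keep, 2L],
    x_max = boxes[keep, 3L], y_max = boxes[keep, 4L],
    erosion_score = max.col(p_ero[sel, , drop = FALSE]) - 1L,
    joint_id = max.col(1 / (1 + exp(-joint_logits[sel, , drop = FALSE]))),
    confidence = conf[sel]
  )
}

#' Correct-detection rule
#'
#' A detection is correct iff it overlaps its ground-truth box with
#' IoU >= 0.3 and predicts exactly the ground-truth erosion score. Joint
#' identity does not enter the rule.
#'
#' @param detection list or one-row data frame with `x_min..y_max` and
#'   `erosion_score`.
#' @param gt same fields for the ground-truth joint.
#' @param iou_threshold location threshold (default 0.3).
#' @return logical.
#' @export
is_correct <- function(detection, gt, iou_threshold = 0.3) {
  ov <- iou(c(detection$x_min, detection$y_min, detection$x_max, detection$y_max),
            c(gt$x_min, gt$y_min, gt$x_max, gt$y_max))
  ov >= iou_threshold && detection$erosion_score == gt$erosion_score
}

# Greedy one-to-one matching of detections to ground truths: detections in
# descending confidence order each claim the unmatched GT with the highest
# (positive) IoU. Returns per-detection matched GT index (NA if none) and
# the pair IoU.
greedy_match <- function(det_boxes, det_conf, gt_boxes) {
  n_det <- nrow(det_boxes); n_gt <- nrow(gt_boxes)
  match_gt <- rep(NA_integer_, n_det)
  match_iou <- rep(0, n_det)
  if (n_det == 0L || n_gt == 0L) return(list(gt = match_gt, iou = match_iou))
  io <- iou_matrix(det_boxes, gt_boxes)
  taken <- rep(FALSE, n_gt)
  for (d in order(det_conf, decreasing = TRUE)) {
    avail <- which(!taken & io[d, ] > 0)
    if (!length(avail)) next
    g <- avail[which.max(io[d, avail])]
    match_gt[d] <- g
    match_iou[d] <- io[d, g]
    taken[g] <- TRUE
  }
  list(gt = match_gt, iou = match_iou)
}

#' Per-class-precision mAP
#'
#' Mean over erosion-score classes of `TP_c / (TP_c + FP_c)`. A class with
#' no detections contributes 0 to the average when it occurs in the ground
#' truth and is excluded from the average otherwise. (This is per-class
#' precision averaged over classes, not the ranked precision-recall COCO
#' metric; see [conventional_ap()] for that.)
#'
#' @param per_class_tp,per_class_fp named nonnegative counts per class.
#' @param gt_classes character/integer vector of classes present in the
#'   ground truth (defaults to classes with any count).
#' @return fraction in `[0, 1]`.
#' @export
map_eq3 <- function(per_class_tp, per_class_fp,
                    gt_classes = names(which(per_class_tp + per_class_fp > 0))) {
  stopifnot(all(per_class_tp >= 0), all(per_class_fp >= 0),
            identical(names(per_class_tp), names(per_class_fp)))
  denom <- per_class_tp + per_class_fp
  include <- denom > 0 | names(per_class_tp) %in% as.character(gt_classes)
  if (!any(include)) return(0)
  prec <- ifelse(denom[include] > 0, per_class_tp[include] / denom[include], 0)
  mean(prec)
}

#' Ranked-PR average precision (conventional AP)
#'
#' The standard all-point interpolated average precision per class,
#' averaged over classes present in the ground truth. Provided for
#' comparison with the per-class precision metric [map_eq3()].
#'
#' @param records data frame with columns `confidence`, `tp` (logical) and
#'   `class`, one row per detection.
#' @param n_gt_per_class named counts of ground-truth instances per class.
#' @return fraction in `[0, 1]`.
#' @export
conventional_ap <- function(records, n_gt_per_class) {
  classes <- names(n_gt_per_class)[n_gt_per_class > 0]
  if (!length(classes)) return(0)
  aps <- vapply(classes, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    if (!nrow(r)) return(0)
    r <- r[order(r$confidence, decreasing = TRUE), , drop = FALSE]
    tp_cum <- cumsum(r$tp)
    prec <- tp_cum / seq_len(nrow(r))
    rec <- tp_cum / n_gt_per_class[[cl]]
    # all-point interpolation
    prec <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * prec)
  }, numeric(1))
  mean(aps)
}

#' Kendall tau-b rank correlation with effect-size banding
#'
#' Tie-corrected Kendall rank correlation with an asymptotic (normal
#' approximation) p-value, classified into effect-size bands: negligible
#' (|tau| < 0.1), low (0.1-0.3), medium (0.3-0.5), strong (> 0.5).
#' Significance is judged against the Bonferroni-adjusted level 0.0083.
#'
#' @param x,y equal-length numeric vectors (at least 2 values, nonzero
#'   variance in each).
#' @param alpha_adjusted significance level (default 0.0083).
#' @return an object of class `correlation_result`: list with `tau`,
#'   `p_value`, `effect_band`, `significant`, `alpha_adjusted`, `n`.
#' @export
kendall_tau <- function(x, y, alpha_adjusted = 0.0083) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE)
  )
  tau <- unname(ct$estimate)
  band <- if (abs(tau) < 0.1) "negligible" else if (abs(tau) < 0.3) "low"
    else if (abs(tau) <= 0.5) "medium" else "strong"
  structure(
    list(tau = tau, p_value = ct$p.value, effect_band = band,
         significant = ct$p.value <= alpha_adjusted,
         alpha_adjusted = alpha_adjusted, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("tau = %.3f (%s), p = %.3g%s, n = %d\n", x$tau, x$effect_band,
              x$p_value,
              if (x$significant) sprintf(" (significant at %.4f)", x$alpha_adjusted)
              else "", x$n))
  invisible(x)
}

#' Score all images of a split against their ground truth
#'
#' The workhorse behind [evaluate()]: takes per-image detection tables and
#' annotation tables and computes every reported metric. A detection is a
#' true positive of its score class when it matches a ground truth with
#' IoU >= 0.3 and the correct erosion score; any other detection is a false
#' positive of its predicted class. Per-image accuracy is the fraction of
#' ground-truth joints covered by a correct detection; mean IoU averages
#' matched-pair IoU over all ground truths (missed joints contribute 0).
#' Missed joints enter the confusion matrix as predicted score 0.
#'
#' @param detections_per_image list of detection data frames
#'   ([decode_detections()] output).
#' @param gts_per_image list of [joint_annotations()] data frames.
#' @return an object of class `eval_report`; see [evaluate()].
#' @export
score_detections <- function(detections_per_image, gts_per_image) {
  stopifnot(length(detections_per_image) == length(gts_per_image))
  n_img <- length(gts_per_image)
  classes <- as.character(0:5)
  tp <- stats::setNames(rep(0L, 6L), classes)
  fp <- stats::setNames(rep(0L, 6L), classes)
  confusion_counts <- matrix(0L, 6L, 6L, dimnames = list(true = classes,
                                                         predicted = classes))
  acc <- miou <- rep(NA_real_, n_img)
  sum_true <- sum_pred <- rep(NA_real_, n_img)
  joint_true <- joint_pred <- list()
  ap_records <- list()

  for (i in seq_len(n_img)) {
    gts <- gts_per_image[[i]]
    dets <- detections_per_image[[i]]
    n_gt <- nrow(gts)
    if (n_gt == 0L) {
      warning("image ", i, " has no ground-truth joints; excluded")
      next
    }
    gt_boxes <- annotation_boxes(gts)
    n_det <- nrow(dets)
    if (n_det > 0L) {
      det_boxes <- as_box_matrix(
        as.matrix(dets[, c("x_min", "y_min", "x_max", "y_max")]))
      m <- greedy_match(det_boxes, dets$confidence, gt_boxes)
    } else {
      m <- list(gt = integer(0), iou = numeric(0))
    }
    located <- !is.na(m$gt) & m$iou >= 0.3
    correct <- located & dets$erosion_score == gts$erosion_score[m$gt]
    # TP/FP bookkeeping per erosion class
    for (d in seq_len(n_det)) {
      cl <- as.character(dets$erosion_score[d])
      if (correct[d]) tp[cl] <- tp[cl] + 1L else fp[cl] <- fp[cl] + 1L
    }
    if (n_det > 0L) {
      ap_records[[length(ap_records) + 1L]] <- data.frame(
        confidence = dets$confidence, tp = correct,
        class = as.character(dets$erosion_score))
    }
    acc[i] <- sum(correct) / n_gt
    miou[i] <- sum(m$iou[!is.na(m$gt)]) / n_gt
    # per-joint predicted score: located joints take their detection's
    # score, missed joints count as predicted 0
    pred_scores <- rep(0L, n_gt)
    if (any(located)) pred_scores[m$gt[located]] <- dets$erosion_score[located]
    for (g in seq_len(n_gt)) {
      confusion_counts[gts$erosion_score[g] + 1L, pred_scores[g] + 1L] <-
        confusion_counts[gts$erosion_score[g] + 1L, pred_scores[g] + 1L] + 1L
    }
    joint_true[[i]] <- gts$erosion_score
    joint_pred[[i]] <- pred_scores
    sum_true[i] <- sum(gts$erosion_score)
    sum_pred[i] <- sum(pred_scores)
  }

  used <- !is.na(acc)
  gt_classes <- as.character(sort(unique(unlist(joint_true))))
  confusion <- confusion_counts
  row_n <- rowSums(confusion_counts)
  nonempty <- row_n > 0
  confusion[nonempty, ] <- confusion_counts[nonempty, ] / row_n[nonempty]

  jt <- unlist(joint_true); jp <- unlist(joint_pred)
  tau_joint <- tryCatch(kendall_tau(jt, jp), error = function(e) NULL)
  tau_sum <- tryCatch(kendall_tau(sum_true[used], sum_pred[used]),
                      error = function(e) NULL)
  n_gt_per_class <- stats::setNames(
    vapply(0:5, function(s) sum(jt == s), integer(1)), classes)
  ap_df <- if (length(ap_records)) do.call(rbind, ap_records) else
    data.frame(confidence = numeric(0), tp = logical(0), class = character(0))

  structure(
    list(
      accuracy = mean(acc[used]), accuracy_sd = stats::sd(acc[used]),
      map = map_eq3(tp, fp, gt_classes),
      mean_iou = mean(miou[used]), mean_iou_sd = stats::sd(miou[used]),
      conventional_ap = conventional_ap(ap_df, n_gt_per_class),
      per_class_tp = tp, per_class_fp = fp,
      confusion = confusion, confusion_counts = confusion_counts,
      tau_per_joint = tau_joint, tau_sum_score = tau_sum,
      per_image = data.frame(image = seq_len(n_img), accuracy = acc,
                             mean_iou = miou, sum_score_true = sum_true,
                             sum_score_pred = sum_pred),
      n_images = sum(used)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report over %d images>\n", x$n_images))
  cat(sprintf("  accuracy  %.3f +/- %.3f\n", x$accuracy, x$accuracy_sd))
  cat(sprintf("  mAP       %.3f (per-class precision)\n", x$map))
  cat(sprintf("  mean IoU  %.3f +/- %.3f\n", x$mean_iou, x$mean_iou_sd))
  if (!is.null(x$tau_per_joint)) {
    cat("  tau (per joint): "); print(x$tau_per_joint)
  }
  invisible(x)
}

# Forward a list of resized annotated images through the model in batches
# and decode detections for each.
predict_detections <- function(model, items, anchors = model_anchors(model$config),
                               batch_size = 8L, score_threshold = 0.3,
                               nms_iou = 0.5, top_k = 64L) {
  s <- model$config$image_size
  anchor_boxes <- rbind(anchors$p2$boxes, anchors$p3$boxes)
  n_lvl <- c(nrow(anchors$p2$boxes), nrow(anchors$p3$boxes))
  out <- vector("list", length(items))
  idx <- seq_along(items)
  for (start in seq(1L, length(items), by = batch_size)) {
    batch_idx <- idx[start:min(start + batch_size - 1L, length(items))]
    xb <- array(0, c(s, s, 1L, length(batch_idx)))
    for (k in seq_along(batch_idx)) {
      xb[, , 1L, k] <- zscore_normalize(items[[batch_idx[k]]]$image)
    }
    fw <- detector_forward(model, xb, training = FALSE)
    for (k in seq_along(batch_idx)) {
      ero <- rbind(fw$outputs$p2$erosion[, , k], fw$outputs$p3$erosion[, , k])
      joi <- rbind(fw$outputs$p2$joint[, , k], fw$outputs$p3$joint[, , k])
      box <- rbind(fw$outputs$p2$box[, , k], fw$outputs$p3$box[, , k])
      out[[batch_idx[k]]] <- decode_detections(
        ero, joi, box, anchor_boxes, c(s, s),
        score_threshold = score_threshold, nms_iou = nms_iou, top_k = top_k)
    }
  }
  out
}

#' Evaluate a trained detector on a dataset split
#'
#' Resizes each image to the model's input size, runs the detector in
#' evaluation mode, decodes detections and scores them against the ground
#' truth with [score_detections()].
#'
#' @param checkpoint a `detector_checkpoint` (from [train()] /
#'   [load_checkpoint()]) or a bare `detector`.
#' @param split a [dataset_split()] or list of [annotated_image()].
#' @param score_threshold,nms_iou,top_k decoding parameters.
#' @return an `eval_report`; see [score_detections()].
#' @export
evaluate <- function(checkpoint, split, score_threshold = 0.3, nms_iou = 0.5,
                     top_k = 64L) {
  model <- if (inherits(checkpoint, "detector")) checkpoint else checkpoint$model
  items <- if (inherits(split, "dataset_split")) split$items else split
  if (!length(items)) stop("empty split")
  s <- model$config$image_size
  items <- lapply(items, resize_with_boxes, target = c(s, s))
  dets <- predict_detections(model, items, score_threshold = score_threshold,
                             nms_iou = nms_iou, top_k = top_k)
  gts <- lapply(items, function(it) it$annotations)
  score_detections(dets, gts)
}
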