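#' Focal loss
#'
#' `-alpha * (1 - p_t)^gamma * log(p_t)` summed over the supplied true-class
#' probabilities and normalized by the number of positive anchors (floored
#' at 1). The modulating factor `(1 - p_t)^gamma` down-weights easy
#' examples, countering the extreme foreground/background imbalance of
#' dense anchor grids; with `gamma = 0, alpha = 1` it reduces to plain
#' cross-entropy.
#'
#' @param p_t probabilities of the true class, in `(0, 1]`; values are
#'   clamped at `1e-7` from below, values above 1 are an error.
#' @param alpha balancing weight (default 0.25).
#' @param gamma focusing exponent (default 2).
#' @param n_positive normalizer: number of positive anchors (default 1).
#' @return nonnegative scalar.
#' @export
focal_loss <- function(p_t, alpha = 0.25, gamma = 2, n_positive = 1L) {
  if (any(p_t > 1)) stop("p_t must not exceed 1")
  p_t <- pmax(p_t, 1e-7)
  sum(-alpha * (1 - p_t)^gamma * log(p_t)) / max(n_positive, 1L)
}

#' Smooth L1 (Huber) loss
#'
#' `0.5 * r^2 / beta` for `|r| < beta`, `|r| - 0.5 * beta` otherwise,
#' averaged over the residuals; continuous at the branch junction. Used for
#' bounding-box regression on the encoded offsets.
#'
#' @param residual numeric vector/matrix of prediction minus target.
#' @param beta transition point between the quadratic and linear branch.
#' @return nonnegative scalar.
#' @export
smooth_l1 <- function(residual, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  r <- abs(residual)
  mean(ifelse(r < beta, 0.5 * r^2 / beta, r - 0.5 * beta))
}

# Sigmoid focal loss on logits with 0/1 targets: returns the summed loss
# and its gradient w.r.t. the logits. `weight` zeroes out ignored anchors.
sigmoid_focal_with_grad <- function(logits, targets, weight,
                                    alpha = 0.25, gamma = 2) {
  p <- 1 / (1 + exp(-logits))
  pt <- targets * p + (1 - targets) * (1 - p)
  atw <- (targets * alpha + (1 - targets) * (1 - alpha)) * weight
  om <- 1 - pt
  omg <- if (gamma == 2) om * om else om^gamma
  lp <- log(pmax(pt, 1e-7))
  loss <- -sum(atw * omg * lp)
  # d/dx[-at (1-pt)^g log pt] with dpt/dx = (2t-1) pt (1-pt)
  grad <- atw * (2 * targets - 1) * omg * (gamma * pt * lp - om)
  list(loss = loss, grad = grad)
}

smooth_l1_with_grad <- function(residual, beta = 1) {
  r <- abs(residual)
  loss <- sum(ifelse(r < beta, 0.5 * r^2 / beta, r - 0.5 * beta))
  grad <- ifelse(r < beta, residual / beta, sign(residual))
  list(loss = loss, grad = grad)
}

#' Loss configuration
#'
#' @param focal_alpha,focal_gamma focal-loss parameters (defaults 0.25, 2).
#' @param box_beta smooth-L1 transition point.
#' @param head_weights weights for the erosion, joint and box terms.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(focal_alpha = 0.25, focal_gamma = 2, box_beta = 1,
                        head_weights = c(erosion = 1, joint = 1, box = 1)) {
  stopifnot(focal_alpha > 0, focal_alpha < 1, focal_gamma >= 0, box_beta > 0,
            length(head_weights) == 3L)
  structure(list(focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 box_beta = box_beta, head_weights = head_weights),
            class = "loss_config")
}

# Assemble per-anchor training targets for one image from a match result.
# Returns one-hot matrices plus masks, anchor-major across both levels.
match_to_targets <- function(match, n_joint_classes, n_erosion_classes) {
  n <- length(match$label)
  pos <- match$label == "positive"
  nonignore <- match$label != "ignore"
  t_ero <- matrix(0, n, n_erosion_classes)
  t_joint <- matrix(0, n, n_joint_classes)
  if (any(pos)) {
    t_ero[cbind(which(pos), match$erosion_score[pos] + 1L)] <- 1
    t_joint[cbind(which(pos), match$joint_id[pos])] <- 1
  }
  list(t_erosion = t_ero, t_joint = t_joint,
       cls_weight = as.numeric(nonignore), pos = pos,
       reg_target = match$regression_target)
}

# Compute the three-headed detection loss for one batch, along with the
# gradients w.r.t. every head output. `matches` is a list of match_result,
# one per batch item, over the concatenated p2+p3 anchors.
detector_loss <- function(outputs, matches, lcfg, n_anchors_per_level) {
  n <- length(matches)
  n_total <- sum(n_anchors_per_level)
  ncl_e <- dim(outputs$p2$erosion)[2L]
  ncl_j <- dim(outputs$p2$joint)[2L]

  cat_levels <- function(head) {
    arr <- array(0, c(n_total, dim(outputs$p2[[head]])[2L], n))
    arr[seq_len(n_anchors_per_level[1L]), , ] <- outputs$p2[[head]]
    arr[n_anchors_per_level[1L] + seq_len(n_anchors_per_level[2L]), , ] <-
      outputs$p3[[head]]
    arr
  }
  ero <- cat_levels("erosion")
  joi <- cat_levels("joint")
  box <- cat_levels("box")

  t_ero <- array(0, dim(ero)); t_joi <- array(0, dim(joi))
  w_cls <- array(0, dim = c(n_total, 1L, n))
  t_box <- array(0, dim(box)); w_box <- array(0, dim = c(n_total, 1L, n))
  n_pos_total <- 0L
  for (i in seq_len(n)) {
    tg <- match_to_targets(matches[[i]], ncl_j, ncl_e)
    t_ero[, , i] <- tg$t_erosion
    t_joi[, , i] <- tg$t_joint
    w_cls[, 1L, i] <- tg$cls_weight
    if (any(tg$pos)) {
      t_box[tg$pos, , i] <- tg$reg_target[tg$pos, ]
      w_box[tg$pos, 1L, i] <- 1
    }
    n_pos_total <- n_pos_total + sum(tg$pos)
  }
  norm <- max(n_pos_total, 1L)
  wce <- aperm(array(w_cls[, 1L, ], c(n_total, n, ncl_e)), c(1L, 3L, 2L))
  wcj <- aperm(array(w_cls[, 1L, ], c(n_total, n, ncl_j)), c(1L, 3L, 2L))
  fe <- sigmoid_focal_with_grad(ero, t_ero, wce, lcfg$focal_alpha, lcfg$focal_gamma)
  fj <- sigmoid_focal_with_grad(joi, t_joi, wcj, lcfg$focal_alpha, lcfg$focal_gamma)

  wb <- aperm(array(w_box[, 1L, ], c(n_total, n, 4L)), c(1L, 3L, 2L))
  res <- (box - t_box) * wb
  sl <- smooth_l1_with_grad(res, lcfg$box_beta)

  hw <- lcfg$head_weights
  loss_ero <- hw[[1L]] * fe$loss / norm
  loss_joint <- hw[[2L]] * fj$loss / norm
  loss_box <- hw[[3L]] * sl$loss / max(4L * n_pos_total, 1L)
  d_ero <- hw[[1L]] * fe$grad / norm
  d_joint <- hw[[2L]] * fj$grad / norm
  d_box <- hw[[3L]] * (sl$grad * wb) / max(4L * n_pos_total, 1L)

  split_levels <- function(arr) {
    list(p2 = arr[seq_len(n_anchors_per_level[1L]), , , drop = FALSE],
         p3 = arr[n_anchors_per_level[1L] + seq_len(n_anchors_per_level[2L]), , ,
                  drop = FALSE])
  }
  de <- split_levels(d_ero); dj <- split_levels(d_joint); db <- split_levels(d_box)
  list(
    loss = loss_ero + loss_joint + loss_box,
    parts = c(erosion = loss_ero, joint = loss_joint, box = loss_box),
    n_positive = n_pos_total,
    d_outputs = list(
      p2 = list(joint = dj$p2, erosion = de$p2, box = db$p2),
      p3 = list(joint = dj$p3, erosion = de$p3, box = db$p3)
    )
  )
}
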