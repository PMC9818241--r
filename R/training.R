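#' Training configuration
#'
#' ADAM with an initial learning rate of 0.001 and weight decay 1e-6,
#' reduce-on-plateau learning-rate scheduling (monitoring validation mAP,
#' maximized), focal/smooth-L1 losses, 4x per-epoch oversampling with fresh
#' augmentations, and model selection by the highest validation mAP.
#'
#' @param epochs total training epochs (default 100).
#' @param lr initial learning rate (default 0.001).
#' @param weight_decay L2 penalty added to gradients (default 1e-6).
#' @param batch_size images per optimization step (default 12).
#' @param oversample_factor augmented passes over the training set per
#'   epoch (default 4: each image is seen four times per epoch).
#' @param plateau_patience,plateau_cooldown,plateau_factor reduce-on-plateau
#'   parameters (defaults 20 / 20 / 0.1).
#' @param schedule an [adaptive_schedule()] governing anchor matching.
#' @param augment an [augment_config()] (or `NULL` to train unaugmented).
#' @param grad_clip global gradient-norm ceiling (`Inf` disables; the small
#'   default backbone benefits from clipping).
#' @param score_threshold,nms_iou decoding parameters for the per-epoch
#'   validation pass.
#' @param selection_metric validation quantity maximized for checkpoint
#'   selection and plateau scheduling: `"map"` (per-class precision mAP,
#'   the default) or `"accuracy"`. With very small validation sets the
#'   per-class precision metric degenerates (a checkpoint emitting a
#'   handful of confident detections scores highest), so desk-scale runs
#'   select by accuracy instead.
#' @param seed integer seed covering weight init, augmentation and batching.
#' @param verbose print one line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 0.001, weight_decay = 1e-6,
                         batch_size = 12L, oversample_factor = 4L,
                         plateau_patience = 20L, plateau_cooldown = 20L,
                         plateau_factor = 0.1,
                         schedule = adaptive_schedule(0.5, 0.4, 50L),
                         augment = augment_config(),
                         grad_clip = 10,
                         score_threshold = 0.3, nms_iou = 0.5,
                         selection_metric = c("map", "accuracy"),
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1L, lr > 0, batch_size >= 1L, oversample_factor >= 1L,
            inherits(schedule, "adaptive_schedule"))
  if (!is.null(schedule$adaptive_epochs) && epochs < schedule$adaptive_epochs) {
    stop("epochs must be at least adaptive_epochs")
  }
  structure(
    list(epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
         batch_size = as.integer(batch_size),
         oversample_factor = as.integer(oversample_factor),
         plateau_patience = as.integer(plateau_patience),
         plateau_cooldown = as.integer(plateau_cooldown),
         plateau_factor = plateau_factor,
         schedule = schedule, augment = augment, grad_clip = grad_clip,
         score_threshold = score_threshold, nms_iou = nms_iou,
         selection_metric = match.arg(selection_metric),
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

# Prepare one training pass: augment (fresh draw) and z-score each item,
# returning normalized pixel arrays plus annotation tables.
prepare_sample <- function(item, aug_cfg) {
  it <- if (is.null(aug_cfg)) item else augment(item, aug_cfg)
  list(x = zscore_normalize(it$image), ann = it$annotations)
}

#' Run one training epoch
#'
#' Anchor matching is recomputed for every sample with the thresholds in
#' force at `epoch` ([current_thresholds()]); the training set is traversed
#' `oversample_factor` times, re-augmented and re-shuffled on each pass.
#'
#' @param model a `detector`.
#' @param items list of resized [annotated_image()] (training split).
#' @param epoch 0-based epoch number.
#' @param tcfg,lcfg [train_config()] and [loss_config()].
#' @param anchors per-level anchor sets from [model_anchors()].
#' @param opt list with `flat` (parameters), `state` (ADAM state), `lr`.
#' @return list with updated `model`, `opt`, and epoch statistics
#'   (`loss`, `parts`, `n_positive_mean`, `thresholds`).
#' @export
run_epoch <- function(model, items, epoch, tcfg, lcfg, anchors, opt) {
  thr <- current_thresholds(tcfg$schedule, epoch)
  anchor_boxes <- rbind(anchors$p2$boxes, anchors$p3$boxes)
  n_lvl <- c(nrow(anchors$p2$boxes), nrow(anchors$p3$boxes))
  s <- model$config$image_size

  order_all <- unlist(lapply(seq_len(tcfg$oversample_factor),
                             function(i) sample(seq_along(items))))
  total_loss <- 0; total_parts <- c(erosion = 0, joint = 0, box = 0)
  n_steps <- 0L; n_pos_sum <- 0
  for (start in seq(1L, length(order_all), by = tcfg$batch_size)) {
    sel <- order_all[start:min(start + tcfg$batch_size - 1L, length(order_all))]
    nb <- length(sel)
    xb <- array(0, c(s, s, 1L, nb))
    matches <- vector("list", nb)
    for (k in seq_len(nb)) {
      smp <- prepare_sample(items[[sel[k]]], tcfg$augment)
      xb[, , 1L, k] <- smp$x
      matches[[k]] <- match_anchors(anchor_boxes, smp$ann,
                                    thr[["pos_iou"]], thr[["neg_iou"]])
    }
    fw <- detector_forward(model, xb, training = TRUE)
    model <- fw$model
    ls <- detector_loss(fw$outputs, matches, lcfg, n_lvl)
    if (!is.finite(ls$loss)) {
      stop(sprintf("non-finite loss at epoch %d step %d; aborting", epoch,
                   n_steps + 1L))
    }
    grads <- detector_backward(model, fw$ctx, ls$d_outputs)
    if (is.finite(tcfg$grad_clip)) grads <- clip_grads(grads, tcfg$grad_clip)
    step <- adam_step(opt$flat, grads, opt$state, lr = opt$lr,
                      weight_decay = tcfg$weight_decay)
    opt$flat <- step$params
    opt$state <- step$state
    model$layers <- assign_params(model$layers, opt$flat)
    total_loss <- total_loss + ls$loss
    total_parts <- total_parts + ls$parts
    n_pos_sum <- n_pos_sum + ls$n_positive / nb
    n_steps <- n_steps + 1L
  }
  list(model = model, opt = opt,
       loss = total_loss / n_steps, parts = total_parts / n_steps,
       n_positive_mean = n_pos_sum / n_steps, thresholds = thr,
       n_samples = length(order_all), n_steps = n_steps)
}

#' Train a detector
#'
#' Full training loop: per-epoch anchor matching under the (possibly
#' adaptive) IoU-threshold schedule, oversampled augmented passes, ADAM
#' updates, a per-epoch validation evaluation, reduce-on-plateau learning
#' rate, and selection of the checkpoint with the highest validation mAP.
#'
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param splits named list with `train` and `validation`
#'   [dataset_split()]s (or plain lists of [annotated_image()]).
#' @param lcfg a [loss_config()].
#' @return list with `checkpoint` (class `detector_checkpoint`: the best
#'   model plus its configs and schedule) and `history` (one row per epoch:
#'   thresholds, losses, validation metrics, learning rate).
#' @export
train <- function(mcfg, tcfg, splits, lcfg = loss_config()) {
  get_items <- function(x) if (inherits(x, "dataset_split")) x$items else x
  train_items <- get_items(splits$train)
  val_items <- get_items(splits$validation)
  if (!length(train_items) || !length(val_items)) {
    stop("train and validation splits must be nonempty")
  }
  set.seed(tcfg$seed)
  s <- mcfg$image_size
  train_items <- lapply(train_items, resize_with_boxes, target = c(s, s))
  val_items <- lapply(val_items, resize_with_boxes, target = c(s, s))
  model <- build_detector(mcfg)
  anchors <- model_anchors(mcfg)
  opt <- list(flat = collect_params(model$layers),
              state = NULL, lr = tcfg$lr)
  opt$state <- adam_init(opt$flat)

  history <- vector("list", tcfg$epochs)
  best <- list(crit = -Inf, map = -Inf, model = NULL, epoch = NA_integer_)
  plateau <- list(best = -Inf, bad = 0L, cooldown = 0L)

  for (epoch in seq_len(tcfg$epochs) - 1L) {
    ep <- run_epoch(model, train_items, epoch, tcfg, lcfg, anchors, opt)
    model <- ep$model; opt <- ep$opt

    val <- evaluate(model, val_items, score_threshold = tcfg$score_threshold,
                    nms_iou = tcfg$nms_iou)
    crit <- if (tcfg$selection_metric == "accuracy") val$accuracy else val$map
    if (crit > best$crit) {
      best <- list(crit = crit, map = val$map, model = model, epoch = epoch)
    }
    # reduce-on-plateau on the selection metric (maximize)
    if (plateau$cooldown > 0L) {
      plateau$cooldown <- plateau$cooldown - 1L
      if (crit > plateau$best) plateau$best <- crit
    } else if (crit > plateau$best) {
      plateau$best <- crit
      plateau$bad <- 0L
    } else {
      plateau$bad <- plateau$bad + 1L
      if (plateau$bad > tcfg$plateau_patience) {
        opt$lr <- opt$lr * tcfg$plateau_factor
        plateau$bad <- 0L
        plateau$cooldown <- tcfg$plateau_cooldown
      }
    }
    history[[epoch + 1L]] <- data.frame(
      epoch = epoch, pos_iou = ep$thresholds[["pos_iou"]],
      neg_iou = ep$thresholds[["neg_iou"]],
      loss = ep$loss, loss_erosion = ep$parts[["erosion"]],
      loss_joint = ep$parts[["joint"]], loss_box = ep$parts[["box"]],
      n_positive_mean = ep$n_positive_mean,
      val_accuracy = val$accuracy, val_map = val$map,
      val_mean_iou = val$mean_iou, lr = opt$lr
    )
    if (tcfg$verbose) {
      cat(sprintf(
        "epoch %3d  thr %.3f/%.3f  loss %.4f  pos/img %.1f  val acc %.3f  mAP %.3f  mIoU %.3f\n",
        epoch, ep$thresholds[["pos_iou"]], ep$thresholds[["neg_iou"]],
        ep$loss, ep$n_positive_mean, val$accuracy, val$map, val$mean_iou))
    }
  }
  history <- do.call(rbind, history)
  checkpoint <- structure(
    list(model = best$model, model_config = mcfg, train_config = tcfg,
         loss_config = lcfg, schedule = tcfg$schedule,
         best_epoch = best$epoch, best_val_map = best$map),
    class = "detector_checkpoint"
  )
  list(checkpoint = checkpoint, history = history)
}

#' @export
print.detector_checkpoint <- function(x, ...) {
  cat(sprintf("<detector_checkpoint: best epoch %d, validation mAP %.3f>\n",
              x$best_epoch, x$best_val_map))
  print(x$schedule)
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints bundle the weights with the model configuration and the
#' IoU-threshold schedule they were trained under.
#'
#' @param checkpoint a `detector_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "detector_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "detector_checkpoint"))
  ck
}
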