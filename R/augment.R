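#' Augmentation configuration
#'
#' The stochastic training-time augmentation chain, applied in a fixed
#' order: gamma contrast adjustment, x/y shift, border crop, occasional 90
#' degree rotation, isotropic scaling, and a final small rotation. All
#' geometric steps are composed into a single affine transform that is
#' applied identically to the image and its boxes.
#'
#' @param gamma_range gamma exponent range (default 0.5-2).
#' @param shift_frac maximum shift along each axis, as a fraction of the
#'   image size (default 0.05).
#' @param crop_frac maximum border crop per side, as a fraction of the image
#'   size (default 0.05); the crop is resized back to the original size.
#' @param rot90_prob probability of a 90 degree (counter-clockwise)
#'   rotation (default 0.10).
#' @param scale_range isotropic scale factor range (default 0.5-2), about
#'   the image center with a fixed canvas.
#' @param rotate_deg_range final rotation range in degrees (default -15..15).
#' @param rot90_dir `"ccw"` or `"cw"`.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(gamma_range = c(0.5, 2), shift_frac = 0.05,
                           crop_frac = 0.05, rot90_prob = 0.10,
                           scale_range = c(0.5, 2),
                           rotate_deg_range = c(-15, 15),
                           rot90_dir = c("ccw", "cw")) {
  stopifnot(gamma_range[1L] <= gamma_range[2L], gamma_range[1L] > 0,
            scale_range[1L] <= scale_range[2L], scale_range[1L] > 0,
            rotate_deg_range[1L] <= rotate_deg_range[2L],
            rot90_prob >= 0, rot90_prob <= 1,
            shift_frac >= 0, crop_frac >= 0, crop_frac < 0.5)
  structure(
    list(gamma_range = gamma_range, shift_frac = shift_frac,
         crop_frac = crop_frac, rot90_prob = rot90_prob,
         scale_range = scale_range, rotate_deg_range = rotate_deg_range,
         rot90_dir = match.arg(rot90_dir)),
    class = "augment_config"
  )
}

identity_augment_config <- function() {
  augment_config(gamma_range = c(1, 1), shift_frac = 0, crop_frac = 0,
                 rot90_prob = 0, scale_range = c(1, 1),
                 rotate_deg_range = c(0, 0))
}

#' Transform boxes through an affine map
#'
#' Each output box is the axis-aligned hull of the four transformed input
#' corners, clipped to the image.
#'
#' @param boxes n x 4 box matrix.
#' @param affine forward 2 x 3 affine matrix.
#' @param image_size `(height, width)` used for clipping.
#' @return n x 4 transformed box matrix (possibly with degenerate rows
#'   after clipping; callers filter).
#' @export
transform_boxes <- function(boxes, affine, image_size) {
  b <- as_box_matrix(boxes)
  affine <- matrix(as.numeric(affine), 2L, 3L)
  if (abs(det(rbind(affine, c(0, 0, 1)))) < 1e-12) stop("singular affine transform")
  if (nrow(b) == 0L) return(b)
  cx <- cbind(b[, 1L], b[, 3L], b[, 1L], b[, 3L])  # 4 corners per box
  cy <- cbind(b[, 2L], b[, 2L], b[, 4L], b[, 4L])
  tx <- affine[1L, 1L] * cx + affine[1L, 2L] * cy + affine[1L, 3L]
  ty <- affine[2L, 1L] * cx + affine[2L, 2L] * cy + affine[2L, 3L]
  hull <- cbind(apply(tx, 1L, min), apply(ty, 1L, min),
                apply(tx, 1L, max), apply(ty, 1L, max))
  clip_boxes(hull, image_size)
}

# Draw the per-sample augmentation parameters from the current RNG stream.
draw_augment_params <- function(config, image_size) {
  h <- image_size[1L]; w <- image_size[2L]
  list(
    gamma = stats::runif(1L, config$gamma_range[1L], config$gamma_range[2L]),
    shift = c(stats::runif(1L, -1, 1), stats::runif(1L, -1, 1)) *
      config$shift_frac * c(w, h),
    crop = stats::runif(4L, 0, config$crop_frac),  # left, right, top, bottom
    rot90 = stats::runif(1L) < config$rot90_prob,
    scale = stats::runif(1L, config$scale_range[1L], config$scale_range[2L]),
    rotate = stats::runif(1L, config$rotate_deg_range[1L],
                          config$rotate_deg_range[2L])
  )
}

# Compose the geometric chain (shift -> crop -> rot90 -> scale -> rotate)
# into one forward affine for a (h, w) image with fixed canvas.
compose_augment_affine <- function(p, h, w) {
  a <- affine_translate(p$shift[1L], p$shift[2L])
  # border crop resized back to the full canvas
  cl <- p$crop[1L] * w; cr <- p$crop[2L] * w
  ct <- p$crop[3L] * h; cb <- p$crop[4L] * h
  sx <- w / (w - cl - cr); sy <- h / (h - ct - cb)
  crop_aff <- affine_compose(affine_scale(sx, sy), affine_translate(-cl, -ct))
  a <- affine_compose(crop_aff, a)
  if (p$rot90) {
    ang <- if (identical(p$rot90_dir, "cw")) 90 else -90
    a <- affine_compose(affine_rotate(ang, center = c(w / 2, h / 2)), a)
  }
  a <- affine_compose(affine_rotate(p$rotate, center = c(w / 2, h / 2)),
                      affine_compose(
                        affine_scale_about(p$scale, c(w / 2, h / 2)), a))
  a
}

affine_scale_about <- function(s, center) {
  affine_compose(affine_translate(center[1L], center[2L]),
                 affine_compose(affine_scale(s),
                                affine_translate(-center[1L], -center[2L])))
}

#' Apply the augmentation chain to an annotated image
#'
#' Gamma is applied on intensities normalized to `[0, 1]` and rescaled, so
#' its effect is independent of the intensity range. All geometric steps
#' are drawn from the current RNG stream (seed it with `set.seed()` for
#' reproducibility), composed into one affine, and applied to image and
#' boxes alike. Boxes whose clipped area falls below 20% of their original
#' area are dropped rather than emitted as slivers.
#'
#' @param item an [annotated_image()] with a loaded image.
#' @param config an [augment_config()].
#' @return the augmented [annotated_image()].
#' @export
augment <- function(item, config = augment_config()) {
  stopifnot(inherits(item, "annotated_image"), !is.null(item$image))
  h <- item$image$height; w <- item$image$width
  p <- draw_augment_params(config, c(h, w))
  p$rot90_dir <- config$rot90_dir

  px <- item$image$pixels
  if (p$gamma != 1) px <- 4096 * (px / 4096)^p$gamma

  a <- compose_augment_affine(p, h, w)
  identity_geometry <- all(abs(a - affine_identity()) < 1e-12)
  if (!identity_geometry) px <- warp_affine(px, a, out_size = c(h, w))

  ann <- item$annotations
  orig_area <- (ann$x_max - ann$x_min) * (ann$y_max - ann$y_min)
  new_boxes <- transform_boxes(annotation_boxes(ann), a, c(h, w))
  # area ratio uses the affine's own area change as the reference so the
  # 20% drop rule measures clipping loss, not the deliberate zoom
  det_a <- abs(det(a[, 1:2]))
  new_area <- pmax(new_boxes[, 3L] - new_boxes[, 1L], 0) *
    pmax(new_boxes[, 4L] - new_boxes[, 2L], 0)
  keep <- new_area >= 0.2 * orig_area * det_a & new_area > 0
  ann <- ann[keep, , drop = FALSE]
  nb <- new_boxes[keep, , drop = FALSE]
  ann$x_min <- nb[, 1L]; ann$y_min <- nb[, 2L]
  ann$x_max <- nb[, 3L]; ann$y_max <- nb[, 4L]

  annotated_image(
    radiograph_image(px, source_id = item$image$source_id),
    ann, image_path = item$image_path, patient_id = item$patient_id
  )
}
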