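#' Class prior over erosion scores in the test population
#'
#' Relative frequencies of Sharp/van der Heijde erosion scores 0-5 observed
#' across 768 scored joints of a reference clinical population (75.26% normal
#' joints, 6.64% score >= 5), renormalized to sum exactly to 1. The
#' synthetic generator draws joint scores from this prior so downstream
#' models face the same class imbalance.
#'
#' @return numeric vector of 6 probabilities, names `"0"`..`"5"`.
#' @export
default_class_prior <- function() {
  p <- c(0.7526, 0.0690, 0.0456, 0.0352, 0.0313, 0.0664)
  p <- p / sum(p)
  names(p) <- as.character(0:5)
  p
}

#' Synthetic bilateral-hand generator configuration
#'
#' The generator emulates the geometry the detector targets: 32 small
#' objects per image, two columnar hand layouts of finger joints plus one
#' tight carpal cluster per hand whose inter-box gaps stay below 25% of the
#' box size (the crowded-wrist failure mode), and an erosion-score
#' appearance model that is monotone in the score.
#'
#' @param image_size square image side in pixels.
#' @param n_images number of images in the dataset.
#' @param class_prior 6 probabilities over erosion scores 0-5.
#' @param carpal_cluster_fraction fraction of the 32 joints placed in the
#'   tight carpal clusters (default 10/32, i.e. 5 per hand).
#' @param joint_size_range `(min, max)` box side in pixels at the configured
#'   `image_size`.
#' @param noise_sd additive Gaussian intensity noise, in `[0, 4096]` units.
#' @param seed integer seed; together with the image index it fully
#'   determines every image.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(image_size = 400L, n_images = 10L,
                             class_prior = default_class_prior(),
                             carpal_cluster_fraction = 10 / 32,
                             joint_size_range = c(8, 24),
                             noise_sd = 60, seed = 1L) {
  stopifnot(length(class_prior) == 6L, all(class_prior >= 0))
  if (abs(sum(class_prior) - 1) > 1e-9) stop("class_prior must sum to 1")
  if (any(joint_size_range <= 0) || joint_size_range[2L] >= image_size / 4) {
    stop("joint sizes must be positive and below image_size / 4")
  }
  if (image_size < 32L) stop("image_size must be at least 32")
  n_carpal <- 2L * round(32 * carpal_cluster_fraction / 2)
  structure(
    list(image_size = as.integer(image_size), n_images = as.integer(n_images),
         class_prior = unname(class_prior),
         carpal_cluster_fraction = carpal_cluster_fraction,
         n_carpal = as.integer(n_carpal),
         joint_size_range = as.numeric(joint_size_range),
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "generator_config"
  )
}

# one independent, reproducible RNG stream per (seed, index)
derive_stream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index)) %% 2147483587)
}

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# relative finger-joint layout for one hand: 5 metacarpophalangeal,
# 4 proximal interphalangeal, 2 distal rows; x offsets relative to the hand
# axis, y relative to image height
finger_layout <- function() {
  rbind(
    cbind(x = c(-0.12, -0.06, 0.00, 0.06, 0.12), y = 0.48),
    cbind(x = c(-0.11, -0.05, 0.01, 0.07),       y = 0.30),
    cbind(x = c(-0.03, 0.03),                    y = 0.16)
  )
}

# compact cluster offsets (units of one spacing), quincunx first
cluster_offsets <- function(n) {
  base <- rbind(
    c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
    c(1, 1), c(-1, -1), c(1, -1), c(-1, 1),
    c(2, 0), c(-2, 0), c(0, 2), c(0, -2)
  )
  if (n > nrow(base)) stop("carpal cluster larger than supported (13 per hand)")
  base[seq_len(n), , drop = FALSE]
}

# Draw a bone shaft: a bright bar along the segment p0-p1 with a smooth
# falloff, rendered with pmax so overlapping structures merge. Shafts give
# the background bone-like clutter so joints are not trivially salient.
render_shaft <- function(canvas, p0, p1, width, intensity = 2400) {
  s <- nrow(canvas)
  x0 <- max(1L, floor(min(p0[1L], p1[1L]) - width - 2))
  x1 <- min(s, ceiling(max(p0[1L], p1[1L]) + width + 2))
  y0 <- max(1L, floor(min(p0[2L], p1[2L]) - width - 2))
  y1 <- min(s, ceiling(max(p0[2L], p1[2L]) + width + 2))
  if (x1 <= x0 || y1 <= y0) return(canvas)
  xs <- seq(x0, x1) - 0.5
  ys <- seq(y0, y1) - 0.5
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- if (len2 > 0) pmin(pmax(((px - p0[1L]) * v[1L] + (py - p0[2L]) * v[2L]) / len2, 0), 1) else 0
  dx <- px - (p0[1L] + t * v[1L])
  dy <- py - (p0[2L] + t * v[2L])
  r <- sqrt(dx^2 + dy^2)
  patch <- intensity * pmax(0, pmin(1, (width / 2 - r) / (width / 4) + 0.5))
  region <- canvas[y0:y1, x0:x1]
  canvas[y0:y1, x0:x1] <- pmax(region, patch)
  canvas
}

# Render one joint onto the canvas: a bright cortical rim (annulus) around a
# trabecular interior. Erosion is drawn as an arc removed from the rim plus
# an interior intensity drop, both monotone in the score, so score classes
# are statistically separable from appearance.
render_joint <- function(canvas, cx, cy, size, score, rim_phase) {
  s <- nrow(canvas)
  r_out <- size / 2
  x0 <- max(1L, floor(cx - r_out - 2)); x1 <- min(s, ceiling(cx + r_out + 2))
  y0 <- max(1L, floor(cy - r_out - 2)); y1 <- min(s, ceiling(cy + r_out + 2))
  xs <- seq(x0, x1) - 0.5
  ys <- seq(y0, y1) - 0.5
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, length(ys), length(xs))
  r <- sqrt(dx^2 + dy^2) / r_out
  theta <- atan2(dy, dx)

  interior_int <- 2800 - 400 * score      # monotone interior darkening
  rim_int <- 3600
  gap_angle <- score * (55 * pi / 180)    # monotone rim arc removal

  body <- interior_int * pmax(0, pmin(1, (1.0 - r) / 0.15 + 1))
  rim <- rim_int * exp(-((r - 0.85) / 0.10)^2)
  if (gap_angle > 0) {
    dphi <- (theta - rim_phase) %% (2 * pi)
    rim[dphi < gap_angle] <- 0
  }
  patch <- pmax(body, rim)
  region <- canvas[y0:y1, x0:x1]
  canvas[y0:y1, x0:x1] <- pmax(region, patch)
  canvas
}

#' Generate one synthetic annotated hand image
#'
#' Deterministic given `(config$seed, index)`: each image has its own RNG
#' stream, so datasets are reproducible regardless of generation order.
#' Produces exactly 32 annotated joints (ids 1-32: left hand 1-16, right
#' hand 17-32) with erosion scores drawn from the configured class prior.
#'
#' @param config a [generator_config()].
#' @param index positive integer image index.
#' @return an [annotated_image()] with a loaded image.
#' @export
generate_image <- function(config, index) {
  stopifnot(inherits(config, "generator_config"), index >= 1)
  with_local_seed(derive_stream_seed(config$seed, index), {
    s <- config$image_size
    szr <- config$joint_size_range
    n_carpal_hand <- config$n_carpal %/% 2L
    n_finger_hand <- 16L - n_carpal_hand
    fl <- finger_layout()
    if (n_finger_hand > nrow(fl)) {
      stop("carpal_cluster_fraction too small: more finger joints than layout slots")
    }

    canvas <- matrix(400 + 300 * (seq_len(s) - 0.5) / s, s, s)  # base + gradient
    centers <- matrix(0, 0, 2)
    sizes <- numeric(0)

    # soft-tissue silhouette of each hand
    gx <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)
    gy <- matrix(seq_len(s) - 0.5, s, s)
    for (hx_rel in c(0.27, 0.73)) {
      d2 <- ((gx - hx_rel * s) / (0.18 * s))^2 + ((gy - 0.45 * s) / (0.40 * s))^2
      tissue <- 1100 * pmax(0, pmin(1, (1 - d2) * 3 + 0.5))
      canvas <- pmax(canvas, tissue)
    }

    # trim a shaft segment so it stops at the joint rims, keeping the
    # score-coded joint interior visible
    shorten <- function(p0, p1, r0, r1) {
      v <- p1 - p0; len <- sqrt(sum(v^2))
      if (len <= r0 + r1) return(NULL)
      u <- v / len
      list(p0 = p0 + u * r0, p1 = p1 - u * r1)
    }

    for (hand in 1:2) {
      hx <- (if (hand == 1) 0.27 else 0.73) * s
      mirror <- if (hand == 1) 1 else -1
      # finger joints: spread columnar layout with positional jitter
      f <- fl[seq_len(n_finger_hand), , drop = FALSE]
      fx <- hx + mirror * f[, 1L] * s + stats::runif(n_finger_hand, -0.015, 0.015) * s
      fy <- f[, 2L] * s + stats::runif(n_finger_hand, -0.015, 0.015) * s
      fsz <- stats::runif(n_finger_hand, szr[1L], szr[2L])
      # carpal cluster: common box size, spacing with gap <= 25% of box size
      csz <- stats::runif(1L, mean(szr), szr[2L])
      gap <- stats::runif(1L, 0.05, 0.25)
      spacing <- csz * (1 + gap)
      off <- cluster_offsets(n_carpal_hand)
      ccx <- hx + mirror * 0.02 * s + off[, 1L] * spacing
      ccy <- 0.66 * s + off[, 2L] * spacing

      # keep every box fully inside the image (shift centers, never shrink)
      fx <- pmin(pmax(fx, fsz / 2 + 1), s - fsz / 2 - 1)
      fy <- pmin(pmax(fy, fsz / 2 + 1), s - fsz / 2 - 1)
      ccx <- pmin(pmax(ccx, csz / 2 + 1), s - csz / 2 - 1)
      ccy <- pmin(pmax(ccy, csz / 2 + 1), s - csz / 2 - 1)

      # phalangeal and metacarpal shafts between consecutive joints, plus
      # two forearm bones below the carpal cluster
      carp_center <- c(mean(ccx), mean(ccy))
      sw <- 0.55 * mean(fsz)
      seg_pairs <- list()
      if (n_finger_hand >= 9L) {
        for (i in 1:4) seg_pairs <- c(seg_pairs, list(c(5L + i, i)))  # PIP-MCP
      }
      if (n_finger_hand >= 11L) {
        seg_pairs <- c(seg_pairs, list(c(10L, 7L), c(11L, 8L)))       # DIP-PIP
      }
      for (sp in seg_pairs) {
        tr <- shorten(c(fx[sp[1L]], fy[sp[1L]]), c(fx[sp[2L]], fy[sp[2L]]),
                      0.75 * fsz[sp[1L]], 0.75 * fsz[sp[2L]])
        if (!is.null(tr)) canvas <- render_shaft(canvas, tr$p0, tr$p1, sw)
      }
      for (i in seq_len(min(5L, n_finger_hand))) {                    # metacarpals
        tr <- shorten(c(fx[i], fy[i]), carp_center, 0.75 * fsz[i], 1.6 * csz)
        if (!is.null(tr)) canvas <- render_shaft(canvas, tr$p0, tr$p1, sw)
      }
      for (dxf in c(-0.03, 0.03)) {                                   # forearm
        p0 <- carp_center + c(dxf * s, 1.6 * csz)
        canvas <- render_shaft(canvas, p0, c(p0[1L] + dxf * s * 0.5, s), sw * 1.3)
      }

      centers <- rbind(centers, cbind(c(fx, ccx), c(fy, ccy)))
      sizes <- c(sizes, fsz, rep(csz, n_carpal_hand))
    }
    half <- sizes / 2

    scores <- sample(0:5, 32L, replace = TRUE, prob = config$class_prior)
    phases <- stats::runif(32L, 0, 2 * pi)
    for (j in 1:32) {
      canvas <- render_joint(canvas, centers[j, 1L], centers[j, 2L],
                             sizes[j], scores[j], phases[j])
    }
    canvas <- canvas + stats::rnorm(s * s, 0, config$noise_sd)
    canvas <- pmin(pmax(canvas, 0), 4096)

    boxes <- cbind(centers[, 1L] - half, centers[, 2L] - half,
                   centers[, 1L] + half, centers[, 2L] + half)
    if (any(pmin(box_widths(boxes), box_heights(boxes)) < 4)) {
      stop("generated box smaller than 4 px; widen joint_size_range")
    }
    id <- sprintf("synth-%05d", index)
    annotated_image(
      radiograph_image(canvas, source_id = id),
      joint_annotations(1:32, boxes, scores),
      image_path = paste0(id, ".tiff"),
      patient_id = id
    )
  })
}

#' Generate a synthetic dataset
#'
#' @param config a [generator_config()].
#' @return an object of class `synthetic_dataset`: list with `items` (list
#'   of [annotated_image()]) and `config`.
#' @export
generate_dataset <- function(config) {
  items <- lapply(seq_len(config$n_images), function(i) generate_image(config, i))
  structure(list(items = items, config = config), class = "synthetic_dataset")
}

#' Split a synthetic dataset into train/validation/test
#'
#' Each synthetic image belongs to its own synthetic patient; patients are
#' assigned to exactly one split, with sizes within rounding of the
#' requested fractions (default 70/10/20).
#'
#' @param config a [generator_config()].
#' @param fractions train/validation/test fractions summing to 1.
#' @return named list of three [dataset_split()] objects.
#' @export
generate_split <- function(config, fractions = c(0.7, 0.1, 0.2)) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  ds <- generate_dataset(config)
  n <- length(ds$items)
  perm <- with_local_seed(derive_stream_seed(config$seed, 0L), sample.int(n))
  n_tr <- round(fractions[1L] * n)
  n_va <- round(fractions[2L] * n)
  n_te <- n - n_tr - n_va
  if (min(n_tr, n_va, n_te) < 1L) stop("every split needs at least one image")
  idx <- list(train = perm[seq_len(n_tr)],
              validation = perm[n_tr + seq_len(n_va)],
              test = perm[n_tr + n_va + seq_len(n_te)])
  lapply(stats::setNames(names(idx), names(idx)), function(nm) {
    dataset_split(nm, ds$items[idx[[nm]]])
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits one 16-bit TIFF per image, a single `annotations.csv` table and a
#' `config.yaml` echo of the generator configuration, so command-line runs
#' are inspectable.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (it in dataset$items) {
    write_image(it$image, file.path(dir, it$image_path))
  }
  write_annotations(dataset$items, file.path(dir, "annotations.csv"))
  cfg <- dataset$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
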