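#' Radiograph image container
#'
#' Wraps a 2-D intensity matrix in the windowed `[0, 4096]` range together
#' with its provenance. Pixel `[i, j]` (1-based row/column) covers the unit
#' square whose corner is `(x, y) = (j - 1, i - 1)` in the 0-based box
#' coordinate system, so an image of `height` rows and `width` columns spans
#' `[0, width] x [0, height]`.
#'
#' @param pixels numeric matrix, values in `[0, 4096]`.
#' @param source_id opaque identifier string.
#' @param window_center,window_width original DICOM window parameters, if the
#'   image came from a windowing step (optional).
#' @return an object of class `radiograph_image`.
#' @export
radiograph_image <- function(pixels, source_id = "unknown",
                             window_center = NULL, window_width = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 4096) {
    stop("pixels must lie in [0, 4096]; apply_window() raw data first")
  }
  if (nrow(pixels) < 32L || ncol(pixels) < 32L) {
    stop("image must be at least 32 x 32 pixels")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         source_id = as.character(source_id),
         window_center = window_center, window_width = window_width),
    class = "radiograph_image"
  )
}

#' @export
print.radiograph_image <- function(x, ...) {
  cat(sprintf("<radiograph_image %s: %d x %d, intensity [%.0f, %.0f]>\n",
              x$source_id, x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Window/level a raw intensity array
#'
#' Maps the window `[center - width/2, center + width/2]` linearly onto
#' `[0, 4096]` and clips outside it, the standard DICOM window/level
#' operation used to normalize 12-bit radiographs before training.
#'
#' @param raw_pixels numeric matrix of raw detector intensities.
#' @param center,width window center and width in the raw intensity units;
#'   `width` must be positive.
#' @inheritParams radiograph_image
#' @return a [radiograph_image()] with pixels in `[0, 4096]`.
#' @export
apply_window <- function(raw_pixels, center, width, source_id = "unknown") {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stop("window width must be a positive number")
  }
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop("window center must be a finite number")
  }
  raw_pixels <- as.matrix(raw_pixels)
  lo <- center - width / 2
  out <- (raw_pixels - lo) / width * 4096
  out <- pmin(pmax(out, 0), 4096)
  radiograph_image(out, source_id = source_id,
                   window_center = center, window_width = width)
}

#' Z-score normalize an image
#'
#' Centers and scales the pixel intensities to sample mean 0 and standard
#' deviation 1 (population convention, divide by N), the form the detector
#' consumes.
#'
#' @param image a [radiograph_image()] or plain numeric matrix.
#' @return a numeric matrix with mean 0 and (population) sd 1.
#' @export
zscore_normalize <- function(image) {
  px <- if (inherits(image, "radiograph_image")) image$pixels else as.matrix(image)
  mu <- mean(px)
  sdev <- sqrt(mean((px - mu)^2))
  if (sdev <= 0) stop("constant image: z-score normalization undefined")
  (px - mu) / sdev
}

# Bilinear sampling of `pixels` at continuous (x, y) positions in the 0-based
# coordinate system (pixel [i, j] has center x = j - 0.5, y = i - 0.5).
# Out-of-bounds samples return `fill`. x and y are equal-length vectors.
bilinear_sample <- function(pixels, x, y, fill = 0) {
  h <- nrow(pixels); w <- ncol(pixels)
  # shift to pixel-center grid coordinates (1-based fractional indices)
  gx <- x + 0.5
  gy <- y + 0.5
  x0 <- floor(gx - 1) + 1  # left neighbor column index
  y0 <- floor(gy - 1) + 1
  fx <- gx - x0
  fy <- gy - y0
  x1 <- x0 + 1; y1 <- y0 + 1
  # clamp indices; weight handles the border via the fill mask below
  inb <- function(i, n) pmin(pmax(i, 1L), n)
  at <- function(iy, ix) pixels[cbind(inb(iy, h), inb(ix, w))]
  v <- (1 - fx) * (1 - fy) * at(y0, x0) +
    fx * (1 - fy) * at(y0, x1) +
    (1 - fx) * fy * at(y1, x0) +
    fx * fy * at(y1, x1)
  outside <- gx < 0.5 | gx > w + 0.5 | gy < 0.5 | gy > h + 0.5
  v[outside] <- fill
  v
}

#' Warp an image with an affine transform
#'
#' Resamples bilinearly onto an output grid of the requested size. `affine`
#' is the forward 2 x 3 matrix mapping input coordinates `(x, y, 1)` to
#' output coordinates; the sampler inverts it.
#'
#' @param pixels numeric matrix.
#' @param affine 2 x 3 forward affine matrix.
#' @param out_size `(height, width)` of the output.
#' @param fill intensity used outside the source image.
#' @return resampled numeric matrix of size `out_size`.
#' @export
warp_affine <- function(pixels, affine, out_size = dim(pixels), fill = 0) {
  affine <- matrix(as.numeric(affine), 2L, 3L)
  a33 <- rbind(affine, c(0, 0, 1))
  if (abs(det(a33)) < 1e-12) stop("singular affine transform")
  inv <- solve(a33)
  h2 <- out_size[1L]; w2 <- out_size[2L]
  # output pixel centers
  xs <- rep(seq_len(w2) - 0.5, each = h2)
  ys <- rep(seq_len(h2) - 0.5, times = w2)
  sx <- inv[1L, 1L] * xs + inv[1L, 2L] * ys + inv[1L, 3L]
  sy <- inv[2L, 1L] * xs + inv[2L, 2L] * ys + inv[2L, 3L]
  matrix(bilinear_sample(pixels, sx, sy, fill = fill), h2, w2)
}

# Affine constructors (2 x 3, forward maps input (x, y) -> output)
affine_identity <- function() cbind(diag(2), c(0, 0))
affine_scale <- function(sx, sy = sx) cbind(diag(c(sx, sy)), c(0, 0))
affine_translate <- function(tx, ty) cbind(diag(2), c(tx, ty))
affine_rotate <- function(theta_deg, center = c(0, 0)) {
  th <- theta_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  cbind(r, center - r %*% center)
}
affine_compose <- function(b, a) {
  # returns the transform "apply a, then b"
  cbind(b[, 1:2] %*% a[, 1:2], b[, 1:2] %*% a[, 3L] + b[, 3L])
}

#' Read a grayscale image file
#'
#' Supports 8/16-bit PNG and TIFF. Intensities are rescaled to the working
#' `[0, 4096]` range.
#'
#' @param path image file path.
#' @return a [radiograph_image()].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of gray+alpha
  radiograph_image(px * 4096, source_id = basename(path))
}

#' Write a grayscale image file
#'
#' Writes 16-bit TIFF (default) or 8-bit PNG, scaling the working
#' `[0, 4096]` range to the full sample range.
#'
#' @param image a [radiograph_image()] or numeric matrix in `[0, 4096]`.
#' @param path output path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "radiograph_image")) image$pixels else as.matrix(image)
  v <- pmin(pmax(px / 4096, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 16L),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)")
  )
  invisible(path)
}
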