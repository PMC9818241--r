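#' Joint annotation tables
#'
#' Annotations for one image are held as a data frame with one row per
#' scored joint site and columns `joint_id` (integer 1-32), `x_min`,
#' `y_min`, `x_max`, `y_max` (0-based half-open pixel corners) and
#' `erosion_score` (integer 0-5, Sharp/van der Heijde erosion grade).
#'
#' @param joint_id integer vector in 1..32, unique within the image.
#' @param boxes n x 4 box matrix.
#' @param erosion_score integer vector in 0..5.
#' @return a validated `data.frame` of annotations.
#' @export
joint_annotations <- function(joint_id, boxes, erosion_score) {
  boxes <- as_box_matrix(boxes)
  ann <- data.frame(
    joint_id = as.integer(joint_id),
    x_min = boxes[, 1L], y_min = boxes[, 2L],
    x_max = boxes[, 3L], y_max = boxes[, 4L],
    erosion_score = as.integer(erosion_score)
  )
  validate_annotations(ann)
}

validate_annotations <- function(ann, where = "annotations") {
  required <- c("joint_id", "x_min", "y_min", "x_max", "y_max", "erosion_score")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop(where, ": missing columns ", paste(missing_cols, collapse = ", "))
  }
  problems <- character()
  bad_joint <- which(is.na(ann$joint_id) | ann$joint_id < 1L | ann$joint_id > 32L)
  if (length(bad_joint)) {
    problems <- c(problems, paste0("joint_id out of 1..32 in rows ",
                                   paste(bad_joint, collapse = ",")))
  }
  bad_score <- which(is.na(ann$erosion_score) |
                       ann$erosion_score < 0L | ann$erosion_score > 5L)
  if (length(bad_score)) {
    problems <- c(problems, paste0("erosion_score out of 0..5 in rows ",
                                   paste(bad_score, collapse = ",")))
  }
  bad_box <- which(!(ann$x_min < ann$x_max & ann$y_min < ann$y_max))
  if (length(bad_box)) {
    problems <- c(problems, paste0("degenerate box in rows ",
                                   paste(bad_box, collapse = ",")))
  }
  dup <- ann$joint_id[duplicated(ann$joint_id)]
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate joint_id: ",
                                   paste(unique(dup), collapse = ",")))
  }
  if (length(problems)) {
    stop(where, " failed validation:\n  ", paste(problems, collapse = "\n  "))
  }
  ann
}

annotation_boxes <- function(ann) {
  as_box_matrix(as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")]))
}

#' An image together with its joint annotations
#'
#' @param image a [radiograph_image()], or `NULL` when only the annotation
#'   table is being manipulated (the image stays on disk, referenced by
#'   `image_path`).
#' @param annotations a [joint_annotations()] data frame (32 rows for a
#'   complete bilateral-hand image; fewer allowed for crops).
#' @param image_path path of the image file, for lazily-loaded datasets.
#' @param patient_id opaque identifier used for split bookkeeping.
#' @return an object of class `annotated_image`.
#' @export
annotated_image <- function(image = NULL, annotations,
                            image_path = NA_character_,
                            patient_id = NA_character_) {
  annotations <- validate_annotations(annotations)
  if (!is.null(image)) {
    stopifnot(inherits(image, "radiograph_image"))
    if (any(annotations$x_max > image$width) ||
        any(annotations$y_max > image$height) ||
        any(annotations$x_min < 0) || any(annotations$y_min < 0)) {
      stop("annotation boxes extend outside the image")
    }
  }
  structure(
    list(image = image, annotations = annotations,
         image_path = image_path, patient_id = patient_id),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  dim_str <- if (is.null(x$image)) "image on disk" else
    sprintf("%d x %d", x$image$height, x$image$width)
  cat(sprintf("<annotated_image: %s, %d joints, scores %s>\n",
              dim_str, nrow(x$annotations),
              paste(range(x$annotations$erosion_score), collapse = "-")))
  invisible(x)
}

#' A named dataset split
#'
#' @param name one of `"train"`, `"validation"`, `"test"`.
#' @param items list of [annotated_image()].
#' @return an object of class `dataset_split`.
#' @export
dataset_split <- function(name, items) {
  name <- match.arg(name, c("train", "validation", "test"))
  stopifnot(all(vapply(items, inherits, logical(1), "annotated_image")))
  structure(
    list(name = name, items = items,
         patient_ids = unique(vapply(items, function(i) i$patient_id, character(1)))),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split %s: %d images, %d patients>\n",
              x$name, length(x$items), length(x$patient_ids)))
  invisible(x)
}

#' Resize an annotated image, rescaling its boxes
#'
#' Resamples the image to `target` (height, width) and scales every box
#' coordinate by the per-axis scale factors, the preprocessing applied
#' before batching (default 400 x 400).
#'
#' @param item an [annotated_image()] with a loaded image.
#' @param target `(height, width)` in pixels.
#' @return the resized [annotated_image()].
#' @export
resize_with_boxes <- function(item, target = c(400L, 400L)) {
  stopifnot(inherits(item, "annotated_image"), !is.null(item$image))
  h <- item$image$height; w <- item$image$width
  sy <- target[1L] / h; sx <- target[2L] / w
  px <- if (sx == 1 && sy == 1) item$image$pixels else
    warp_affine(item$image$pixels, affine_scale(sx, sy), out_size = target)
  ann <- item$annotations
  ann$x_min <- ann$x_min * sx; ann$x_max <- ann$x_max * sx
  ann$y_min <- ann$y_min * sy; ann$y_max <- ann$y_max * sy
  annotated_image(
    radiograph_image(px, source_id = item$image$source_id,
                     window_center = item$image$window_center,
                     window_width = item$image$window_width),
    ann, image_path = item$image_path, patient_id = item$patient_id
  )
}

#' Read an annotation table
#'
#' One delimited table (CSV) describes a whole dataset: columns
#' `image_path, patient_id, joint_id, x_min, y_min, x_max, y_max,
#' erosion_score`, one row per joint. Rows are grouped by `image_path` into
#' [annotated_image()] objects; images themselves stay on disk.
#'
#' @param path CSV file path.
#' @param load_images if `TRUE`, read each referenced image (paths resolved
#'   relative to the table's directory).
#' @return list of [annotated_image()].
#' @export
read_annotations <- function(path, load_images = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_path", "joint_id", "x_min", "y_min", "x_max", "y_max",
                "erosion_score")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("annotation table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$patient_id)) tab$patient_id <- tab$image_path
  base_dir <- dirname(path)
  items <- lapply(split(tab, tab$image_path), function(g) {
    rownames(g) <- NULL
    ann <- validate_annotations(
      g[, c("joint_id", "x_min", "y_min", "x_max", "y_max", "erosion_score")],
      where = paste0("annotations for ", g$image_path[1L])
    )
    img <- NULL
    if (load_images) {
      img_path <- g$image_path[1L]
      if (!file.exists(img_path)) img_path <- file.path(base_dir, g$image_path[1L])
      img <- read_image(img_path)
    }
    annotated_image(img, ann, image_path = g$image_path[1L],
                    patient_id = g$patient_id[1L])
  })
  unname(items[unique(tab$image_path)])
}

#' Write an annotation table
#'
#' Inverse of [read_annotations()]: integer fields round-trip bit-exactly.
#'
#' @param items list of [annotated_image()].
#' @param path output CSV path.
#' @export
write_annotations <- function(items, path) {
  rows <- lapply(items, function(it) {
    cbind(image_path = it$image_path, patient_id = it$patient_id,
          it$annotations)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export annotations as COCO-style detection JSON
#'
#' Interoperability exporter: images, categories (erosion scores 0-5) and
#' annotations with `[x, y, width, height]` boxes.
#'
#' @param items list of [annotated_image()].
#' @param path output JSON path.
#' @export
write_coco_json <- function(items, path) {
  images <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    list(id = i, file_name = it$image_path,
         height = if (!is.null(it$image)) it$image$height else NA,
         width = if (!is.null(it$image)) it$image$width else NA)
  })
  anns <- list(); k <- 0L
  for (i in seq_along(items)) {
    a <- items[[i]]$annotations
    for (r in seq_len(nrow(a))) {
      k <- k + 1L
      anns[[k]] <- list(
        id = k, image_id = i, category_id = a$erosion_score[r],
        joint_id = a$joint_id[r],
        bbox = c(a$x_min[r], a$y_min[r],
                 a$x_max[r] - a$x_min[r], a$y_max[r] - a$y_min[r]),
        area = (a$x_max[r] - a$x_min[r]) * (a$y_max[r] - a$y_min[r]),
        iscrowd = 0L
      )
    }
  }
  categories <- lapply(0:5, function(s) {
    list(id = s, name = paste0("erosion_", s), supercategory = "joint")
  })
  jsonlite::write_json(
    list(images = images, annotations = anns, categories = categories),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
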