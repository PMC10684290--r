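#' Point-annotation set for one image
#'
#' A `point_set` holds the object-center annotations of a single image: one
#' continuous (x, y) coordinate per object. Coordinates are 0-based with the
#' pixel-center convention, so valid x lie in `[0, width)` and valid y in
#' `[0, height)`. The number of points is the image's true object count and
#' the target integral of its ground-truth density map.
#'
#' @param image_id character identifier of the image.
#' @param width,height image dimensions in pixels (positive integers).
#' @param points numeric matrix with columns `x` and `y` (or `NULL` / 0-row
#'   for an unannotated empty image).
#' @return An object of class `point_set`.
#' @examples
#' ps <- point_set("img1", 64, 64, cbind(x = c(10, 20.5), y = c(30, 40)))
#' n_points(ps)
#' @export
point_set <- function(image_id, width, height, points = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(length(width) == 1, length(height) == 1, width > 0, height > 0)
  if (is.null(points) || length(points) == 0) {
    points <- matrix(numeric(0), ncol = 2)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("`points` must have two columns (x, y)")
  colnames(points) <- c("x", "y")
  storage.mode(points) <- "double"
  if (nrow(points) > 0) {
    bad <- points[, "x"] < 0 | points[, "x"] >= width |
      points[, "y"] < 0 | points[, "y"] >= height
    if (any(bad)) {
      stop(sprintf(
        "point(s) outside the %d x %d image at row(s): %s",
        width, height, paste(which(bad), collapse = ", ")
      ))
    }
  }
  structure(
    list(image_id = as.character(image_id), width = width, height = height,
         points = points),
    class = "point_set"
  )
}

#' Number of annotated points
#'
#' @param ps a [point_set()].
#' @return Integer count of annotations.
#' @export
n_points <- function(ps) {
  stopifnot(inherits(ps, "point_set"))
  nrow(ps$points)
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %s: %d points on %d x %d image\n",
              x$image_id, n_points(x), x$width, x$height))
  invisible(x)
}

#' Read point annotations from Labelme JSON or CSV
#'
#' Accepts the two annotation formats produced by common point-labeling
#' workflows: Labelme-style JSON (shapes with `shape_type = "point"`, or
#' single-vertex polygons) and a plain 2-column CSV with an `x,y` header.
#' Labelme files carry the image size; for CSV, `width` and `height` must be
#' supplied. All coordinates are validated against the image bounds.
#'
#' @param file path to a `.json` or `.csv` annotation file.
#' @param width,height image size in pixels; required for CSV, and used to
#'   override the embedded size for JSON when given.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [point_set()].
#' @export
read_points <- function(file, width = NULL, height = NULL, image_id = NULL) {
  if (!file.exists(file)) stop("annotation file not found: ", file)
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(file))
  ext <- tolower(tools::file_ext(file))
  if (ext == "json") {
    doc <- tryCatch(jsonlite::read_json(file),
                    error = function(e) stop("malformed Labelme JSON in ", file,
                                             ": ", conditionMessage(e)))
    if (is.null(width)) width <- doc$imageWidth
    if (is.null(height)) height <- doc$imageHeight
    if (is.null(width) || is.null(height)) {
      stop("image size missing: no imageWidth/imageHeight in ", file)
    }
    pts <- lapply(doc$shapes, function(s) {
      p <- s$points
      if (length(p) != 1) {
        stop("shape in ", file, " is not a single point (", length(p),
             " vertices)")
      }
      as.numeric(unlist(p[[1]]))
    })
    pts <- if (length(pts)) do.call(rbind, pts) else NULL
    point_set(image_id, width, height, pts)
  } else if (ext == "csv") {
    if (is.null(width) || is.null(height)) {
      stop("width and height must be given for CSV annotations")
    }
    df <- tryCatch(utils::read.csv(file),
                   error = function(e) stop("malformed CSV in ", file, ": ",
                                            conditionMessage(e)))
    if (!all(c("x", "y") %in% names(df))) {
      stop("CSV ", file, " must have an 'x,y' header")
    }
    point_set(image_id, width, height, cbind(x = df$x, y = df$y))
  } else {
    stop("unsupported annotation format: .", ext)
  }
}

#' Write point annotations
#'
#' `write_points_csv()` writes the plain `x,y` CSV form;
#' `write_points_json()` writes a Labelme-style JSON file with one
#' `shape_type = "point"` entry per annotation. Both round-trip through
#' [read_points()] without coordinate loss.
#'
#' @param ps a [point_set()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_points_csv <- function(ps, file) {
  stopifnot(inherits(ps, "point_set"))
  utils::write.csv(as.data.frame(ps$points), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_points_csv
#' @export
write_points_json <- function(ps, file) {
  stopifnot(inherits(ps, "point_set"))
  shapes <- lapply(seq_len(n_points(ps)), function(i) {
    list(label = "object",
         points = list(as.numeric(ps$points[i, ])),
         shape_type = "point")
  })
  doc <- list(version = "5.0.0",
              shapes = shapes,
              imagePath = paste0(ps$image_id, ".png"),
              imageWidth = ps$width,
              imageHeight = ps$height)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
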