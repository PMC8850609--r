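# Shared image/annotation data types, file I/O and the IoU metric.
#
# Conventions used across the whole package:
#  * pixel coordinates are 1-based (row, col), origin at the top-left;
#  * visible images are H x W x 3 arrays with intensities in [0, 1];
#  * thermal images are H x W matrices of temperatures in degrees Celsius;
#  * bounding boxes are c(min_row, min_col, height, width), covering rows
#    min_row .. min_row + height - 1 and likewise for columns.

#' Construct a visible-spectrum image
#'
#' @param pixels H x W x 3 numeric array of intensities in `[0, 1]`.
#' @return The validated array, classed `"visible_image"`.
#' @export
visible_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    stop_thermoprick("visible image must be an H x W x 3 array")
  if (d[1] < 1 || d[2] < 1) stop_thermoprick("visible image must be non-empty")
  if (!all(is.finite(pixels))) stop_thermoprick("visible image contains non-finite values")
  structure(pixels, class = "visible_image")
}

#' Construct a thermal image
#'
#' @param pixels H x W numeric matrix of per-pixel temperatures in degrees
#'   Celsius.
#' @return The validated matrix, classed `"thermal_image"`.
#' @export
thermal_image <- function(pixels) {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop_thermoprick("thermal image must be a non-empty matrix")
  if (!all(is.finite(pixels))) stop_thermoprick("thermal image contains non-finite values")
  structure(pixels, class = "thermal_image")
}

#' Bundle a pixel-correlated visible/thermal image pair
#'
#' The acquisition device records both spectra simultaneously, so within one
#' series the two images are correlated at the pixel level and must have
#' identical height and width.
#'
#' @param visible H x W x 3 array (see [visible_image()]).
#' @param thermal H x W matrix in degrees Celsius (see [thermal_image()]).
#' @param series `"pre"` (before allergen application) or `"post"`
#'   (15 minutes after).
#' @return An object of class `"image_bundle"` with elements `visible`,
#'   `thermal` and `series`.
#' @export
image_bundle <- function(visible, thermal, series = c("pre", "post")) {
  series <- match.arg(series)
  visible <- unclass(visible_image(visible))
  thermal <- unclass(thermal_image(thermal))
  if (!identical(dim(visible)[1:2], dim(thermal)))
    stop_thermoprick("pixel correlation violated: visible is ",
                     paste(dim(visible)[1:2], collapse = "x"), " but thermal is ",
                     paste(dim(thermal), collapse = "x"))
  structure(list(visible = visible, thermal = thermal, series = series),
            class = "image_bundle")
}

#' @export
print.image_bundle <- function(x, ...) {
  d <- dim(x$visible)
  cat(sprintf("<image_bundle: %s series, %d x %d px, thermal %.1f..%.1f degC>\n",
              x$series, d[1], d[2], min(x$thermal), max(x$thermal)))
  invisible(x)
}

# minimal single-strip uncompressed float32 TIFF writer (little-endian);
# tiff::writeTIFF cannot store values outside [0, 1], which rules it out for
# temperatures in degC.  tiff::readTIFF reads this container natively.
write_float_tiff <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  nbytes <- 4L * h * w
  ifd_offset <- data_offset + nbytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")  # row-major
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tags <- list(
    c(256, 4, w), c(257, 4, h), c(258, 3, 32), c(259, 3, 1), c(262, 3, 1),
    c(273, 4, data_offset), c(277, 3, 1), c(278, 4, h), c(279, 4, nbytes),
    c(339, 3, 3))  # SampleFormat = IEEE floating point
  writeBin(length(tags), con, size = 2, endian = "little")
  for (t in tags) tag(t[1], t[2], 1, t[3])
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

read_thermal_file <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.matrix(read.csv(path, header = FALSE))
  } else {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  }
}

write_thermal_file <- function(m, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.table(format(m, digits = 9, trim = TRUE), path, sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    write_float_tiff(m, path)
  }
  invisible(path)
}

#' Read a visible/thermal image pair from disk
#'
#' The visible image is an 8-bit RGB PNG or TIFF; the thermal image is a
#' single-channel float32 TIFF holding degrees Celsius directly (no
#' scale/offset), or a headerless CSV grid as plain-text fallback.
#'
#' @param visible_path Path to the visible-spectrum image (PNG or TIFF).
#' @param thermal_path Path to the thermal image (TIFF or CSV).
#' @param series Series tag, `"pre"` or `"post"`.
#' @return An [image_bundle()].
#' @export
read_bundle <- function(visible_path, thermal_path, series = c("pre", "post")) {
  series <- match.arg(series)
  if (!file.exists(visible_path)) stop_thermoprick("cannot read ", visible_path)
  if (!file.exists(thermal_path)) stop_thermoprick("cannot read ", thermal_path)
  vis <- if (grepl("\\.png$", visible_path, ignore.case = TRUE)) {
    png::readPNG(visible_path)
  } else {
    tiff::readTIFF(visible_path)
  }
  if (length(dim(vis)) == 3 && dim(vis)[3] == 4) vis <- vis[, , 1:3]  # drop alpha
  th <- read_thermal_file(thermal_path)
  image_bundle(vis, th, series)
}

#' Write a visible/thermal image pair to disk
#'
#' @param bundle An [image_bundle()].
#' @param visible_path Output PNG path for the visible image.
#' @param thermal_path Output TIFF (float32) or CSV path for the thermal image.
#' @return The bundle, invisibly.
#' @export
write_bundle <- function(bundle, visible_path, thermal_path) {
  stopifnot(inherits(bundle, "image_bundle"))
  png::writePNG(bundle$visible, visible_path)
  write_thermal_file(bundle$thermal, thermal_path)
  invisible(bundle)
}

#' Intersection over union of two binary masks
#'
#' Computes `|A intersect B| / |A union B|`.  When both masks are empty the
#' ratio is defined as 1 (identity semantics for the degenerate case).
#'
#' @param mask_a,mask_b Logical or 0/1 matrices of identical shape.
#' @return A ratio in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_thermoprick("iou: mask shapes differ")
  a <- mask_a > 0.5
  b <- mask_b > 0.5
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Construct a marker annotation
#'
#' A manual annotation of one allergen application site: the injection point
#' and a point on the highlighter marker edge.  The implied mask radius is the
#' distance between the two points.
#'
#' @param injection_point Numeric `(row, col)` of the injection point.
#' @param marker_point Numeric `(row, col)` of a point on the marker edge;
#'   must differ from `injection_point`.
#' @param shape `"circle"` or `"square"` (square marks the histamine control).
#' @param site_id Identifier (allergen name or control type).
#' @return An object of class `"marker_annotation"`.
#' @export
marker_annotation <- function(injection_point, marker_point,
                              shape = c("circle", "square"), site_id = "") {
  shape <- match.arg(shape)
  injection_point <- as.numeric(injection_point)
  marker_point <- as.numeric(marker_point)
  if (length(injection_point) != 2 || length(marker_point) != 2)
    stop_thermoprick("annotation points must be (row, col) pairs")
  if (all(marker_point == injection_point))
    stop_thermoprick("marker_point must differ from injection_point")
  structure(list(injection_point = injection_point, marker_point = marker_point,
                 shape = shape, site_id = as.character(site_id)),
            class = "marker_annotation")
}

annotation_radius <- function(a) sqrt(sum((a$marker_point - a$injection_point)^2))

#' Read or write marker annotations (JSON)
#'
#' One JSON file per image, a list of objects with fields `site_id`, `shape`,
#' `injection_point` and `marker_point`.
#'
#' @param path JSON file path.
#' @return For `read_annotations`, a list of [marker_annotation()] objects.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    marker_annotation(unlist(raw$injection_point[i]), unlist(raw$marker_point[i]),
                      raw$shape[i], raw$site_id[i]))
}

#' @param annotations List of [marker_annotation()] objects.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(site_id = vapply(annotations, `[[`, "", "site_id"),
                   shape = vapply(annotations, `[[`, "", "shape"))
  df$injection_point <- lapply(annotations, `[[`, "injection_point")
  df$marker_point <- lapply(annotations, `[[`, "marker_point")
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a patient interview record
#'
#' @param patient_id Identifier.
#' @param sex `"M"` or `"F"`.
#' @param age Years (> 0).
#' @param weight Kilograms (> 0).
#' @param height Centimetres.
#' @param body_temperature Degrees Celsius, within (30, 45).
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, sex, age, weight, height, body_temperature) {
  sex <- match.arg(sex, c("M", "F"))
  if (!is.numeric(age) || age <= 0) stop_thermoprick("age must be positive")
  if (!is.numeric(weight) || weight <= 0) stop_thermoprick("weight must be positive")
  if (!is.numeric(body_temperature) || body_temperature <= 30 || body_temperature >= 45)
    stop_thermoprick("body_temperature must lie in (30, 45) degC")
  structure(list(patient_id = as.character(patient_id), sex = sex, age = age,
                 weight = weight, height = height,
                 body_temperature = body_temperature),
            class = "patient_record")
}

#' Construct a detected or inferred application-site segment
#'
#' @param center Numeric `(row, col)` centre of the site.
#' @param bbox Numeric `(min_row, min_col, height, width)` bounding box;
#'   must contain the centre.
#' @param grid_index Optional `c(line, position)` with line in `{1, 2}` and
#'   position in `{1, .., 4}` (left to right).
#' @param provenance `"detected"` (from segmentation) or `"inferred"`
#'   (filled in by grid completion).
#' @return An object of class `"prick_segment"`.
#' @export
prick_segment <- function(center, bbox, grid_index = NULL,
                          provenance = c("detected", "inferred")) {
  provenance <- match.arg(provenance)
  center <- as.numeric(center)
  bbox <- as.numeric(bbox)
  if (length(center) != 2 || length(bbox) != 4)
    stop_thermoprick("segment needs center (row, col) and bbox (min_row, min_col, h, w)")
  if (bbox[3] <= 0 || bbox[4] <= 0) stop_thermoprick("segment bbox extents must be positive")
  if (center[1] < bbox[1] || center[1] > bbox[1] + bbox[3] - 1 ||
      center[2] < bbox[2] || center[2] > bbox[2] + bbox[4] - 1)
    stop_thermoprick("segment bbox must contain its center")
  if (!is.null(grid_index)) {
    grid_index <- as.integer(grid_index)
    stopifnot(length(grid_index) == 2)
  }
  structure(list(center = center, bbox = bbox, grid_index = grid_index,
                 provenance = provenance),
            class = "prick_segment")
}

#' @export
print.prick_segment <- function(x, ...) {
  gi <- if (is.null(x$grid_index)) "-" else paste(x$grid_index, collapse = ",")
  cat(sprintf("<segment %s at (%.1f, %.1f), bbox %dx%d, grid %s>\n",
              x$provenance, x$center[1], x$center[2],
              round(x$bbox[3]), round(x$bbox[4]), gi))
  invisible(x)
}

#' Read or write per-site diagnosis labels (CSV)
#'
#' Columns: `patient_id`, `forearm`, `site_id`, `label` (0 = no reaction,
#' 1 = allergic reaction).
#'
#' @param path CSV path.
#' @return For `read_labels`, a data frame.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "forearm", "site_id", "label") %in% names(df)),
            all(df$label %in% c(0, 1)))
  df
}

#' @param labels Data frame with the columns above.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
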