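# Marker-site segmentation: mask construction from manual annotations,
# contour extraction and filtering of U-Net predictions, and the
# grid-completion heuristic for undetected markers.

#' Rasterise marker annotations into a binary training mask
#'
#' Each application site becomes a filled disc around the injection point
#' with radius equal to the distance to the marker-edge point, clipped at the
#' image border.  Square (histamine) markers are rendered as discs too — a
#' deliberate simplification; the downstream contour filter tolerates it.
#'
#' @param annotations List of [marker_annotation()]s.
#' @param image_size `(height, width)` in pixels.
#' @return A logical H x W matrix.
#' @export
annotations_to_mask <- function(annotations, image_size) {
  if (length(image_size) != 2 || any(image_size < 1))
    stop_thermoprick("image_size must be positive (height, width)")
  h <- image_size[1]; w <- image_size[2]
  mask <- matrix(FALSE, h, w)
  for (a in annotations) {
    r <- annotation_radius(a)
    cr <- a$injection_point[1]; cc <- a$injection_point[2]
    rows <- max(1, floor(cr - r)):min(h, ceiling(cr + r))
    cols <- max(1, floor(cc - r)):min(w, ceiling(cc + r))
    d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    mask[rows, cols] <- mask[rows, cols] | (d2 <= r^2)
  }
  mask
}

#' Contour filter for candidate marker segments
#'
#' Detected connected components are kept only when their bounding box looks
#' like a marker.  The side range defaults to the observed segment-size
#' statistics at native scale (mean 85 px, sd 6, min 60, max 104) widened by
#' roughly 10%; boxes are compared after rescaling the range by
#' `image_width / reference_width`, so the same filter works at any
#' resolution.
#'
#' @param bbox_side_range Acceptable bounding-box side lengths, pixels at
#'   `reference_width` scale.
#' @param aspect_ratio_range Acceptable height/width ratio.
#' @param reference_width Image width at which `bbox_side_range` is
#'   expressed (native acquisition width by default).
#' @return An object of class `"contour_filter"`.
#' @export
contour_filter <- function(bbox_side_range = c(54, 114),
                           aspect_ratio_range = c(0.6, 1.67),
                           reference_width = 1024) {
  stopifnot(length(bbox_side_range) == 2, bbox_side_range[1] > 0,
            bbox_side_range[2] > bbox_side_range[1],
            length(aspect_ratio_range) == 2, aspect_ratio_range[1] > 0,
            aspect_ratio_range[2] > aspect_ratio_range[1])
  structure(list(bbox_side_range = bbox_side_range,
                 aspect_ratio_range = aspect_ratio_range,
                 reference_width = reference_width),
            class = "contour_filter")
}

#' Extract marker segments from a probability mask
#'
#' Binarises the mask, labels 4-connected components, computes bounding
#' boxes, and keeps components whose box sides and aspect ratio pass the
#' [contour_filter()].  Segment centres are bounding-box centres.
#'
#' @param prob_mask H x W matrix of marker probabilities in `[0, 1]` (or a
#'   binary mask).
#' @param threshold Binarisation threshold (default 0.5).
#' @param filter A [contour_filter()].
#' @return A list of [prick_segment()]s with provenance `"detected"`
#'   (possibly empty).
#' @export
extract_segments <- function(prob_mask, threshold = 0.5, filter = contour_filter()) {
  stopifnot(inherits(filter, "contour_filter"))
  bin <- prob_mask >= threshold
  if (!any(bin)) return(list())
  lab <- cpp_label_components(bin)
  scale <- ncol(prob_mask) / filter$reference_width
  lo <- filter$bbox_side_range[1] * scale
  hi <- filter$bbox_side_range[2] * scale
  segs <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
    cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
    hh <- rmax - rmin + 1; ww <- cmax - cmin + 1
    ar <- hh / ww
    if (hh < lo || hh > hi || ww < lo || ww > hi) next
    if (ar < filter$aspect_ratio_range[1] || ar > filter$aspect_ratio_range[2]) next
    segs[[length(segs) + 1]] <-
      prick_segment(center = c((rmin + rmax) / 2, (cmin + cmax) / 2),
                    bbox = c(rmin, cmin, hh, ww))
  }
  segs
}

#' Complete a partially detected 2 x 4 marker grid
#'
#' Detected segments are split into two lines by their row coordinate
#' (threshold at the midpoint of the row range), ordered by column within
#' each line, and anchored at the rightmost detected marker of each line
#' ("offset from the right side").  The minimal-length displacement vector
#' between detected neighbours serves as the grid pitch for position
#' assignment; missing positions are then synthesised from a per-line
#' least-squares fit of detected centres on their assigned positions (which
#' averages out per-marker jitter that a single displacement vector cannot),
#' with a bounding box of the median detected size and provenance
#' `"inferred"`.
#'
#' @param segments List of detected [prick_segment()]s (>= 4, spanning both
#'   lines).
#' @param expected `(n_lines, n_per_line)`, default `c(2, 4)`.
#' @param pitch `"within_line"` (default: shortest displacement between
#'   within-line neighbours) or `"global"` (shortest over all detected
#'   pairs) — two readings of "minimal length vector between the positioned
#'   segments".
#' @param image_size Optional `(height, width)` of the source image.  When
#'   the rightmost marker of *both* lines is undetected, anchoring at the
#'   rightmost detection alone shifts every assignment by one position; the
#'   application protocol centres the grid on the forearm frame, so when the
#'   image size is known the shift that best centres the completed grid is
#'   chosen.
#' @return A list of exactly `n_lines * n_per_line` segments ordered by
#'   `(line, position)`, every one carrying a `grid_index`.
#' @export
complete_grid <- function(segments, expected = c(2, 4),
                          pitch = c("within_line", "global"),
                          image_size = NULL) {
  pitch <- match.arg(pitch)
  n_lines <- expected[1]; n_pos <- expected[2]
  if (length(segments) < 4)
    stop_thermoprick("incomplete grid: only ", length(segments),
                     " segments detected (need >= 4); fall back to manual annotation")
  centres <- t(vapply(segments, `[[`, numeric(2), "center"))
  split_row <- (max(centres[, 1]) + min(centres[, 1])) / 2
  line_of <- ifelse(centres[, 1] <= split_row, 1L, 2L)
  if (length(unique(line_of)) < n_lines)
    stop_thermoprick("incomplete grid: all detected segments lie in one line")

  # grid pitch: minimal-length displacement between column-adjacent detected
  # segments, per line or globally
  cand <- list()
  if (pitch == "within_line") {
    for (ln in 1:n_lines) {
      idx <- which(line_of == ln)
      if (length(idx) < 2) next
      ord <- idx[order(centres[idx, 2])]
      for (i in seq_len(length(ord) - 1))
        cand[[length(cand) + 1]] <- centres[ord[i + 1], ] - centres[ord[i], ]
    }
  } else {
    for (i in seq_len(nrow(centres) - 1)) for (j in (i + 1):nrow(centres))
      cand[[length(cand) + 1]] <- centres[j, ] - centres[i, ]
  }
  if (!length(cand))
    stop_thermoprick("incomplete grid: no within-line neighbours to estimate pitch")
  lens <- vapply(cand, function(v) sqrt(sum(v^2)), 0)
  v_pitch <- cand[[which.min(lens)]]
  # the minimal vector may span one or more grid steps; a single step cannot
  # be shorter than the minimum observed, so treat it as one pitch unit
  if (v_pitch[2] < 0) v_pitch <- -v_pitch

  med_h <- median(vapply(segments, function(s) s$bbox[3], 0))
  med_w <- median(vapply(segments, function(s) s$bbox[4], 0))

  # shared right anchor: the rightmost detected marker across both lines
  # defines the position-n_pos column; anchoring each line at its own
  # rightmost detection would shift a whole line whenever its rightmost
  # marker is among the dropped ones
  anchor_col <- max(centres[, 2])
  anchor_pos <- n_pos
  if (!is.null(image_size)) {
    # both rightmost markers may be undetected; choose the anchor position
    # whose completed grid sits most symmetrically in the frame
    asym <- vapply(c(n_pos, n_pos - 1L), function(ap) {
      cols <- anchor_col - (ap - seq_len(n_pos)) * v_pitch[2]
      abs((min(cols) - 1) - (image_size[2] - max(cols)))
    }, 0)
    anchor_pos <- c(n_pos, n_pos - 1L)[which.min(asym)]
  }

  out <- vector("list", n_lines * n_pos)
  for (ln in 1:n_lines) {
    idx <- which(line_of == ln)
    ord <- idx[order(centres[idx, 2])]
    # positions by column offset from the shared right anchor
    pos <- integer(length(ord))
    for (i in seq_along(ord)) {
      off <- (anchor_col - centres[ord[i], 2]) / v_pitch[2]
      pos[i] <- anchor_pos - as.integer(round(off))
    }
    if (anyDuplicated(pos) || any(pos < 1) || any(pos > n_pos))
      stop_thermoprick("incomplete grid: detected segments are inconsistent with a ",
                       n_lines, "x", n_pos, " layout")
    for (i in seq_along(ord)) {
      s <- segments[[ord[i]]]
      s$grid_index <- as.integer(c(ln, pos[i]))
      out[[(ln - 1) * n_pos + pos[i]]] <- s
    }
  }

  # infill: fit the regular-grid model centre = line_offset + position * pitch
  # (per-line 2-d intercept, pitch shared across lines) by least squares over
  # all detected markers; pooling both lines averages out the per-marker
  # jitter that a single minimal-length vector cannot
  det <- which(!vapply(out, is.null, TRUE))
  if (length(det) < n_lines * n_pos) {
    det_ln <- (det - 1) %/% n_pos + 1
    det_p <- (det - 1) %% n_pos + 1
    det_ctr <- t(vapply(out[det], `[[`, numeric(2), "center"))
    lf <- factor(det_ln, levels = seq_len(n_lines))
    fr <- lm(det_ctr[, 1] ~ lf + det_p)
    fc <- lm(det_ctr[, 2] ~ lf + det_p)
    nd <- data.frame(lf = factor(rep(seq_len(n_lines), each = n_pos),
                                 levels = seq_len(n_lines)),
                     det_p = rep(seq_len(n_pos), n_lines))
    pred <- cbind(predict(fr, nd), predict(fc, nd))
    for (slot in setdiff(seq_len(n_lines * n_pos), det)) {
      ln <- (slot - 1) %/% n_pos + 1
      p <- (slot - 1) %% n_pos + 1
      ctr <- pred[slot, ]
      out[[slot]] <- prick_segment(center = ctr,
                                   bbox = c(ctr[1] - med_h / 2, ctr[2] - med_w / 2,
                                            med_h, med_w),
                                   grid_index = c(ln, p), provenance = "inferred")
    }
  }
  out
}

#' Segments from ground-truth annotations (manual segmentation)
#'
#' Converts manual marker annotations directly into grid-indexed segments,
#' bypassing the U-Net — the "manual segmentation" reference configuration,
#' and the fallback when automatic detection finds too few markers.
#'
#' @param annotations List of [marker_annotation()]s (one grid's worth).
#' @param expected `(n_lines, n_per_line)`.
#' @return A list of grid-indexed [prick_segment()]s ordered by
#'   `(line, position)`.
#' @export
segments_from_annotations <- function(annotations, expected = c(2, 4)) {
  centres <- t(vapply(annotations, `[[`, numeric(2), "injection_point"))
  radii <- vapply(annotations, annotation_radius, 0)
  split_row <- (max(centres[, 1]) + min(centres[, 1])) / 2
  line_of <- ifelse(centres[, 1] <= split_row, 1L, 2L)
  out <- list()
  for (ln in seq_len(expected[1])) {
    idx <- which(line_of == ln)
    ord <- idx[order(centres[idx, 2])]
    for (p in seq_along(ord)) {
      i <- ord[p]
      out[[length(out) + 1]] <-
        prick_segment(center = centres[i, ],
                      bbox = c(centres[i, 1] - radii[i], centres[i, 2] - radii[i],
                               2 * radii[i], 2 * radii[i]),
                      grid_index = c(ln, p), provenance = "detected")
    }
  }
  out
}

#' Per-site IoU between predicted segments and ground-truth annotations
#'
#' Matches each grid-indexed predicted segment to the ground-truth annotation
#' at the same grid slot and computes the intersection-over-union of the two
#' discs (the predicted disc has radius equal to the mean bounding-box
#' half-side; the ground-truth disc radius is the annotation's
#' injection-to-marker distance), rasterised over a window covering both.
#'
#' @param segments Grid-indexed segments (see [complete_grid()]).
#' @param annotations Ground-truth [marker_annotation()]s for the same image.
#' @param expected Grid layout.
#' @return Numeric vector of per-site IoU values (one per grid slot).
#' @export
per_site_iou <- function(segments, annotations, expected = c(2, 4)) {
  gt <- segments_from_annotations(annotations, expected)
  key <- function(s) paste(s$grid_index, collapse = ",")
  gk <- vapply(gt, key, "")
  vapply(segments, function(s) {
    g <- gt[[match(key(s), gk)]]
    r_pred <- (s$bbox[3] + s$bbox[4]) / 4
    r_gt <- g$bbox[3] / 2
    lim <- ceiling(max(r_pred, r_gt) + 2)
    rows <- (floor(min(s$center[1], g$center[1])) - lim):(ceiling(max(s$center[1], g$center[1])) + lim)
    cols <- (floor(min(s$center[2], g$center[2])) - lim):(ceiling(max(s$center[2], g$center[2])) + lim)
    gr <- outer(rows, cols * 0, `+`)
    gc <- outer(rows * 0, cols, `+`)
    a <- (gr - s$center[1])^2 + (gc - s$center[2])^2 <= r_pred^2
    b <- (gr - g$center[1])^2 + (gc - g$center[2])^2 <= r_gt^2
    iou(a, b)
  }, 0)
}

#' Segment one visible image end to end
#'
#' Runs the U-Net, extracts and filters contours, and completes the marker
#' grid.  When fewer than four markers are detected (or grid completion
#' fails) and ground-truth annotations are supplied, the image is routed to
#' the manual-annotation fallback.
#'
#' @param model A trained [build_unet()] model.
#' @param visible H x W x 3 visible image.
#' @param filter A [contour_filter()].
#' @param threshold Mask binarisation threshold.
#' @param annotations_fallback Optional list of [marker_annotation()]s.
#' @param expected Grid layout.
#' @return A list with `segments` (grid-indexed), `source` (`"unet"` or
#'   `"manual"`) and `n_detected`.
#' @export
segment_image <- function(model, visible, filter = contour_filter(),
                          threshold = 0.5, annotations_fallback = NULL,
                          expected = c(2, 4)) {
  pm <- predict_mask(model, visible)
  det <- extract_segments(pm, threshold, filter)
  res <- tryCatch(
    list(segments = complete_grid(det, expected, image_size = dim(visible)[1:2]),
         source = "unet", n_detected = length(det)),
    error = function(e) e)
  if (!inherits(res, "error")) return(res)
  if (is.null(annotations_fallback)) stop(res)
  list(segments = segments_from_annotations(annotations_fallback, expected),
       source = "manual", n_detected = length(det))
}
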