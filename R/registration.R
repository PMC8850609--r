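# Alignment of pre-application to post-application thermal images from
# matched marker sets, and delta-image construction.
#
# Two estimators mirror the two alignment techniques of the reading pipeline:
# a least-squares homography from >= 4 marker correspondences (normalized
# DLT) and a lower-degree-of-freedom rigid transform derived from regression
# lines fitted through each marker set.

#' Construct a planar transform
#'
#' @param matrix 3 x 3 homogeneous matrix acting on `(row, col, 1)` column
#'   vectors, mapping pre-series to post-series pixel coordinates.
#' @param kind `"homography"` or `"rigid"`.  Rigid transforms must have an
#'   orthonormal upper-left 2 x 2 block with determinant +1.
#' @return An object of class `"planar_transform"`.
#' @export
planar_transform <- function(matrix, kind = c("homography", "rigid")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)), all(is.finite(matrix)))
  if (abs(det(matrix)) < 1e-12) stop_thermoprick("transform matrix is singular")
  if (kind == "rigid") {
    Rm <- matrix[1:2, 1:2]
    if (max(abs(t(Rm) %*% Rm - diag(2))) > 1e-6 || det(Rm) < 0)
      stop_thermoprick("rigid transform needs an orthonormal rotation block with det +1")
    if (max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-9)
      stop_thermoprick("rigid transform must be affine (last row 0 0 1)")
  }
  structure(list(matrix = matrix, kind = kind), class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform %s>\n", x$kind))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Apply a planar transform to points
#'
#' @param transform A [planar_transform()].
#' @param points N x 2 matrix of `(row, col)` coordinates.
#' @return N x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points)  # accept a single (row, col) vector
  ph <- transform$matrix %*% rbind(t(points), 1)
  t(ph[1:2, , drop = FALSE]) / ph[3, ]
}

#' Pair detected markers between series by grid index
#'
#' Marker correspondence uses the completed grid indices, the only reliable
#' matching key once both series have been segmented: nearest-neighbour
#' matching would fail exactly in the large-motion cases registration exists
#' for.
#'
#' @param pre_segments,post_segments Lists of 8 [prick_segment()]s, each
#'   carrying a `grid_index` (see [complete_grid()]).
#' @return A list with `pre` and `post`, two N x 2 matrices of corresponding
#'   centres in matching row order.
#' @export
match_markers <- function(pre_segments, post_segments) {
  key <- function(segs) {
    gi <- lapply(segs, `[[`, "grid_index")
    if (any(vapply(gi, is.null, TRUE)))
      stop_thermoprick("correspondence error: segments without grid_index")
    vapply(gi, function(g) paste(g, collapse = ","), "")
  }
  k1 <- key(pre_segments); k2 <- key(post_segments)
  if (anyDuplicated(k1) || anyDuplicated(k2) || !setequal(k1, k2))
    stop_thermoprick("correspondence error: grid indices do not match one-to-one")
  ord <- match(sort(k1), k1)
  ord2 <- match(sort(k1), k2)
  pre <- t(vapply(pre_segments[ord], `[[`, numeric(2), "center"))
  post <- t(vapply(post_segments[ord2], `[[`, numeric(2), "center"))
  if (nrow(pre) < 4) stop_thermoprick("correspondence error: fewer than 4 pairs")
  list(pre = pre, post = post)
}

#' Estimate a homography from point correspondences
#'
#' Least-squares estimate by the normalized direct linear transform over all
#' correspondences (no robust reweighting: with eight grid-completed markers,
#' outliers are handled upstream).
#'
#' @param pre_points,post_points N x 2 matrices (N >= 4) of corresponding
#'   `(row, col)` coordinates, not all collinear.
#' @return A [planar_transform()] of kind `"homography"` with attribute
#'   `"residual_rms"`, the reprojection RMS over the input pairs in pixels.
#' @export
estimate_homography <- function(pre_points, post_points) {
  stopifnot(nrow(pre_points) == nrow(post_points))
  n <- nrow(pre_points)
  if (n < 4) stop_thermoprick("estimation error: need >= 4 correspondences")
  collinear <- function(p) {
    cp <- sweep(p, 2, colMeans(p))
    svd(cp)$d[2] < 1e-8 * max(1, svd(cp)$d[1])
  }
  if (collinear(pre_points)) stop_thermoprick("estimation error: degenerate (collinear) points")
  normalize <- function(p) {
    ctr <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    Tn <- matrix(c(sc, 0, 0, 0, sc, 0, -sc * ctr[1], -sc * ctr[2], 1), 3, 3)
    list(T = Tn, p = cbind(sc * (p[, 1] - ctr[1]), sc * (p[, 2] - ctr[2])))
  }
  n1 <- normalize(pre_points)
  n2 <- normalize(post_points)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- c(n1$p[i, ], 1)
    u <- n2$p[i, 1]; v <- n2$p[i, 2]
    A[2 * i - 1, ] <- c(x, 0, 0, 0, -u * x)
    A[2 * i, ] <- c(0, 0, 0, x, -v * x)
  }
  hvec <- svd(A)$v[, 9]
  Hn <- matrix(hvec, 3, 3, byrow = TRUE)
  H <- solve(n2$T) %*% Hn %*% n1$T
  H <- H / H[3, 3]
  tf <- planar_transform(H, "homography")
  proj <- transform_points(tf, pre_points)
  attr(tf, "residual_rms") <- sqrt(mean(rowSums((proj - post_points)^2)))
  tf
}

# total-least-squares line through points: returns unit direction and centroid
tls_line <- function(p) {
  ctr <- colMeans(p)
  cp <- sweep(p, 2, ctr)
  dir <- svd(cp)$v[, 1]
  list(centroid = ctr, dir = dir)
}

#' Estimate a rigid transform by aligning marker regression lines
#'
#' Fits a least-squares line through each marker set and derives the rigid
#' motion that carries the pre line onto the post line: the rotation is the
#' difference of the two line angles, and the translation carries the
#' projection of the pre-set centroid onto its line (the centroid itself,
#' which lies on the fitted line) to the corresponding point of the post
#' line, so the transformed pre line coincides with the post line.  The line
#' fit minimises orthogonal distance (total least squares, the principal
#' axis of the point set): unlike a row-on-column regression this fit is
#' rotation-equivariant, so marker sets related by an exact rigid motion
#' (rotation below 90 degrees) recover that motion exactly, and the
#' vertical-line case needs no special handling.
#'
#' @param pre_points,post_points N x 2 matrices (N >= 2) of `(row, col)`
#'   marker centres, not all coincident.
#' @return A [planar_transform()] of kind `"rigid"` with attribute
#'   `"residual_rms"`.
#' @export
estimate_rigid_lines <- function(pre_points, post_points) {
  stopifnot(nrow(pre_points) == nrow(post_points), nrow(pre_points) >= 2)
  l1 <- tls_line(pre_points)
  l2 <- tls_line(post_points)
  # orient both directions consistently (positive column component)
  if (l1$dir[2] < 0) l1$dir <- -l1$dir
  if (l2$dir[2] < 0) l2$dir <- -l2$dir
  if (!all(is.finite(l1$dir)) || !all(is.finite(l2$dir)))
    stop_thermoprick("estimation error: degenerate line fit")
  ang <- function(d) atan2(d[2], d[1])
  theta <- ang(l2$dir) - ang(l1$dir)
  theta <- atan2(sin(theta), cos(theta))  # wrap
  if (abs(theta) > pi / 2) theta <- theta - sign(theta) * pi  # direction sign ambiguity
  proj <- function(l) l$centroid  # centroid lies on the least-squares line
  p1 <- proj(l1); p2 <- proj(l2)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Tm <- diag(3)
  Tm[1:2, 1:2] <- R
  Tm[1:2, 3] <- p2 - R %*% p1
  tf <- planar_transform(Tm, "rigid")
  projp <- transform_points(tf, pre_points)
  attr(tf, "residual_rms") <- sqrt(mean(rowSums((projp - post_points)^2)))
  tf
}

#' Warp a pre-series thermal image into the post-series frame
#'
#' Each output pixel is inverse-mapped through the transform and sampled
#' bilinearly from the source; pixels mapping outside the source are 0 and
#' flagged invalid.
#'
#' @param pre H x W thermal matrix (degC), pre series.
#' @param transform [planar_transform()] mapping pre to post coordinates.
#' @param out_shape `(height, width)` of the output, default the input shape.
#' @return A list with `pixels` (warped matrix) and `valid_mask` (logical).
#' @export
warp_thermal <- function(pre, transform, out_shape = dim(pre)) {
  pre <- unclass(pre)
  Minv <- solve(transform$matrix)
  res <- cpp_warp_projective(pre, Minv, out_shape[1], out_shape[2])
  list(pixels = res$pixels, valid_mask = res$valid)
}

#' Delta thermal image: post minus aligned pre
#'
#' The subtraction isolates reaction-induced temperature change; a warming
#' reaction is positive.  Pixels without pre-image support are set to 0 and
#' excluded via the validity mask.
#'
#' @param post H x W post-series thermal matrix (degC).
#' @param pre_aligned Result of [warp_thermal()] with matching shape.
#' @return An object of class `"delta_image"` with `pixels` (degC difference)
#'   and `valid_mask`.
#' @export
delta_image <- function(post, pre_aligned) {
  post <- unclass(post)
  if (!identical(dim(post), dim(pre_aligned$pixels)))
    stop_thermoprick("delta: shape mismatch between post and aligned pre")
  px <- (post - pre_aligned$pixels) * pre_aligned$valid_mask
  structure(list(pixels = px, valid_mask = pre_aligned$valid_mask),
            class = "delta_image")
}

#' Align one case and compute its delta image
#'
#' Convenience wrapper: match markers by grid index, estimate the transform
#' with the chosen technique and subtract.
#'
#' @param pre_thermal,post_thermal H x W thermal matrices.
#' @param pre_segments,post_segments Grid-indexed segment lists.
#' @param method `"homography"` or `"lines"`.
#' @return A list with `delta` ([delta_image()]) and `transform`.
#' @export
align_and_delta <- function(pre_thermal, post_thermal, pre_segments, post_segments,
                            method = c("homography", "lines")) {
  method <- match.arg(method)
  mm <- match_markers(pre_segments, post_segments)
  tf <- if (method == "homography") estimate_homography(mm$pre, mm$post)
        else estimate_rigid_lines(mm$pre, mm$post)
  warped <- warp_thermal(pre_thermal, tf, dim(unclass(post_thermal)))
  list(delta = delta_image(post_thermal, warped), transform = tf)
}
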