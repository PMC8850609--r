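# Marker matching, transform estimation, warping and delta images.

test_that("match_markers pairs by grid index and reports displacements", {
  set.seed(1)
  pre <- complete_grid(make_grid_segments(jitter = 2))
  post <- lapply(pre, function(s) {
    s$center <- s$center + c(5, -3)
    s$bbox[1:2] <- s$bbox[1:2] + c(5, -3)
    s
  })
  mm <- match_markers(pre, post[sample(8)])   # order must not matter
  expect_equal(nrow(mm$pre), 8)
  expect_equal(mm$post - mm$pre, matrix(rep(c(5, -3), each = 8), 8, 2))
  mm2 <- match_markers(pre, pre)
  expect_equal(mm2$post, mm2$pre)

  broken <- pre
  broken[[3]]$grid_index <- NULL
  expect_error(match_markers(broken, post), "correspondence")
  dup <- pre
  dup[[2]]$grid_index <- dup[[1]]$grid_index
  expect_error(match_markers(dup, post), "correspondence")
})

test_that("estimate_homography recovers identity, translation and rigid maps", {
  set.seed(2)
  pts <- centers_of(make_grid_segments(jitter = 4))
  th <- estimate_homography(pts, pts)
  expect_lt(max(abs(th$matrix - diag(3))), 1e-6)

  shifted <- cbind(pts[, 1] + 10, pts[, 2])
  tt <- estimate_homography(pts, shifted)
  expect_lt(max(abs(transform_points(tt, pts) - shifted)), 1e-6)

  theta <- 4 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot <- t(R %*% (t(pts) - colMeans(pts)) + colMeans(pts) + c(7, -2))
  tr <- estimate_homography(pts, rot)
  expect_lt(max(abs(transform_points(tr, pts) - rot)), 1e-6)
  expect_lt(attr(tr, "residual_rms"), 1e-6)

  expect_error(estimate_homography(pts[1:3, ], rot[1:3, ]), ">= 4")
  line <- cbind(1:6, 2 * (1:6) + 3)
  expect_error(estimate_homography(line, line), "collinear")
})

test_that("estimate_rigid_lines recovers shifts and rotations exactly", {
  pts <- centers_of(make_grid_segments())
  ti <- estimate_rigid_lines(pts, pts)
  expect_lt(max(abs(ti$matrix - diag(3))), 1e-6)

  shifted <- cbind(pts[, 1], pts[, 2] + 10)
  ts <- estimate_rigid_lines(pts, shifted)
  expect_lt(abs(atan2(ts$matrix[2, 1], ts$matrix[1, 1])), 1e-9)
  expect_lt(max(abs(transform_points(ts, pts) - shifted)), 1e-6)

  theta <- 5 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot <- t(R %*% (t(pts) - colMeans(pts)) + colMeans(pts))
  tr <- estimate_rigid_lines(pts, rot)
  expect_equal(atan2(tr$matrix[2, 1], tr$matrix[1, 1]) * 180 / pi, 5,
               tolerance = 1e-6)
  expect_lt(max(abs(transform_points(tr, pts) - rot)), 1e-6)
  # rigid invariant enforced by the constructor
  Rm <- tr$matrix[1:2, 1:2]
  expect_lt(max(abs(t(Rm) %*% Rm - diag(2))), 1e-9)
})

test_that("homography specialises to rigid on rigid-generated correspondences", {
  set.seed(8)
  cfg <- scene_config()
  for (i in 1:5) {
    cs <- generate_case(cfg, i, render = FALSE)
    pre <- centers_of(segments_from_annotations(cs$annotations))
    post <- transform_points(cs$true_transform, pre)
    th <- estimate_homography(pre, post)
    expect_lt(max(abs(transform_points(th, pre) -
                      transform_points(cs$true_transform, pre))), 1e-6)
  }
})

test_that("warp_thermal is exact for identity and integer translations", {
  set.seed(4)
  th <- matrix(rnorm(40 * 50, 33), 40, 50)
  ident <- planar_transform(diag(3), "rigid")
  w <- warp_thermal(th, ident)
  expect_identical(w$pixels, th)
  expect_true(all(w$valid_mask))

  Tm <- diag(3); Tm[2, 3] <- 7           # shift 7 columns (pre -> post)
  tt <- planar_transform(Tm, "rigid")
  w2 <- warp_thermal(th, tt)
  expect_equal(w2$pixels[, 8:50], th[, 1:43])   # bilinear exact at integers
  expect_true(all(!w2$valid_mask[, 1:7]))
  expect_true(all(w2$pixels[, 1:7] == 0))

  Tm3 <- diag(3); Tm3[1:2, 3] <- c(500, 500)    # pushes image out of frame
  w3 <- warp_thermal(th, planar_transform(Tm3, "rigid"))
  expect_true(mean(w3$valid_mask) == 0)
})

test_that("delta_image subtracts where valid and guards shapes", {
  th <- matrix(rnorm(30 * 30, 33), 30, 30)
  w <- warp_thermal(th, planar_transform(diag(3), "rigid"))
  d <- delta_image(th, w)
  expect_true(all(d$pixels == 0))
  expect_error(delta_image(th[1:10, ], w), "shape")
})

test_that("delta of a noiseless positive case equals the truncated Gaussian bump", {
  cfg <- scene_config(noise_sd = 0, visible_noise_sd = 0,
                      hair_density = 0, vessel_count = 0)
  cs <- generate_case(cfg, 12, labels = c(1, rep(0, 7)))
  w <- warp_thermal(cs$pre$thermal, cs$true_transform)
  d <- delta_image(cs$post$thermal, w)
  # reconstruct the analytic bump field on the post frame from the recorded
  # ground-truth hotspot (exactly one: the single positive site)
  expect_equal(nrow(cs$hotspots), 1)
  hs <- cs$hotspots[1, ]
  Tinv <- solve(cs$true_transform$matrix)
  h <- nrow(d$pixels); wd <- ncol(d$pixels)
  sr <- outer(1:h, rep(1, wd)); sc <- outer(rep(1, h), 1:wd)
  src_r <- Tinv[1, 1] * sr + Tinv[1, 2] * sc + Tinv[1, 3]
  src_c <- Tinv[2, 1] * sr + Tinv[2, 2] * sc + Tinv[2, 3]
  d2 <- (src_r - hs["row"])^2 + (src_c - hs["col"])^2
  bump <- hs["amplitude"] * pmax(exp(-d2 / (2 * hs["sigma"]^2)) - exp(-8), 0)
  # bilinear interpolation bounds the residual: max |f''| h^2 / 8 of the
  # bump plus the resampled smooth background
  expect_lt(max(abs(d$pixels - bump)[d$valid_mask]), 5e-3)
  # far from the bump the delta is interpolation error only
  far <- d$valid_mask & (d2 > (5 * hs["sigma"])^2)
  expect_lt(mean(abs(d$pixels[far])), 1e-3)
  # and with no pose change at all the delta is exactly the bump field
  cfg0 <- scene_config(noise_sd = 0, visible_noise_sd = 0, hair_density = 0,
                       vessel_count = 0, pose_max_rotation = 0,
                       pose_max_translation = 0)
  cs0 <- generate_case(cfg0, 12, labels = c(1, rep(0, 7)))
  d0 <- cs0$post$thermal - cs0$pre$thermal
  expect_gte(min(d0), 0)
  expect_equal(max(d0), cfg0$hotspot_amplitude * (1 - exp(-8)), tolerance = 0.16)
})
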