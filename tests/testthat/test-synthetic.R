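# Synthetic forearm generator: structure, determinism, ground-truth
# consistency and label statistics.

test_that("a generated case has eight annotated sites with one histamine square", {
  cfg <- tiny_scene()
  cs <- generate_case(cfg, 1)
  expect_length(cs$annotations, 8)
  shapes <- vapply(cs$annotations, `[[`, "", "shape")
  expect_equal(sum(shapes == "square"), 1)
  expect_equal(cs$site_meta$shape[cs$site_meta$role == "histamine"], "square")
  expect_equal(unname(cs$labels["histamine"]), 1L)
  expect_equal(unname(cs$labels["negative_control"]), 0L)
  expect_equal(dim(cs$pre$visible)[1:2], dim(cs$pre$thermal))
  expect_equal(dim(cs$pre$visible), dim(cs$post$visible))
})

test_that("generation is bitwise deterministic given the seeds", {
  cfg <- tiny_scene(seed = 9)
  a <- generate_case(cfg, 4)
  b <- generate_case(cfg, 4)
  expect_identical(a$pre$visible, b$pre$visible)
  expect_identical(a$post$thermal, b$post$thermal)
  expect_identical(a$true_transform$matrix, b$true_transform$matrix)
  c <- generate_case(cfg, 5)
  expect_false(identical(a$pre$thermal, c$pre$thermal))
  # generation does not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(generate_case(cfg, 6)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("true_transform maps pre marker centres onto post centres", {
  cfg <- tiny_scene()
  for (i in 1:5) {
    cs <- generate_case(cfg, i, render = FALSE)
    pre <- t(vapply(cs$annotations, `[[`, numeric(2), "injection_point"))
    post <- t(vapply(cs$annotations_post, `[[`, numeric(2), "injection_point"))
    err <- sqrt(rowSums((transform_points(cs$true_transform, pre) - post)^2))
    expect_lt(max(err), 0.5)
  }
})

test_that("hot spots integrate to the expected mean over the core disc", {
  cfg <- scene_config(hotspot_amplitude = 1.5, noise_sd = 0.05,
                      pose_max_rotation = 0, pose_max_translation = 0)
  cs <- generate_case(cfg, 2, labels = c(1, rep(0, 7)))
  hs <- cs$hotspots[1, ]
  d <- cs$post$thermal - cs$pre$thermal
  h <- nrow(d); w <- ncol(d)
  d2 <- outer((1:h - hs["row"])^2, (1:w - hs["col"])^2, `+`)
  disc <- d2 <= hs["sigma"]^2
  # analytic mean of an amplitude-A Gaussian over a disc of radius sigma is
  # 2 A (1 - exp(-1/2)) ~ 0.787 A; the per-site amplitude factor is >= 0.85 A
  # and residual noise contributes at most 3 sd / sqrt(n)
  mean_delta <- mean(d[disc])
  expect_gt(mean_delta, 0.5)
  expect_gt(mean_delta, 2 * 0.85 * 1.5 * (1 - exp(-0.5)) - exp(-8) -
                        3 * sqrt(2) * cfg$noise_sd / sqrt(sum(disc)) - 0.2)
})

test_that("noiseless, pose-free negative cases have exactly zero thermal delta", {
  cfg <- tiny_scene(noise_sd = 0, visible_noise_sd = 0,
                    pose_max_rotation = 0, pose_max_translation = 0)
  cs <- generate_case(cfg, 3, labels = rep(0, 8))
  expect_identical(cs$post$thermal, cs$pre$thermal)
  # positive sites then differ only inside the truncated bump support
  cs1 <- generate_case(cfg, 3, labels = c(0, 0, 1, rep(0, 5)))
  d <- cs1$post$thermal - cs1$pre$thermal
  hs <- cs1$hotspots[1, ]
  h <- nrow(d); w <- ncol(d)
  d2 <- outer((1:h - hs["row"])^2, (1:w - hs["col"])^2, `+`)
  expect_true(all(d[d2 >= (4 * hs["sigma"])^2] == 0))
  expect_gt(max(d), 1)
})

test_that("dropped markers render at reduced contrast in both series", {
  cfg <- tiny_scene(marker_dropout = 0, noise_sd = 0, visible_noise_sd = 0,
                    hair_density = 0, vessel_count = 0,
                    pose_max_rotation = 0, pose_max_translation = 0)
  base <- generate_case(cfg, 8, labels = rep(0, 8))
  weak <- generate_case(cfg, 8, labels = rep(0, 8), dropped = 1L)
  ring_contrast <- function(cs, i, series = "pre") {
    a <- cs$annotations[[i]]
    px <- cs[[series]]$visible[round(a$marker_point[1]), round(a$marker_point[2]), ]
    ref <- cs[[series]]$visible[3, 3, ]
    sum(abs(px - ref))
  }
  expect_gt(ring_contrast(base, 1), 0.3)            # kept marker: strong ink
  expect_lt(ring_contrast(weak, 1), ring_contrast(base, 1) / 3)
  expect_lt(ring_contrast(weak, 1, "post"), ring_contrast(base, 1, "post") / 3)
  expect_equal(weak$dropped_markers, 1L)
})

test_that("cohorts have the right composition and label statistics", {
  cfg <- tiny_scene()
  co <- generate_cohort(cfg, 4, render = FALSE)
  expect_length(co$cases, 8)
  expect_equal(nrow(co$labels), 4 * 2 * 8)
  expect_equal(nrow(co$patients), 4)
  expect_true(all(co$labels$label[co$labels$role == "histamine"] == 1))
  expect_true(all(co$labels$label[co$labels$role == "negative_control"] == 0))
  # per-patient attributes are shared across that patient's samples
  expect_true(all(table(co$labels$patient_id) == 16))

  # degenerate prevalence: only histamine controls positive
  co0 <- generate_cohort(tiny_scene(prevalence = 0), 3, render = FALSE)
  expect_true(all(co0$labels$label[co0$labels$role != "histamine"] == 0))

  # realized positive fraction of non-control sites: binomial check
  co3 <- generate_cohort(tiny_scene(prevalence = 0.3, seed = 5), 200,
                         render = FALSE)
  frac <- mean(co3$labels$label[co3$labels$role == "allergen"])
  n <- sum(co3$labels$role == "allergen")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("infeasible marker grids are rejected at configuration", {
  expect_error(scene_config(image_size = c(100, 120), inter_marker_spacing = 60),
               "configuration error")
  expect_error(scene_config(prevalence = 1.2), "prevalence")
  expect_error(scene_config(marker_dropout = 1), "marker_dropout")
})

test_that("cohort write/read round-trips the on-disk layout", {
  dir <- tempfile("cohort")
  co <- generate_cohort(tiny_scene(seed = 3), 1)
  write_cohort(co, dir)
  rd <- read_cohort(dir)
  expect_length(rd$cases, 2)
  expect_equal(rd$labels, co$labels)
  i <- which(vapply(rd$cases, `[[`, "", "case_id") == co$cases[[1]]$case_id)
  expect_lt(max(abs(rd$cases[[i]]$pre$thermal - co$cases[[1]]$pre$thermal)), 1e-4)
  expect_equal(rd$cases[[i]]$annotations[[3]]$injection_point,
               co$cases[[1]]$annotations[[3]]$injection_point)
  unlink(dir, recursive = TRUE)
})
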