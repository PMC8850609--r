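# Mask construction, contour extraction/filtering and grid completion.

test_that("annotations_to_mask agrees with brute-force disc membership", {
  a <- marker_annotation(c(100, 100), c(100, 110))
  m <- annotations_to_mask(list(a), c(200, 200))
  # enumeration oracle over a window comfortably containing the disc
  count <- 0
  for (r in 88:112) for (c in 88:112)
    if ((r - 100)^2 + (c - 100)^2 <= 100) count <- count + 1
  expect_equal(sum(m), count)
  expect_true(m[100, 100] && m[100, 110] && !m[100, 111])

  # clipped disc near the border
  a2 <- marker_annotation(c(3, 50), c(13, 50))
  m2 <- annotations_to_mask(list(a2), c(60, 100))
  count2 <- 0
  for (r in 1:13) for (c in 40:60)
    if ((r - 3)^2 + (c - 50)^2 <= 100) count2 <- count2 + 1
  expect_equal(sum(m2), count2)

  expect_equal(sum(annotations_to_mask(list(), c(30, 30))), 0)
  expect_error(annotations_to_mask(list(a), c(0, 10)), "positive")
})

test_that("annotations_to_mask equals enumeration on randomized fixtures", {
  set.seed(21)
  for (i in 1:15) {
    ctr <- runif(2, 10, 50)
    edge <- ctr + runif(2, -9, 9)
    a <- marker_annotation(ctr, edge)
    m <- annotations_to_mask(list(a), c(60, 60))
    r2 <- sum((edge - ctr)^2)
    oracle <- outer(1:60, 1:60,
                    function(r, c) (r - ctr[1])^2 + (c - ctr[2])^2 <= r2)
    expect_identical(unname(m), unname(oracle))
  }
})

test_that("extract_segments keeps marker-sized discs and drops clutter", {
  # native-scale frame: a disc of radius 40 -> bbox ~81, inside [54, 114]
  mask <- matrix(0, 770, 1024)
  disc <- function(m, ctr, r) {
    rows <- (ctr[1] - r - 1):(ctr[1] + r + 1)
    cols <- (ctr[2] - r - 1):(ctr[2] + r + 1)
    m[rows, cols] <- m[rows, cols] |
      (outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`) <= r^2)
    m
  }
  mask <- disc(mask, c(300, 400), 40)
  segs <- extract_segments(mask)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$bbox[3], 81, tolerance = 1)
  expect_equal(segs[[1]]$bbox[4], 81, tolerance = 1)
  expect_lt(max(abs(segs[[1]]$center - c(300, 400))), 1)
  expect_equal(segs[[1]]$provenance, "detected")

  # a 3 px blob is filtered out; an elongated bar fails the aspect test
  mask2 <- disc(mask, c(100, 100), 2)
  mask2[600:605, 100:400] <- 1
  segs2 <- extract_segments(mask2)
  expect_length(segs2, 1)
  expect_equal(segs2[[1]]$center, segs[[1]]$center)

  expect_length(extract_segments(matrix(0, 100, 100)), 0)
})

test_that("complete_grid assigns indices without inventing segments when full", {
  set.seed(3)
  segs <- make_grid_segments(jitter = 3)
  out <- complete_grid(segs)
  expect_length(out, 8)
  expect_true(all(vapply(out, function(s) s$provenance, "") == "detected"))
  gi <- t(vapply(out, `[[`, integer(2), "grid_index"))
  expect_equal(gi, cbind(rep(1:2, each = 4), rep(1:4, 2)))
  # idempotence: re-running on its own output leaves centres unchanged
  out2 <- complete_grid(out)
  expect_equal(centers_of(out2), centers_of(out))
})

test_that("complete_grid reconstructs a removed interior marker", {
  segs <- make_grid_segments(rows = c(120, 260), cols = c(85, 205, 325, 445))
  true_ctr <- segs[[2]]$center             # line 1, position 2
  out <- complete_grid(segs[-2])
  expect_length(out, 8)
  inferred <- out[[2]]
  expect_equal(inferred$provenance, "inferred")
  expect_equal(inferred$grid_index, c(1L, 2L))
  expect_lt(sqrt(sum((inferred$center - true_ctr)^2)), 5)
})

test_that("complete_grid rejects unusable inputs", {
  segs <- make_grid_segments()
  expect_error(complete_grid(segs[1:3]), "incomplete grid")
  one_line <- segs[1:4]                     # all in line 1
  expect_error(complete_grid(one_line), "one line")
})

test_that("grid completion recovers dropped markers on jittered grids", {
  set.seed(77)
  recovered <- total <- 0
  for (i in 1:100) {
    segs <- make_grid_segments(jitter = 5)
    drop <- sample(8, sample(1:2, 1))
    out <- tryCatch(complete_grid(segs[-drop], image_size = c(385, 512)),
                    error = function(e) NULL)
    if (is.null(out)) next
    for (d in drop) {
      ln <- (d - 1) %/% 4 + 1; p <- (d - 1) %% 4 + 1
      inf <- out[[(ln - 1) * 4 + p]]
      total <- total + 1
      if (sqrt(sum((inf$center - segs[[d]]$center)^2)) <= 10)
        recovered <- recovered + 1
    }
  }
  expect_gte(total, 90)
  expect_gte(recovered / total, 0.95)
})

test_that("segments_from_annotations yields an ordered grid-indexed set", {
  cfg <- tiny_scene()
  cs <- generate_case(cfg, 5, render = FALSE)
  segs <- segments_from_annotations(cs$annotations)
  expect_length(segs, 8)
  gi <- t(vapply(segs, `[[`, integer(2), "grid_index"))
  expect_equal(gi, cbind(rep(1:2, each = 4), rep(1:4, 2)))
  # grid slots match the generator's site metadata
  ord <- order(cs$site_meta$line, cs$site_meta$pos)
  expect_equal(centers_of(segs),
               unname(as.matrix(cs$site_meta[ord, c("row", "col")])),
               tolerance = 1e-8)
})
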