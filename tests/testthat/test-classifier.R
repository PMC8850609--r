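# Sample assembly, normalisation, paired augmentation, architecture
# conformance and classifier training/prediction contracts.

test_that("extract_roi crops interior windows exactly and zero-pads borders", {
  img <- array(runif(770 * 1024 * 3), c(770, 1024, 3))
  roi <- extract_roi(img, c(400, 500), 300)
  expect_equal(dim(roi), c(300, 300, 3))
  expect_equal(roi, img[251:550, 351:650, ])      # no padding in the interior

  edge <- extract_roi(img, c(20, 20), 300)
  expect_true(all(edge[1:130, , ] == 0))          # 150 - 20 = 130 padded rows
  expect_true(all(edge[, 1:130, ] == 0))
  expect_equal(edge[131:300, 131:300, ], img[1:170, 1:170, ])

  expect_error(extract_roi(img, c(-5, 10)), "outside")
  expect_error(extract_roi(img, c(5, 2000)), "outside")
})

make_test_samples <- function(n_patients = 4, per_patient = 4, size = 16,
                              seed = 1) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_patients)) {
    attrs <- c(sex = p %% 2, age = 20 + 10 * p, weight = 60 + 5 * p,
               body_temperature = 36 + 0.1 * p)
    for (i in seq_len(per_patient)) {
      lab <- (i %% 2 == 0) * 1L
      delta <- matrix(rnorm(size^2, 0, 0.1), size, size)
      if (lab == 1) {
        d2 <- outer((1:size - size / 2)^2, (1:size - size / 2)^2, `+`)
        delta <- delta + 1.5 * exp(-d2 / (2 * (size / 6)^2))
      }
      out[[length(out) + 1]] <- structure(list(
        visible_roi = array(runif(size^2 * 3), c(size, size, 3)),
        delta_roi = delta, attributes = attrs, label = lab,
        patient_id = sprintf("P%02d", p), site_id = paste0("s", i),
        normalized = FALSE), class = "prick_sample")
    }
  }
  out
}

test_that("normalisation statistics standardise training data and invert", {
  smp <- make_test_samples()
  st <- fit_norm_stats(smp)
  expect_equal(st$attr_min[["age"]], 30)
  expect_equal(st$attr_max[["age"]], 60)
  norm <- apply_normalization(smp, st)
  # standardisation identity on the training set
  for (ch in 1:3) {
    px <- unlist(lapply(norm, function(s) s$visible_roi[, , ch]))
    expect_equal(mean(px), 0, tolerance = 1e-6)
    expect_equal(sd(px), 1, tolerance = 1e-2)  # population vs sample sd at n=4096
  }
  dpx <- unlist(lapply(norm, function(s) s$delta_roi))
  expect_equal(mean(dpx), 0, tolerance = 1e-6)
  # attributes at the training extremes map to 0 and 1; outside maps outside
  ages <- vapply(norm, function(s) s$attributes[["age"]], 0)
  expect_equal(range(ages), c(0, 1))
  test_s <- smp[[1]]
  test_s$attributes[["age"]] <- 70
  expect_gt(apply_normalization(test_s, st)$attributes[["age"]], 1)
  # algebraic inverse round-trips
  x <- smp[[5]]
  n1 <- apply_normalization(x, st)
  back <- n1$delta_roi * st$delta_sd + st$delta_mean
  expect_equal(back, x$delta_roi, tolerance = 1e-10)
  # guards
  flat <- smp
  for (i in seq_along(flat)) flat[[i]]$delta_roi[] <- 3
  expect_error(fit_norm_stats(flat), "zero-variance")
  expect_error(fit_norm_stats(smp[1]), ">= 2")
})

test_that("augment_pair applies one realised transform to both channels", {
  cfg <- augment_config()
  smp <- make_test_samples(size = 24)[[2]]
  # coordinate-encoding pattern placed in both channels
  pat <- outer(1:24, 1:24, function(r, c) r + 100 * c) / 2500
  smp$visible_roi[, , 1] <- pat
  smp$visible_roi[, , 2] <- pat
  smp$visible_roi[, , 3] <- pat
  smp$delta_roi <- pat
  set.seed(31)
  for (i in 1:25) {
    a <- augment_pair(smp, cfg)
    expect_equal(a$delta_roi, a$visible_roi[, , 1], tolerance = 1e-12)
    expect_equal(a$delta_roi, a$visible_roi[, , 3], tolerance = 1e-12)
    expect_identical(a$label, smp$label)
    expect_identical(a$attributes, smp$attributes)
  }
})

test_that("augmentation draws reproduce flips and integer translations exactly", {
  smp <- make_test_samples(size = 20)[[1]]
  # identity when no transform fires
  none <- augment_config(p_each = 0)
  expect_identical(augment_pair(smp, none), smp)
  # forced horizontal flip only: p_each = 1 with all other magnitudes zero
  flip_only <- augment_config(p_each = 1, max_rotation = 0,
                              max_translation = 0, max_zoom = 1, flips = TRUE)
  set.seed(2)
  a <- augment_pair(smp, flip_only)
  # hflip mirrors columns, vflip mirrors rows; both fire at p_each = 1
  expect_equal(a$delta_roi, smp$delta_roi[20:1, 20:1], tolerance = 1e-12)
  # forced pure translation: shift contract per the warp primitive
  tr_only <- augment_config(p_each = 1, max_rotation = 0, max_translation = 4,
                            max_zoom = 1, flips = FALSE)
  set.seed(7)
  b <- augment_pair(smp, tr_only)
  expect_equal(dim(b$delta_roi), dim(smp$delta_roi))
  expect_false(identical(b$delta_roi, smp$delta_roi))
})

test_that("the full classifier architecture matches the published plan", {
  cfg <- classifier_config(profile = "full")
  expect_equal(cfg$conv_plan$channels,
               c(32L, 64L, 64L, 128L, 128L, 256L, 256L, 256L, 256L, 256L, 256L))
  expect_equal(sum(cfg$conv_plan$pool), 6)
  # spatial trace 300 -> 149 -> 74 -> 36 -> 17 -> 8 -> 3
  s <- 300
  trace <- c()
  for (i in seq_len(nrow(cfg$conv_plan)))
    if (cfg$conv_plan$pool[i]) { s <- floor((s - 3) / 2) + 1; trace <- c(trace, s) }
  expect_equal(trace, c(149, 74, 36, 17, 8, 3))
  expect_equal(thermoprick:::classifier_spatial(cfg), 3)

  model <- build_classifier(cfg)
  # four input channels in "both" mode; first dense takes 256*3*3 + 4 inputs
  expect_equal(dim(model$params$cw1), c(3, 3, 4, 32))
  expect_equal(ncol(model$params$fw1), 256 * 3 * 3 + 4)
  expect_equal(nrow(model$params$fw1), 64)
  for (l in seq_len(11))
    expect_equal(dim(model$params[[paste0("cw", l)]])[4], cfg$conv_plan$channels[l])

  th <- build_classifier(classifier_config(profile = "full",
                                           input_mode = "thermal_only"))
  expect_equal(dim(th$params$cw1)[3], 1)
  vi <- build_classifier(classifier_config(profile = "full",
                                           input_mode = "visible_only"))
  expect_equal(dim(vi$params$cw1)[3], 3)
})

test_that("a forward pass through the full architecture has the right shape", {
  cfg <- classifier_config(profile = "full")
  model <- build_classifier(cfg)
  x <- array(rnorm(300 * 300 * 4), c(300, 300, 4, 1))
  at <- matrix(runif(4), 4, 1)
  f <- thermoprick:::cpp_cnn_forward(x, at, model$params, model$state,
                                     model$arch, FALSE, NULL)
  expect_equal(dim(f$logits), c(1, 1))
  expect_true(is.finite(f$logits[1, 1]))
})

test_that("training learns a separable synthetic signal and guards inputs", {
  smp <- make_test_samples(n_patients = 6, per_patient = 6)
  cfg <- classifier_config(input_mode = "thermal_only", profile = "reduced",
                           roi_size = 16,
                           conv_plan = data.frame(channels = c(8L, 16L),
                                                  pool = c(TRUE, TRUE)),
                           epochs = 8, batch_size = 8, seed = 3,
                           augment = NULL)
  model <- train_classifier(smp, cfg)
  expect_s3_class(model, "prick_classifier")
  h <- model$history
  expect_lt(h$loss[nrow(h)], 0.5 * h$loss[1])      # loss halves while learning
  pr <- predict_proba(model, smp)
  expect_true(all(pr >= 0 & pr <= 1))
  labs <- vapply(smp, `[[`, 0L, "label")
  expect_gt(mean(pr[labs == 1]), mean(pr[labs == 0]))
  # duplicate samples score identically
  expect_equal(predict_proba(model, smp[c(1, 1)])[1],
               predict_proba(model, smp[c(1, 1)])[2])
  # determinism: same config trains to identical weights
  model2 <- train_classifier(smp, cfg)
  expect_identical(model$params, model2$params)
  # guards
  ones <- smp[vapply(smp, `[[`, 0L, "label") == 1]
  expect_error(train_classifier(ones, cfg), "single class")
  bare <- build_classifier(cfg)
  expect_error(predict_proba(bare, smp), "statistics")
})

test_that("normalisation statistics never see held-out patients", {
  smp <- make_test_samples(n_patients = 5, per_patient = 4)
  pid <- vapply(smp, `[[`, "", "patient_id")
  plan <- make_patient_folds(pid, k = 5, seed = 2)
  for (f in plan$folds) {
    st <- fit_norm_stats(smp[pid %in% f$train])
    expect_length(intersect(st$train_patient_ids, f$test), 0)
  }
})
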