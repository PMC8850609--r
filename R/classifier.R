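# Per-site sample assembly (ROI extraction, normalisation, paired
# augmentation) and the convolutional classifier with patient-attribute
# fusion.  Three input-spectra variants are supported: both images fused into
# a four-channel tensor, the delta-thermal channel alone, or the visible
# channels alone.

#' Augmentation configuration
#'
#' Each of horizontal flip, vertical flip, rotation, translation and zoom is
#' applied independently with probability `p_each`; parameters are drawn
#' uniformly.  The realised transform chain is applied identically to the
#' visible and delta channels of a sample.
#'
#' @param p_each Per-transform application probability.
#' @param max_rotation Maximum absolute rotation, degrees.
#' @param max_translation Maximum absolute translation per axis, pixels.
#' @param max_zoom Maximum zoom ratio (>= 1).
#' @param flips Enable horizontal/vertical flips.
#' @return An object of class `"augment_config"`.
#' @export
augment_config <- function(p_each = 0.5, max_rotation = 45, max_translation = 4,
                           max_zoom = 1.3, flips = TRUE) {
  stopifnot(p_each >= 0, p_each <= 1, max_zoom >= 1)
  structure(list(p_each = p_each, max_rotation = max_rotation,
                 max_translation = max_translation, max_zoom = max_zoom,
                 flips = flips),
            class = "augment_config")
}

#' Classifier configuration
#'
#' The `"full"` profile is the reading pipeline's reference architecture:
#' 300 x 300 ROIs through eleven 3x3 convolutions with output channels
#' 32, 64, 64, 128, 128, 256, 256, 256, 256, 256, 256, each followed by
#' batch normalisation and LeakyReLU, with 3x3 stride-2 average pooling
#' after convolutions 1, 2, 5, 7, 9 and 11 (spatial trace
#' 300-149-74-36-17-8-3); the flattened features are concatenated with the
#' four patient attributes and passed through a 64-unit dense layer,
#' LeakyReLU, 0.5 dropout and a final dense layer.  Optimised with AdamW
#' (learning rate 0.001, decoupled weight decay 1e-4) under cross-entropy
#' loss, with a fixed 80-epoch budget as early stopping.  The `"reduced"`
#' profile is a proportionally narrower desk-scale variant (small ROIs,
#' truncated convolution plan) for fast experiments on synthetic cohorts.
#'
#' @param input_mode `"both"` (4 input channels), `"thermal_only"` (1) or
#'   `"visible_only"` (3).
#' @param profile `"full"` or `"reduced"` preset, overridable below.
#' @param roi_size ROI side length, pixels.
#' @param conv_plan Data frame with `channels` and `pool` columns, one row
#'   per convolution.
#' @param leaky_slope Negative slope of LeakyReLU.
#' @param head_hidden Width of the dense layer before the output.
#' @param dropout Dropout probability between the dense layers.
#' @param head `"sigmoid"` (single logit with binary cross-entropy) or
#'   `"softmax2"` (two logits with cross-entropy); the two are
#'   mathematically equivalent parameterisations of the same model.
#' @param lr AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param epochs Fixed training-epoch budget.
#' @param batch_size Samples per gradient step.
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @param seed Integer seed (initialisation, shuffling, augmentation draws,
#'   dropout).
#' @return An object of class `"classifier_config"`.
#' @export
classifier_config <- function(input_mode = c("both", "thermal_only", "visible_only"),
                              profile = c("full", "reduced"),
                              roi_size = NULL, conv_plan = NULL,
                              leaky_slope = 0.01, head_hidden = 64, dropout = 0.5,
                              head = c("sigmoid", "softmax2"),
                              lr = 1e-3, weight_decay = 1e-4,
                              epochs = NULL, batch_size = 32,
                              augment = augment_config(), seed = 1) {
  input_mode <- match.arg(input_mode)
  profile <- match.arg(profile)
  head <- match.arg(head)
  if (is.null(conv_plan)) {
    conv_plan <- if (profile == "full") {
      data.frame(channels = c(32L, 64L, 64L, 128L, 128L, 256L, 256L, 256L, 256L, 256L, 256L),
                 pool = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
    } else {
      data.frame(channels = c(8L, 16L, 32L, 32L),
                 pool = c(TRUE, TRUE, FALSE, TRUE))
    }
  }
  if (is.null(roi_size)) roi_size <- if (profile == "full") 300L else 48L
  if (is.null(epochs)) epochs <- if (profile == "full") 80L else 12L
  stopifnot(nrow(conv_plan) >= 1, lr > 0, dropout >= 0, dropout < 1)
  cfg <- structure(list(input_mode = input_mode, profile = profile,
                        roi_size = as.integer(roi_size), conv_plan = conv_plan,
                        leaky_slope = leaky_slope, head_hidden = as.integer(head_hidden),
                        dropout = dropout, head = head, lr = lr,
                        weight_decay = weight_decay, epochs = as.integer(epochs),
                        batch_size = as.integer(batch_size), augment = augment,
                        seed = as.integer(seed)),
                   class = "classifier_config")
  classifier_spatial(cfg)  # validates that pooling leaves a positive map
  cfg
}

n_input_channels <- function(input_mode) {
  switch(input_mode, both = 4L, thermal_only = 1L, visible_only = 3L,
         stop_thermoprick("unknown input_mode: ", input_mode))
}

# spatial size after the conv trunk (3x3 stride-2 pools, no padding)
classifier_spatial <- function(cfg) {
  s <- cfg$roi_size
  for (i in seq_len(nrow(cfg$conv_plan)))
    if (cfg$conv_plan$pool[i]) s <- floor((s - 3) / 2) + 1
  if (s < 1) stop_thermoprick("conv plan pools the ", cfg$roi_size,
                              "px ROI away; reduce pooling or enlarge the ROI")
  s
}

#' Extract a square region of interest around a segment centre
#'
#' The ROI is a `size`-sided square centred on the (rounded) segment centre,
#' the same coordinates being used for the visible and the delta image
#' (pixel-level correlation).  Out-of-bounds area is zero-padded.
#'
#' @param image H x W matrix or H x W x C array.
#' @param center `(row, col)`; must lie inside the image.
#' @param size ROI side length (default 300).
#' @return A `size` x `size` (x C) array.
#' @export
extract_roi <- function(image, center, size = 300) {
  image <- unclass(image)
  d <- dim(image)
  if (center[1] < 1 || center[1] > d[1] || center[2] < 1 || center[2] > d[2])
    stop_thermoprick("ROI center (", center[1], ", ", center[2], ") outside image")
  r0 <- round(center[1]) - floor(size / 2) + (1 - size %% 2)
  c0 <- round(center[2]) - floor(size / 2) + (1 - size %% 2)
  rows <- r0:(r0 + size - 1)
  cols <- c0:(c0 + size - 1)
  rok <- rows >= 1 & rows <= d[1]
  cok <- cols >= 1 & cols <= d[2]
  if (length(d) == 3) {
    out <- array(0, c(size, size, d[3]))
    out[rok, cok, ] <- image[rows[rok], cols[cok], , drop = FALSE]
  } else {
    out <- matrix(0, size, size)
    out[rok, cok] <- image[rows[rok], cols[cok]]
  }
  out
}

#' Assemble classification samples for one forearm case
#'
#' Cuts the visible ROI from the post-series visible image and the thermal
#' ROI from the delta image at the same coordinates (segments are found on
#' the visible-spectrum image; the two spectra are pixel-correlated), and
#' attaches the four interview attributes (sex, age, weight, body
#' temperature) and the per-site label looked up by grid index.
#'
#' @param visible_post H x W x 3 post-series visible image.
#' @param delta A [delta_image()] in the post-series frame.
#' @param segments Grid-indexed segments (8 per forearm).
#' @param patient A [patient_record()].
#' @param site_meta Data frame with `line`, `pos`, `site_id`, `label`
#'   (as in a `synthetic_case`).
#' @param roi_size ROI side length.
#' @return A list of `"prick_sample"` objects: `visible_roi`, `delta_roi`,
#'   `attributes`, `label`, `patient_id`, `site_id`.
#' @export
make_samples <- function(visible_post, delta, segments, patient, site_meta,
                         roi_size = 300) {
  stopifnot(inherits(delta, "delta_image"), inherits(patient, "patient_record"))
  lapply(segments, function(s) {
    if (is.null(s$grid_index)) stop_thermoprick("segments must carry grid_index")
    m <- which(site_meta$line == s$grid_index[1] & site_meta$pos == s$grid_index[2])
    stopifnot(length(m) == 1)
    structure(list(
      visible_roi = extract_roi(visible_post, s$center, roi_size),
      delta_roi = extract_roi(delta$pixels, s$center, roi_size),
      attributes = c(sex = as.numeric(patient$sex == "F"), age = patient$age,
                     weight = patient$weight,
                     body_temperature = patient$body_temperature),
      label = as.integer(site_meta$label[m]),
      patient_id = patient$patient_id,
      site_id = site_meta$site_id[m],
      normalized = FALSE), class = "prick_sample")
  })
}

#' Fit normalisation statistics on training samples
#'
#' Per-channel mean and standard deviation over all training ROIs (three
#' visible channels and the delta channel), and per-attribute minimum and
#' maximum over training patients.  Computed on training data only and then
#' applied unchanged to test data; the patient ids that contributed are
#' recorded so leakage can be asserted against.
#'
#' @param train_samples List of samples from [make_samples()] (>= 2).
#' @return An object of class `"norm_stats"`.
#' @export
fit_norm_stats <- function(train_samples) {
  if (length(train_samples) < 2) stop_thermoprick("need >= 2 training samples")
  vis <- vapply(train_samples, function(s) {
    c(colMeans(matrix(s$visible_roi, ncol = 3)),
      colMeans(matrix(s$visible_roi, ncol = 3)^2))
  }, numeric(6))
  vm <- rowMeans(vis[1:3, , drop = FALSE])
  vs <- sqrt(pmax(rowMeans(vis[4:6, , drop = FALSE]) - vm^2, 0))
  dm <- mean(vapply(train_samples, function(s) mean(s$delta_roi), 0))
  ds <- sqrt(max(mean(vapply(train_samples, function(s) mean(s$delta_roi^2), 0)) - dm^2, 0))
  if (any(c(vs, ds) < 1e-9))
    stop_thermoprick("zero-variance image channel in training data")
  at <- t(vapply(train_samples, `[[`, numeric(4), "attributes"))
  pid <- vapply(train_samples, `[[`, "", "patient_id")
  first <- !duplicated(pid)
  amin <- apply(at[first, , drop = FALSE], 2, min)
  amax <- apply(at[first, , drop = FALSE], 2, max)
  fix <- amax - amin < 1e-12
  amax[fix] <- amin[fix] + 1  # constant attribute (e.g. single-sex fold)
  structure(list(vis_mean = vm, vis_sd = vs, delta_mean = dm, delta_sd = ds,
                 attr_min = amin, attr_max = amax,
                 train_patient_ids = unique(pid)),
            class = "norm_stats")
}

#' Apply normalisation statistics to samples
#'
#' Image channels are standardised to zero mean and unit variance; the four
#' attributes are min-max rescaled to `[0, 1]` without clipping (test values
#' outside the training range map outside `[0, 1]`).
#'
#' @param samples A sample or list of samples.
#' @param stats A [fit_norm_stats()] result.
#' @return Normalised sample(s).
#' @export
apply_normalization <- function(samples, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  one <- function(s) {
    for (ch in 1:3)
      s$visible_roi[, , ch] <- (s$visible_roi[, , ch] - stats$vis_mean[ch]) / stats$vis_sd[ch]
    s$delta_roi <- (s$delta_roi - stats$delta_mean) / stats$delta_sd
    s$attributes <- (s$attributes - stats$attr_min) / (stats$attr_max - stats$attr_min)
    s$normalized <- TRUE
    s
  }
  if (inherits(samples, "prick_sample")) one(samples) else lapply(samples, one)
}

# realised augmentation: returns the 3x3 output->source matrix, or NULL for
# the identity
draw_augment_matrix <- function(size, config) {
  ctr <- (size + 1) / 2
  use <- runif(5) < config$p_each
  hflip <- use[1] && config$flips
  vflip <- use[2] && config$flips
  theta <- if (use[3]) runif(1, -1, 1) * config$max_rotation * pi / 180 else 0
  trans <- if (use[4]) runif(2, -1, 1) * config$max_translation else c(0, 0)
  zoom <- if (use[5]) runif(1, 1, config$max_zoom) else 1
  if (!hflip && !vflip && theta == 0 && all(trans == 0) && zoom == 1) return(NULL)
  Fm <- diag(3)
  about_ctr <- function(M2) {
    M <- diag(3); M[1:2, 1:2] <- M2; M[1:2, 3] <- c(ctr, ctr) - M2 %*% c(ctr, ctr); M
  }
  if (vflip) Fm <- about_ctr(diag(c(-1, 1))) %*% Fm
  if (hflip) Fm <- about_ctr(diag(c(1, -1))) %*% Fm
  Rz <- zoom * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Fm <- about_ctr(Rz) %*% Fm
  Tt <- diag(3); Tt[1:2, 3] <- trans
  Fm <- Tt %*% Fm
  solve(Fm)
}

#' Paired augmentation of one sample
#'
#' Draws the transform chain once (from the current R RNG state) and applies
#' the identical realised transform to the visible and delta ROIs; labels
#' and attributes are unchanged.  Rotation/zoom use bilinear interpolation
#' with zero fill — after normalisation, zero is the training-channel mean.
#'
#' @param sample A `"prick_sample"`.
#' @param config An [augment_config()].
#' @return The augmented sample.
#' @export
augment_pair <- function(sample, config = augment_config()) {
  size <- nrow(sample$delta_roi)
  M <- draw_augment_matrix(size, config)
  if (is.null(M)) return(sample)
  for (ch in 1:3)
    sample$visible_roi[, , ch] <- cpp_warp_projective(sample$visible_roi[, , ch],
                                                      M, size, size)$pixels
  sample$delta_roi <- cpp_warp_projective(sample$delta_roi, M, size, size)$pixels
  sample
}

#' Build the classifier network
#'
#' @param config A [classifier_config()].
#' @param seed Initialisation seed (defaults to `config$seed`).
#' @return An object of class `"prick_classifier"` (untrained).
#' @export
build_classifier <- function(config = classifier_config(), seed = config$seed) {
  stopifnot(inherits(config, "classifier_config"))
  in_ch <- n_input_channels(config$input_mode)
  plan <- config$conv_plan
  sp <- classifier_spatial(config)
  n_out <- if (config$head == "softmax2") 2L else 1L
  feat <- sp * sp * plan$channels[nrow(plan)] + 4L
  params <- with_seed(seed, {
    p <- list()
    cin <- in_ch
    for (l in seq_len(nrow(plan))) {
      co <- plan$channels[l]
      p[[paste0("cw", l)]] <- he_init(c(3, 3, cin, co), 9 * cin)
      p[[paste0("cb", l)]] <- rep(0, co)
      p[[paste0("bng", l)]] <- rep(1, co)
      p[[paste0("bnb", l)]] <- rep(0, co)
      cin <- co
    }
    p$fw1 <- matrix(rnorm(config$head_hidden * feat, 0, sqrt(2 / feat)),
                    config$head_hidden, feat)
    p$fb1 <- rep(0, config$head_hidden)
    p$fw2 <- matrix(rnorm(n_out * config$head_hidden, 0, sqrt(1 / config$head_hidden)),
                    n_out, config$head_hidden)
    p$fb2 <- rep(0, n_out)
    p
  })
  state <- list()
  for (l in seq_len(nrow(plan))) {
    state[[paste0("bnm", l)]] <- rep(0, plan$channels[l])
    state[[paste0("bnv", l)]] <- rep(1, plan$channels[l])
  }
  arch <- list(in_ch = in_ch, channels = as.integer(plan$channels),
               pool = plan$pool, slope = config$leaky_slope,
               bn_eps = 1e-5, bn_momentum = 0.9,
               pool_kernel = 3L, pool_stride = 2L, n_out = n_out)
  structure(list(arch = arch, params = params, state = state, config = config,
                 norm_stats = NULL, history = NULL),
            class = "prick_classifier")
}

#' @export
print.prick_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0))
  cat(sprintf("<prick_classifier %s: %d convs, %s parameters%s>\n",
              x$config$input_mode, length(x$arch$channels),
              format(np, big.mark = ","),
              if (is.null(x$norm_stats)) ", untrained" else ""))
  invisible(x)
}

# stack normalised samples into the network input tensor for a given mode
assemble_batch <- function(samples, input_mode) {
  n <- length(samples)
  size <- nrow(samples[[1]]$delta_roi)
  C <- n_input_channels(input_mode)
  x <- array(0, c(size, size, C, n))
  for (i in seq_len(n)) {
    s <- samples[[i]]
    if (input_mode == "both") {
      x[, , 1:3, i] <- s$visible_roi
      x[, , 4, i] <- s$delta_roi
    } else if (input_mode == "thermal_only") {
      x[, , 1, i] <- s$delta_roi
    } else {
      x[, , 1:3, i] <- s$visible_roi
    }
  }
  attrs <- vapply(samples, `[[`, numeric(4), "attributes")
  list(x = x, attrs = matrix(attrs, 4, n))
}

#' Train the classifier on labelled samples
#'
#' Fits normalisation statistics on the training samples, then minimises
#' cross-entropy with AdamW for a fixed epoch budget, drawing fresh paired
#' augmentations every epoch.  Deterministic given `config$seed`.
#'
#' @param train_samples List of `"prick_sample"`s containing both classes.
#' @param config A [classifier_config()].
#' @param verbose Print per-epoch loss/accuracy.
#' @return A trained `"prick_classifier"` carrying its `norm_stats` and a
#'   training `history` (`epoch`, `loss`, `accuracy`).
#' @export
train_classifier <- function(train_samples, config = classifier_config(),
                             verbose = FALSE) {
  labs <- vapply(train_samples, `[[`, 0L, "label")
  if (length(unique(labs)) < 2)
    stop_thermoprick("training data contains a single class")
  stats <- fit_norm_stats(train_samples)
  norm <- apply_normalization(train_samples, stats)
  model <- build_classifier(config, seed = derive_seed(config$seed, 11L))
  model$norm_stats <- stats
  params <- model$params
  state <- model$state
  opt <- adam_state(params)
  n <- length(norm)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  with_seed(derive_seed(config$seed, 202L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        batch <- norm[b]
        if (!is.null(config$augment))
          batch <- lapply(batch, augment_pair, config = config$augment)
        ab <- assemble_batch(batch, config$input_mode)
        dm <- dropout_mask(config$head_hidden, length(b), config$dropout)
        out <- cpp_cnn_fwdbwd(ab$x, ab$attrs, labs[b], params, state, model$arch, dm)
        state <- out$state
        st <- adam_step(params, out$grads, opt, config$lr, config$weight_decay)
        params <- st$params; opt <- st$opt
        ep_loss <- ep_loss + out$loss * length(b)
        ep_correct <- ep_correct + sum((out$probs >= 0.5) == (labs[b] == 1))
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                     accuracy = ep_correct / n))
      if (verbose) message(sprintf("epoch %d: loss %.4f acc %.3f",
                                   ep, ep_loss / n, ep_correct / n))
    }
  })
  model$params <- params
  model$state <- state
  model$history <- hist
  model
}

#' Predict per-site reaction probabilities
#'
#' Normalises the samples with the model's stored training statistics and
#' runs the network in inference mode (batch-norm running statistics, no
#' dropout, no augmentation).
#'
#' @param model A trained `"prick_classifier"`.
#' @param samples A sample or list of `"prick_sample"`s (raw, not
#'   pre-normalised).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, samples) {
  stopifnot(inherits(model, "prick_classifier"))
  if (is.null(model$norm_stats))
    stop_thermoprick("model carries no normalisation statistics; train it first")
  if (inherits(samples, "prick_sample")) samples <- list(samples)
  norm <- apply_normalization(samples, model$norm_stats)
  out <- numeric(length(norm))
  for (b in split(seq_along(norm), ceiling(seq_along(norm) / 64))) {
    ab <- assemble_batch(norm[b], model$config$input_mode)
    fw <- cpp_cnn_forward(ab$x, ab$attrs, model$params, model$state, model$arch,
                          FALSE, NULL)
    z <- fw$logits
    out[b] <- if (model$arch$n_out == 1) 1 / (1 + exp(-z[1, ]))
              else exp(z[2, ]) / (exp(z[1, ]) + exp(z[2, ]))
  }
  out
}
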