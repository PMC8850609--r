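# U-Net segmentation model: the encoder-decoder-with-skips architecture used
# to find allergen application markers on visible-spectrum forearm images.

unet_param_names <- function(depth) {
  nm <- character(0)
  for (l in seq_len(depth)) nm <- c(nm, paste0("we", 2 * l - 1), paste0("we", 2 * l))
  nm <- c(nm, "wb1", "wb2")
  for (l in depth:1) nm <- c(nm, paste0("wu", l), paste0("wd", 2 * l - 1), paste0("wd", 2 * l))
  c(nm, "wo")
}

init_unet_params <- function(in_ch, widths) {
  depth <- length(widths) - 1
  p <- list()
  add <- function(nm, ci, co, k = 3) {
    p[[paste0("w", nm)]] <<- he_init(c(k, k, ci, co), k * k * ci)
    p[[paste0("b", nm)]] <<- rep(0, co)
  }
  cin <- in_ch
  for (l in seq_len(depth)) {
    add(paste0("e", 2 * l - 1), cin, widths[l])
    add(paste0("e", 2 * l), widths[l], widths[l])
    cin <- widths[l]
  }
  add("b1", widths[depth], widths[depth + 1])
  add("b2", widths[depth + 1], widths[depth + 1])
  for (l in depth:1) {
    cup <- if (l == depth) widths[depth + 1] else widths[l + 1]
    add(paste0("u", l), cup, widths[l])
    add(paste0("d", 2 * l - 1), 2 * widths[l], widths[l])
    add(paste0("d", 2 * l), widths[l], widths[l])
  }
  add("o", widths[1], 1, k = 1)
  p
}

#' Build a U-Net segmentation model
#'
#' An encoder-decoder fully-convolutional network with skip connections: each
#' encoder level applies two 3x3 same-padding convolutions with ReLU and a
#' 2x2 max pool, channel width doubling per level; the decoder mirrors it
#' with x2 nearest-neighbour upsampling followed by a 3x3 convolution, skip
#' concatenation and two further convolutions; a 1x1 convolution with sigmoid
#' produces the per-pixel marker probability.  The default widths
#' (64, 128, 256, 512, 1024 over four pooling levels) follow the original
#' U-Net recipe; `base_width` and `depth` allow proportionally narrower
#' models for desk-scale training, where the synthetic markers are far easier
#' than general biomedical segmentation.
#'
#' @param in_channels Input channels (3: the visible image; markers are drawn
#'   in ink and are invisible in thermal).
#' @param base_width First-level channel width.
#' @param depth Number of pooling levels.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `"unet_model"`.
#' @export
build_unet <- function(in_channels = 3, base_width = 64, depth = 4, seed = 1) {
  stopifnot(is_count(base_width), base_width >= 1, is_count(depth), depth >= 1)
  widths <- as.integer(base_width * 2^(0:depth))
  params <- with_seed(seed, init_unet_params(in_channels, widths))
  structure(list(arch = list(depth = as.integer(depth), widths = widths,
                             in_ch = as.integer(in_channels)),
                 params = params, history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0))
  cat(sprintf("<unet_model: depth %d, widths %s, %s parameters%s>\n",
              x$arch$depth, paste(x$arch$widths, collapse = "-"),
              format(np, big.mark = ","),
              if (is.null(x$history)) ", untrained" else ""))
  invisible(x)
}

# zero-pad (bottom/right) an H x W x C x N array so H and W divide 2^depth
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  if (ph == 0 && pw == 0) return(list(x = x, h = d[1], w = d[2]))
  out <- array(0, c(d[1] + ph, d[2] + pw, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = out, h = d[1], w = d[2])
}

as_image_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3)
    return(array(images, c(dim(images), 1)))
  if (is.matrix(images)) return(array(images, c(dim(images), 1, 1)))
  stopifnot(is.list(images), length(images) >= 1)
  d <- dim(images[[1]])
  if (length(d) == 2) d <- c(d, 1)
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

#' Predict marker probability masks
#'
#' @param model A trained (or freshly built) [build_unet()] model.
#' @param images An H x W x 3 array, a list of them, or an H x W x 3 x N
#'   array, pixel values in `[0, 1]`.
#' @return An H x W matrix of probabilities for a single image, else an
#'   H x W x N array.
#' @export
predict_mask <- function(model, images) {
  stopifnot(inherits(model, "unet_model"))
  x <- as_image_batch(images)
  single <- dim(x)[4] == 1
  pad <- pad_to_multiple(x, 2^model$arch$depth)
  pr <- cpp_unet_predict(pad$x, model$params, model$arch)
  pr <- pr[seq_len(pad$h), seq_len(pad$w), 1, , drop = FALSE]
  if (single) matrix(pr, pad$h, pad$w) else array(pr, dim(pr)[c(1, 2, 4)])
}

#' Segmentation training configuration
#'
#' @param epochs Training epochs (default 30).
#' @param lr Adam learning rate (framework-default 0.001; the optimiser is
#'   Adam with binary cross-entropy loss).
#' @param batch_size Images per gradient step.
#' @param train_size `(height, width)` the training images are downscaled to;
#'   the default is half the native acquisition size.
#' @param seed Integer seed controlling shuffling (and weight initialisation
#'   when [train_unet()] builds the model itself).
#' @return An object of class `"seg_train_config"`.
#' @export
seg_train_config <- function(epochs = 30, lr = 1e-3, batch_size = 4,
                             train_size = c(385, 512), seed = 1) {
  if (!is_count(epochs) || epochs < 1) stop_thermoprick("epochs must be >= 1")
  stopifnot(all(train_size > 0))
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 train_size = as.integer(train_size), seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Train the U-Net on image/mask pairs
#'
#' Minimises pixel-wise binary cross-entropy with Adam.  Images and masks are
#' bilinearly resized to `config$train_size` (masks re-binarised at 0.5);
#' pixel values are assumed normalised to `[0, 1]`.  Training is
#' deterministic given `config$seed`.
#'
#' @param images List (or 4-d array) of H x W x 3 visible images.
#' @param masks List (or array) of matching binary masks (see
#'   [annotations_to_mask()]).
#' @param config A [seg_train_config()].
#' @param model Optional pre-built [build_unet()]; by default a model with
#'   the original widths is created with `config$seed`.
#' @param verbose Print per-epoch loss.
#' @return The trained `"unet_model"` with a `history` data frame
#'   (`epoch`, `loss`).
#' @export
train_unet <- function(images, masks, config = seg_train_config(), model = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "seg_train_config"))
  x <- as_image_batch(images)
  y <- as_image_batch(masks)
  if (!identical(dim(x)[c(1, 2, 4)], dim(y)[c(1, 2, 4)]))
    stop_thermoprick("images and masks have mismatched shapes")
  n <- dim(x)[4]
  if (n < 1) stop_thermoprick("need at least one training pair")
  th <- config$train_size[1]; tw <- config$train_size[2]
  if (dim(x)[1] != th || dim(x)[2] != tw) {
    xr <- array(0, c(th, tw, 3, n)); yr <- array(0, c(th, tw, 1, n))
    for (i in seq_len(n)) {
      xr[, , , i] <- resize_bilinear(x[, , , i], th, tw)
      yr[, , 1, i] <- resize_bilinear(y[, , 1, i], th, tw) >= 0.5
    }
    x <- xr; y <- yr
  }
  if (is.null(model)) model <- build_unet(seed = config$seed)
  pad <- pad_to_multiple(x, 2^model$arch$depth)
  ypad <- pad_to_multiple(y, 2^model$arch$depth)
  params <- model$params
  if (is.null(model$history)) {
    # initialise the output bias at the foreground log-odds so optimisation
    # starts calibrated to the class balance (marker pixels are a small
    # fraction of skin) instead of spending its step budget drifting there
    prior <- min(max(mean(ypad$x), 1e-3), 1 - 1e-3)
    params$bo <- rep(log(prior / (1 - prior)), length(params$bo))
  }
  opt <- adam_state(params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0))
  with_seed(derive_seed(config$seed, 101L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        out <- cpp_unet_fwdbwd(pad$x[, , , b, drop = FALSE],
                               ypad$x[, , , b, drop = FALSE],
                               params, model$arch)
        st <- adam_step(params, out$grads, opt, config$lr)
        params <- st$params; opt <- st$opt
        ep_loss <- ep_loss + out$loss * length(b)
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n))
      if (verbose) message(sprintf("epoch %d: loss %.5f", ep, ep_loss / n))
    }
  })
  model$params <- params
  model$history <- hist
  model
}
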