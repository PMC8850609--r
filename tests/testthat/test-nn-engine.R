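# The compiled network engine: analytic gradients vs central finite
# differences on small networks, and basic forward contracts.  These checks
# cover convolution, batch normalisation, pooling, dense layers, dropout
# masking, the attribute-fusion head and both loss heads.

cnn_arch <- function(channels, pool, in_ch, n_out = 1L) {
  list(in_ch = as.integer(in_ch), channels = as.integer(channels),
       pool = pool, slope = 0.01, bn_eps = 1e-5, bn_momentum = 0.9,
       pool_kernel = 3L, pool_stride = 2L, n_out = as.integer(n_out))
}

init_tiny_cnn <- function(in_ch, channels, pool, hw, hidden = 5, n_out = 1) {
  p <- list(); cin <- in_ch; s <- hw
  for (l in seq_along(channels)) {
    co <- channels[l]
    p[[paste0("cw", l)]] <- array(rnorm(9 * cin * co, 0, 0.3), c(3, 3, cin, co))
    p[[paste0("cb", l)]] <- rnorm(co) * 0.1
    p[[paste0("bng", l)]] <- 1 + rnorm(co) * 0.1
    p[[paste0("bnb", l)]] <- rnorm(co) * 0.1
    if (pool[l]) s <- floor((s - 3) / 2) + 1
    cin <- co
  }
  feat <- s * s * cin + 4
  p$fw1 <- matrix(rnorm(hidden * feat, 0, 0.2), hidden, feat)
  p$fb1 <- rnorm(hidden) * 0.1
  p$fw2 <- matrix(rnorm(n_out * hidden, 0, 0.3), n_out, hidden)
  p$fb2 <- rnorm(n_out) * 0.1
  st <- list()
  for (l in seq_along(channels)) {
    st[[paste0("bnm", l)]] <- rep(0, channels[l])
    st[[paste0("bnv", l)]] <- rep(1, channels[l])
  }
  list(params = p, state = st)
}

test_that("classifier gradients match finite differences (both heads)", {
  set.seed(42)
  for (n_out in c(1L, 2L)) {
    channels <- c(3L, 4L); pool <- c(TRUE, FALSE); hw <- 9; N <- 3
    arch <- cnn_arch(channels, pool, 2, n_out)
    m <- init_tiny_cnn(2, channels, pool, hw, n_out = n_out)
    x <- array(rnorm(hw * hw * 2 * N), c(hw, hw, 2, N))
    at <- matrix(runif(4 * N), 4, N)
    y <- c(1, 0, 1)
    dm <- matrix(rbinom(5 * N, 1, 0.8) * 2, 5, N)
    loss_at <- function(p)
      thermoprick:::cpp_cnn_fwdbwd(x, at, y, p, m$state, arch, dm)$loss
    out <- thermoprick:::cpp_cnn_fwdbwd(x, at, y, m$params, m$state, arch, dm)
    for (nm in names(m$params)) {
      g <- out$grads[[nm]]
      idx <- sample(length(g), min(4, length(g)))
      for (i in idx) {
        eps <- 1e-5
        p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-3,
                     label = sprintf("analytic grad %s[%d] (n_out %d)", nm, i, n_out))
      }
    }
  }
})

test_that("U-Net gradients match finite differences", {
  set.seed(43)
  arch <- list(depth = 2L, widths = c(2L, 3L, 4L), in_ch = 2L)
  p <- thermoprick:::with_seed(1, thermoprick:::init_unet_params(2, c(2L, 3L, 4L)))
  # perturb away from the zero-bias init so ReLU masks are generic
  p <- lapply(p, function(w) w + rnorm(length(w), 0, 0.05))
  hw <- 8; N <- 2
  x <- array(rnorm(hw * hw * 2 * N), c(hw, hw, 2, N))
  y <- array(rbinom(hw * hw * N, 1, 0.3), c(hw, hw, 1, N))
  out <- thermoprick:::cpp_unet_fwdbwd(x, y, p, arch)
  for (nm in names(p)) {
    g <- out$grads[[nm]]
    expect_length(g, length(p[[nm]]))
    idx <- sample(length(g), min(4, length(g)))
    for (i in idx) {
      eps <- 1e-5
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (thermoprick:::cpp_unet_fwdbwd(x, y, p1, arch)$loss -
              thermoprick:::cpp_unet_fwdbwd(x, y, p2, arch)$loss) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = sprintf("analytic U-Net grad %s[%d]", nm, i))
    }
  }
})

test_that("inference mode is deterministic and respects running statistics", {
  set.seed(44)
  channels <- c(3L); pool <- c(TRUE)
  arch <- cnn_arch(channels, pool, 1)
  m <- init_tiny_cnn(1, channels, pool, 9)
  x <- array(rnorm(81 * 2), c(9, 9, 1, 2))
  at <- matrix(runif(8), 4, 2)
  f1 <- thermoprick:::cpp_cnn_forward(x, at, m$params, m$state, arch, FALSE, NULL)
  f2 <- thermoprick:::cpp_cnn_forward(x, at, m$params, m$state, arch, FALSE, NULL)
  expect_identical(f1$logits, f2$logits)
  # training mode uses batch statistics: different running stats, same loss
  st2 <- m$state
  st2$bnm1 <- st2$bnm1 + 5
  f3 <- thermoprick:::cpp_cnn_forward(x, at, m$params, st2, arch, FALSE, NULL)
  expect_false(identical(f1$logits, f3$logits))
})

test_that("warp primitive matches direct array shifts and flags support", {
  src <- matrix(rnorm(30 * 20), 30, 20)
  M <- diag(3); M[2, 3] <- 3   # output (r, c) samples source (r, c + 3)
  w <- thermoprick:::cpp_warp_projective(src, M, 30, 20)
  expect_equal(w$pixels[, 1:17], src[, 4:20])
  expect_true(all(!w$valid[, 18:20]))
  ident <- thermoprick:::cpp_warp_projective(src, diag(3), 30, 20)
  expect_identical(ident$pixels, src)
})

test_that("connected-component labelling separates touching-diagonal blobs", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[5:7, 5:7] <- TRUE     # touches the first blob only diagonally
  m[9, 9] <- TRUE
  lab <- thermoprick:::cpp_label_components(m)
  expect_equal(max(lab), 3)  # 4-connectivity keeps diagonal blobs separate
  expect_equal(sum(lab == lab[3, 3]), 9)
  expect_equal(sum(lab > 0), sum(m))
})
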