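# internal helpers shared across modules

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a child seed from a base seed and integer tags, kept below 2^31
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed %% 2147483647)
  for (t in tags) x <- (x * 69069 + as.double(t) * 2654435761) %% 2147483629
  as.integer(x)
}

stop_thermoprick <- function(...) stop(..., call. = FALSE)

# bilinear resize of a matrix or H x W x C array (pixel-centre aligned)
resize_bilinear <- function(img, out_h, out_w) {
  one <- function(m) {
    h <- nrow(m); w <- ncol(m)
    M <- matrix(c(h / out_h, 0, 0, 0, w / out_w, 0,
                  0.5 - 0.5 * h / out_h, 0.5 - 0.5 * w / out_w, 1), 3, 3)
    cpp_warp_projective(m, M, out_h, out_w)$pixels
  }
  if (length(dim(img)) == 3) {
    out <- array(0, c(out_h, out_w, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- one(img[, , ch])
    out
  } else one(img)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

config_hash <- function(x) cpp_fnv1a(serialize(x, NULL, version = 2))
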