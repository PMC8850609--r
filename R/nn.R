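# Shared neural-network plumbing for the compiled engine: parameter
# initialisation and the Adam / AdamW optimiser acting on named parameter
# lists.  Forward and backward passes live in src/nn_ops.cpp; gradients are
# verified against finite differences in the test suite.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step; decoupled weight decay (AdamW) is applied to weight tensors
# only (names starting with "cw", "fw", "w"), never to biases or batch-norm
# scale/shift, following common practice for decoupled regularisation.
adam_step <- function(params, grads, opt, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / b1t) / (sqrt(opt$v[[nm]] / b2t) + eps)
    if (weight_decay > 0 && grepl("^(cw|fw|w)", nm))
      step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}

# dropout mask for one batch, drawn from the R RNG (keeps training fully
# reproducible from set.seed); inverted-dropout scaling included
dropout_mask <- function(hidden, n, p) {
  if (p <= 0) return(matrix(1, hidden, n))
  matrix(rbinom(hidden * n, 1, 1 - p) / (1 - p), hidden, n)
}
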