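# Shared pieces of the small conv-net engine: weight initializers matching
# the compiled kernels' layout conventions, ReLU/sigmoid, numerically clipped
# binary cross-entropy, and Adam/AdamW over flat named parameter lists.
#
# Layout conventions (must match src/nn_ops.cpp):
#   3x3 conv weight: matrix (9*Cin) x Cout, row = c*9 + (dj+1)*3 + (di+1)
#   2x2 transposed-conv weight: matrix Cin x (4*Cout), col = q*Cout + co,
#     quadrant q = dj*2 + di
#   1x1 conv weight: plain Cin x Cout matrix applied to the (HW x C) unfold

init_conv3 <- function(cin, cout) {
  matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout)
}

init_convt2 <- function(cin, cout) {
  matrix(rnorm(cin * 4 * cout, sd = sqrt(2 / cin)), cin, 4 * cout)
}

init_dense <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean binary cross-entropy with clipping to avoid log(0); y and p may be
# arrays of any (common) shape.
bce_mean <- function(y, p, clip = 1e-7) {
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Conv application to the channel unfold: x is H x W x C.
conv1x1 <- function(x, w, b) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2]) %*% w
  m <- sweep(m, 2, b, "+")
  array(m, c(d[1], d[2], ncol(w)))
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

accum_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

# Adam with optional decoupled weight decay (AdamW). State and parameters
# are flat named lists of numeric arrays/matrices/vectors.
optimizer_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L,
       m = zeros_like(params), v = zeros_like(params))
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    if (opt$weight_decay > 0)
      upd <- upd + opt$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - opt$lr * upd
  }
  list(opt = opt, params = params)
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}
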