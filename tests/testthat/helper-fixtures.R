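# Shared in-code fixtures for the unit tests. Everything is generated at
# test time; nothing is read from disk except trees the tests write
# themselves under tempdir().

# Tiny placeholder labeled images (s x s x 3, constant intensity per label).
tiny_records <- function(n, s = 2L, labels = rep(0L, n)) {
  lapply(seq_len(n), function(i) {
    labeled_image(array((labels[i] + 1) * 40, c(s, s, 3)), labels[i],
                  sprintf("rec%04d", i))
  })
}

# Linearly separable two-class set: uniform dark vs uniform bright images
# with mild noise, the classic sanity fixture for a supervised stage.
bright_dark_records <- function(n_per_class = 10, s = 16, seed = 1) {
  withr::with_seed(seed, {
    recs <- list()
    for (k in 0:1) {
      base <- if (k == 0) 60 else 190
      for (i in seq_len(n_per_class)) {
        px <- pmin(pmax(array(base + rnorm(s * s * 3, sd = 10), c(s, s, 3)),
                        0), 255)
        recs[[length(recs) + 1L]] <- labeled_image(px, k,
                                                   sprintf("c%d_%02d", k, i))
      }
    }
    recs
  })
}

# Independent brute-force metric oracles (naive loops, no vectorization),
# used to cross-check the packaged implementations.
dice_bruteforce <- function(y, yhat) {
  inter <- 0; sy <- 0; syh <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) inter <- inter + 1
    if (y[i] == 1) sy <- sy + 1
    if (yhat[i] == 1) syh <- syh + 1
  }
  if (sy + syh == 0) return(1)
  2 * inter / (sy + syh)
}

iou_bruteforce <- function(y, yhat, eps = 1e-7) {
  inter <- 0; uni <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) inter <- inter + 1
    if (y[i] == 1 || yhat[i] == 1) uni <- uni + 1
  }
  inter / (uni + eps)
}

pixacc_bruteforce <- function(y, yhat) {
  ok <- 0
  for (i in seq_along(y)) if (y[i] == yhat[i]) ok <- ok + 1
  ok / length(y)
}

random_mask_pair <- function(s = 8, p = 0.4) {
  list(y = matrix(rbinom(s * s, 1, p), s, s),
       yhat = matrix(rbinom(s * s, 1, p), s, s))
}

# Minimal run configuration pointed at tempdir-scale problems.
tiny_run_config <- function(out, seed = 1L) {
  cfg <- default_run_config()
  cfg$seed <- seed
  cfg$output_dir <- out
  cfg$fixtures$classification <- list(num_classes = 2L, n_per_class = 6L,
                                      image_size = 16L, noise_sd = 8)
  cfg$fixtures$segmentation <- list(n = 6L, image_size = 16L,
                                    noise_sd = 0.02, contrast = 0.4)
  cfg$data$image_size <- 16L
  cfg$data$seg_size <- 16L
  cfg$cnn$epochs <- 1L
  cfg$q$episodes <- 5L
  cfg$q$max_steps <- 10L
  cfg$unet <- list(depth = 2L, base_filters = 4L, attention = TRUE)
  cfg$seg_train$epochs <- 1L
  cfg
}
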