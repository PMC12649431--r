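#' Configure the feature-extraction CNN
#'
#' The classification backbone is a compact convolutional network trained
#' from scratch: conv(32 filters, 3x3) -> ReLU -> maxpool(2x2) ->
#' conv(64, 3x3) -> ReLU -> maxpool(2x2) -> flatten -> dense(64) + ReLU,
#' followed by a K-way classification head used only during supervised
#' pretraining. With same padding a 64x64x3 input flows through feature
#' maps 64x64x32 -> 32x32x32 -> 32x32x64 -> 16x16x64 -> 16384 -> 64. The
#' 64-dimensional non-negative embedding is the Q-learning agent's raw
#' state.
#'
#' @param num_classes number of classes K for the pretraining head.
#' @param input_size input side length (64).
#' @param channels input channels (3).
#' @param conv1_filters,conv2_filters filter counts of the two conv stages.
#' @param fc_dim embedding width (64).
#' @param padding_mode `"same"` padding keeps the clean 64->32->16 spatial
#'   chain; it is the only mode implemented.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(num_classes, input_size = 64, channels = 3,
                       conv1_filters = 32, conv2_filters = 64, fc_dim = 64,
                       padding_mode = "same") {
  padding_mode <- match.arg(padding_mode, "same")
  if (any(c(num_classes, input_size, channels, conv1_filters, conv2_filters,
            fc_dim) <= 0))
    stop("all architecture dimensions must be positive")
  if (input_size %% 4 != 0)
    stop("input_size must be divisible by 4 (two 2x2 pooling stages)")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 fc_dim = as.integer(fc_dim),
                 padding_mode = padding_mode),
            class = "cnn_config")
}

#' Configure supervised CNN pretraining
#'
#' Defaults follow the classification-stage training hyperparameters:
#' AdamW optimizer, batch size 32, and element-wise binary cross-entropy on
#' one-hot targets with sigmoid outputs (a categorical cross-entropy switch
#' is provided).
#'
#' @param epochs training epochs (default 10).
#' @param batch_size minibatch size (32).
#' @param optimizer `"adamw"` or `"adam"`.
#' @param loss `"bce"` (per-class binary cross-entropy on one-hot targets)
#'   or `"cce"` (categorical cross-entropy with softmax).
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay for AdamW.
#' @param seed integer seed for shuffling.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(epochs = 10, batch_size = 32,
                            optimizer = c("adamw", "adam"),
                            loss = c("bce", "cce"), lr = 1e-3,
                            weight_decay = 1e-4, seed = 0L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer), loss = match.arg(loss),
                 lr = lr, weight_decay = weight_decay, seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Build the CNN with seeded initialization
#'
#' @param config a [cnn_config()].
#' @param seed integer seed for He-normal weight initialization.
#' @return A `gastroq_cnn` object (untrained, `frozen = FALSE`).
#' @export
build_cnn <- function(config, seed = 0L) {
  stopifnot(inherits(config, "cnn_config"))
  s4 <- config$input_size / 4
  flat_dim <- s4 * s4 * config$conv2_filters
  params <- withr::with_seed(as.integer(seed), list(
    c1.w = init_conv3(config$channels, config$conv1_filters),
    c1.b = numeric(config$conv1_filters),
    c2.w = init_conv3(config$conv1_filters, config$conv2_filters),
    c2.b = numeric(config$conv2_filters),
    fc.w = init_dense(flat_dim, config$fc_dim),
    fc.b = numeric(config$fc_dim),
    head.w = init_dense(config$fc_dim, config$num_classes),
    head.b = numeric(config$num_classes)
  ))
  structure(list(params = params, config = config, frozen = FALSE,
                 history = NULL),
            class = "gastroq_cnn")
}

# Forward pass for one H x W x C input in [0, 1]; returns the embedding f,
# class probabilities, and (optionally) everything needed for backprop.
cnn_forward <- function(params, x, loss = "bce", cache = FALSE) {
  z1 <- conv3_fw(x, params$c1.w, params$c1.b)
  p1 <- maxpool2_fw(relu(z1))
  z2 <- conv3_fw(p1$y, params$c2.w, params$c2.b)
  p2 <- maxpool2_fw(relu(z2))
  flat <- as.vector(p2$y)
  fz <- drop(crossprod(params$fc.w, flat)) + params$fc.b
  f <- relu(fz)
  logits <- drop(crossprod(params$head.w, f)) + params$head.b
  prob <- if (loss == "cce") {
    e <- exp(logits - max(logits)); e / sum(e)
  } else sigmoid(logits)
  out <- list(f = f, prob = prob)
  if (cache)
    out <- c(out, list(x = x, z1 = z1, p1 = p1, z2 = z2, p2 = p2,
                       flat = flat, fz = fz))
  out
}

# Backward pass from the head loss; returns flat gradient list.
cnn_backward <- function(params, fw, y_onehot, loss = "bce") {
  K <- length(y_onehot)
  dlog <- if (loss == "cce") fw$prob - y_onehot else (fw$prob - y_onehot) / K
  g <- list()
  g$head.w <- outer(fw$f, dlog)
  g$head.b <- dlog
  df <- drop(params$head.w %*% dlog) * (fw$fz > 0)
  g$fc.w <- outer(fw$flat, df)
  g$fc.b <- df
  dflat <- array(drop(params$fc.w %*% df), dim(fw$p2$y))
  da2 <- maxpool2_bw(dflat, fw$p2$idx, dim(fw$z2)[1], dim(fw$z2)[2])
  bw2 <- conv3_bw(fw$p1$y, params$c2.w, da2 * (fw$z2 > 0))
  g$c2.w <- bw2$gw
  g$c2.b <- as.vector(bw2$gb)
  da1 <- maxpool2_bw(bw2$gx, fw$p1$idx, dim(fw$z1)[1], dim(fw$z1)[2])
  bw1 <- conv3_bw(fw$x, params$c1.w, da1 * (fw$z1 > 0))
  g$c1.w <- bw1$gw
  g$c1.b <- as.vector(bw1$gb)
  g
}

record_input <- function(rec) {
  if (inherits(rec, "labeled_image")) normalize_intensity(rec$pixels)
  else if (is.array(rec) && length(dim(rec)) == 3L) {
    if (max(rec) > 1 || min(rec) < 0)
      stop("plain array inputs must already be normalized to [0, 1]")
    rec
  } else stop("expected a labeled_image or an H x W x C array")
}

#' Supervised CNN pretraining
#'
#' Trains the full network (backbone plus classification head) on labeled
#' images, then freezes the backbone so that feature extraction is
#' deterministic; the trained head stays attached for inspection but plays
#' no role downstream. Images enter as 0--255 records and are rescaled to
#' `[0, 1]` internally.
#'
#' @param model an untrained `gastroq_cnn` from [build_cnn()].
#' @param train non-empty list of [labeled_image()] records.
#' @param cfg a [pretrain_config()].
#' @return The model with `frozen = TRUE` and a `history` tibble
#'   (`epoch`, `loss`, `accuracy`).
#' @export
pretrain_cnn <- function(model, train, cfg = pretrain_config()) {
  stopifnot(inherits(model, "gastroq_cnn"), inherits(cfg, "pretrain_config"))
  if (!length(train)) stop("empty training set")
  params <- model$params
  K <- model$config$num_classes
  labels <- vapply(train, function(r) r$label, integer(1))
  if (any(labels < 0 | labels >= K)) stop("labels must lie in [0, K-1]")
  inputs <- lapply(train, record_input)
  hist <- NULL
  if (cfg$epochs > 0) {
    wd <- if (cfg$optimizer == "adamw") cfg$weight_decay else 0
    opt <- optimizer_new(params, lr = cfg$lr, weight_decay = wd)
    n <- length(inputs)
    withr::with_seed(cfg$seed, {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        ep_correct <- 0L
        for (start in seq(1, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          grads <- NULL
          for (i in idx) {
            fw <- cnn_forward(params, inputs[[i]], cfg$loss, cache = TRUE)
            y <- numeric(K)
            y[labels[i] + 1L] <- 1
            ep_loss <- ep_loss + if (cfg$loss == "cce")
              -log(max(fw$prob[labels[i] + 1L], 1e-12)) else bce_mean(y, fw$prob)
            ep_correct <- ep_correct + (which.max(fw$prob) - 1L == labels[i])
            grads <- accum_grads(grads, cnn_backward(params, fw, y, cfg$loss))
          }
          st <- optimizer_step(opt, params, scale_grads(grads, 1 / length(idx)))
          opt <- st$opt
          params <- st$params
        }
        hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                       accuracy = ep_correct / n))
      }
    })
  }
  model$params <- params
  model$frozen <- TRUE
  model$history <- if (is.null(hist)) tibble::tibble(epoch = integer(),
                                                     loss = numeric(),
                                                     accuracy = numeric())
  else tibble::as_tibble(hist)
  model
}

#' Extract the frozen 64-d feature embedding
#'
#' Runs the frozen backbone on one image and returns the non-negative
#' post-ReLU embedding `f` that serves as the Q-agent's raw state. The
#' model must be frozen (pretrained) so the mapping is deterministic.
#'
#' @param model a frozen `gastroq_cnn`.
#' @param image a [labeled_image()] (0--255 scale) or an `H x W x C` array
#'   already in `[0, 1]`.
#' @return Numeric vector of length `fc_dim` (64), all entries >= 0.
#' @export
extract_features <- function(model, image) {
  stopifnot(inherits(model, "gastroq_cnn"))
  if (!model$frozen) stop("model must be frozen (pretrained) before feature extraction")
  x <- record_input(image)
  if (!all(dim(x) == c(model$config$input_size, model$config$input_size,
                       model$config$channels)))
    stop("input shape does not match the configured ",
         model$config$input_size, "x", model$config$input_size, "x",
         model$config$channels)
  cnn_forward(model$params, x)$f
}

#' Extract features for a list of records
#'
#' @param model a frozen `gastroq_cnn`.
#' @param records list of [labeled_image()] records.
#' @return List with `features` (n x 64 matrix, one row per record) and
#'   `labels` (integer vector, `NA` where a record has no label).
#' @export
extract_feature_matrix <- function(model, records) {
  feats <- t(vapply(records, function(r) extract_features(model, r),
                    numeric(model$config$fc_dim)))
  list(features = feats,
       labels = vapply(records, record_label, integer(1)))
}

#' @export
print.gastroq_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<gastroq_cnn> ", cfg$input_size, "x", cfg$input_size, "x", cfg$channels,
      " -> conv", cfg$conv1_filters, "/pool -> conv", cfg$conv2_filters,
      "/pool -> f[", cfg$fc_dim, "] -> head[", cfg$num_classes, "]  ",
      if (x$frozen) "(frozen)" else "(untrained)", "\n", sep = "")
  invisible(x)
}
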