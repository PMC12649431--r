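#' Configure the attention U-Net segmenter
#'
#' An encoder-decoder segmentation network: `depth` encoder levels of two
#' 3x3 conv + ReLU each with 2x2 max pooling between, a bridge block,
#' and a decoder that upsamples with 2x2 stride-2 transposed convolutions.
#' Before each skip concatenation an additive attention gate rescales the
#' encoder features by per-location coefficients in (0, 1) computed from the
#' skip and the coarser gating signal; a final 1x1 convolution with sigmoid
#' yields a per-pixel foreground probability.
#'
#' @param input_size input side length, divisible by `2^depth` (128).
#' @param in_channels input channels (3).
#' @param depth number of encoder levels (4).
#' @param base_filters filters at the first level, doubling per level (16).
#' @param attention_on_skips gate the skips (`TRUE`); `FALSE` gives a plain
#'   U-Net with identical shapes.
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_size = 128, in_channels = 3, depth = 4,
                        base_filters = 16, attention_on_skips = TRUE) {
  if (depth < 1 || base_filters < 1 || in_channels < 1)
    stop("all architecture dimensions must be positive")
  if (input_size %% (2^depth) != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 attention_on_skips = isTRUE(attention_on_skips)),
            class = "unet_config")
}

#' Configure segmentation training
#'
#' Defaults follow the published segmentation-stage hyperparameters: batch
#' size 8, Adam optimizer, 50 epochs, pixel-wise binary cross-entropy loss
#' (predictions clipped at 1e-7 to avoid log(0)), prediction threshold 0.5.
#'
#' @param epochs training epochs (50).
#' @param batch_size minibatch size (8).
#' @param lr Adam learning rate.
#' @param threshold probability cut for binary masks (0.5).
#' @param seed integer seed for shuffling.
#' @return A `seg_train_config` list.
#' @export
seg_train_config <- function(epochs = 50, batch_size = 8, lr = 1e-3,
                             threshold = 0.5, seed = 0L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 threshold = threshold, seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Attention gate parameters
#'
#' Creates the trainable parameters of one additive attention gate: 1x1
#' projections `wf` (skip, no bias) and `wg` (gating signal, with bias)
#' into an intermediate space, and a single-channel 1x1 projection `psi`
#' whose sigmoid gives the attention coefficients. With all parameters
#' zero the gate reduces exactly to a 0.5 scaling of the skip.
#'
#' @param cx skip feature channels.
#' @param cg gating feature channels.
#' @param cint intermediate channels (default `cx`).
#' @param init `"he"` (seeded random) or `"zero"`.
#' @param seed seed for `"he"` initialization.
#' @return Named list `wf`, `wg`, `bg`, `psi`, `bpsi`.
#' @export
attention_params <- function(cx, cg, cint = cx, init = c("he", "zero"),
                             seed = 0L) {
  init <- match.arg(init)
  if (init == "zero")
    return(list(wf = matrix(0, cx, cint), wg = matrix(0, cg, cint),
                bg = numeric(cint), psi = matrix(0, cint, 1),
                bpsi = numeric(1)))
  withr::with_seed(as.integer(seed), list(
    wf = init_dense(cx, cint), wg = init_dense(cg, cint),
    bg = numeric(cint), psi = init_dense(cint, 1), bpsi = numeric(1)))
}

# Attention gate forward. x: H x W x Cx skip features; g: (H/2) x (W/2) x Cg
# gating signal from the coarser level. Both are projected with 1x1 convs,
# the gating projection bilinearly resized to x's spatial dims, summed,
# passed through ReLU and a single-channel 1x1 projection, and squashed with
# a sigmoid into coefficients alpha in (0,1); the gated output is alpha * x.
att_forward <- function(x, g, pr, cache = FALSE) {
  fx <- conv1x1(x, pr$wf, numeric(ncol(pr$wf)))
  gg <- conv1x1(g, pr$wg, pr$bg)
  gu <- up2_bilinear_fw(gg)
  if (!all(dim(gu)[1:2] == dim(x)[1:2]))
    stop("gating signal must come from the adjacent (half-resolution) level")
  s_pre <- fx + gu
  s <- relu(s_pre)
  d <- dim(s)
  h <- matrix(s, d[1] * d[2]) %*% pr$psi + pr$bpsi
  alpha <- array(sigmoid(h), d[1:2])
  xg <- x * as.vector(alpha)  # broadcast over channels (column-major)
  out <- list(xg = xg, alpha = alpha)
  if (cache) out <- c(out, list(x = x, g = g, s_pre = s_pre, s = s))
  out
}

att_backward <- function(ca, pr, dxg) {
  d <- dim(ca$x)
  hw <- d[1] * d[2]
  alpha_v <- as.vector(ca$alpha)
  dalpha <- rowSums(matrix(dxg * ca$x, hw))
  dx <- dxg * alpha_v
  dh <- dalpha * alpha_v * (1 - alpha_v)
  s_m <- matrix(ca$s, hw)
  g_psi <- crossprod(s_m, dh)
  ds <- array(tcrossprod(dh, pr$psi), dim(ca$s))
  ds_pre <- ds * (ca$s_pre > 0)
  ds_m <- matrix(ds_pre, hw)
  x_m <- matrix(ca$x, hw)
  g_wf <- crossprod(x_m, ds_m)
  dx <- dx + array(tcrossprod(ds_m, pr$wf), d)
  dgg <- up2_bilinear_bw(array(ds_pre, dim(ca$s_pre)))
  dg_m <- matrix(dgg, prod(dim(dgg)[1:2]))
  g_m <- matrix(ca$g, prod(dim(ca$g)[1:2]))
  g_wg <- crossprod(g_m, dg_m)
  g_bg <- colSums(dg_m)
  dg <- array(tcrossprod(dg_m, pr$wg), dim(ca$g))
  list(dx = dx, dg = dg,
       grads = list(wf = g_wf, wg = g_wg, bg = g_bg, psi = g_psi,
                    bpsi = sum(dh)))
}

#' Apply an attention gate to a skip feature map
#'
#' Standalone forward application of the additive attention gate, returning
#' the gated features and the coefficient map. The gating signal `g` must
#' come from the adjacent coarser level (half the spatial resolution of
#' `x`); it is projected, bilinearly resized to `x`'s dims, combined with
#' the projected skip, and squashed to coefficients in (0, 1).
#'
#' @param x skip feature map, `H x W x Cx`.
#' @param g gating feature map, `(H/2) x (W/2) x Cg`.
#' @param params an [attention_params()] list.
#' @return List with `gated` (`H x W x Cx`, equals `alpha * x`) and
#'   `alpha` (`H x W` matrix of coefficients in (0, 1)).
#' @export
attention_gate <- function(x, g, params) {
  x <- as_cube(x)
  g <- as_cube(g)
  if (nrow(params$wf) != dim(x)[3])
    stop("skip channel count does not match the wf projection")
  if (nrow(params$wg) != dim(g)[3])
    stop("gating channel count does not match the wg projection")
  fw <- att_forward(x, g, params)
  list(gated = fw$xg, alpha = fw$alpha)
}

att_names <- c("wf", "wg", "bg", "psi", "bpsi")

#' Build the attention U-Net with seeded initialization
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for He-normal initialization.
#' @return A `gastroq_unet` model object.
#' @export
build_attention_unet <- function(cfg = unet_config(), seed = 0L) {
  stopifnot(inherits(cfg, "unet_config"))
  filt <- cfg$base_filters * 2^(seq_len(cfg$depth) - 1L)
  bridge_f <- cfg$base_filters * 2^cfg$depth
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    cin <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      p[[paste0("enc", l, ".c1.w")]] <- init_conv3(cin, filt[l])
      p[[paste0("enc", l, ".c1.b")]] <- numeric(filt[l])
      p[[paste0("enc", l, ".c2.w")]] <- init_conv3(filt[l], filt[l])
      p[[paste0("enc", l, ".c2.b")]] <- numeric(filt[l])
      cin <- filt[l]
    }
    p[["bridge.c1.w"]] <- init_conv3(filt[cfg$depth], bridge_f)
    p[["bridge.c1.b"]] <- numeric(bridge_f)
    p[["bridge.c2.w"]] <- init_conv3(bridge_f, bridge_f)
    p[["bridge.c2.b"]] <- numeric(bridge_f)
    for (l in rev(seq_len(cfg$depth))) {
      c_below <- if (l == cfg$depth) bridge_f else filt[l + 1L]
      p[[paste0("dec", l, ".up.w")]] <- init_convt2(c_below, filt[l])
      p[[paste0("dec", l, ".up.b")]] <- numeric(filt[l])
      if (cfg$attention_on_skips) {
        ap <- attention_params(filt[l], c_below, filt[l], init = "he",
                               seed = sample.int(.Machine$integer.max, 1))
        for (nm in att_names) p[[paste0("dec", l, ".att.", nm)]] <- ap[[nm]]
      }
      p[[paste0("dec", l, ".c1.w")]] <- init_conv3(2L * filt[l], filt[l])
      p[[paste0("dec", l, ".c1.b")]] <- numeric(filt[l])
      p[[paste0("dec", l, ".c2.w")]] <- init_conv3(filt[l], filt[l])
      p[[paste0("dec", l, ".c2.b")]] <- numeric(filt[l])
    }
    p[["out.w"]] <- init_dense(filt[1], 1)
    p[["out.b"]] <- numeric(1)
    p
  })
  structure(list(params = params, config = cfg, history = NULL,
                 trained = FALSE),
            class = "gastroq_unet")
}

cat3 <- function(a, b) {
  da <- dim(a)
  array(c(a, b), c(da[1], da[2], da[3] + dim(b)[3]))
}

unet_forward <- function(params, cfg, x, cache = FALSE) {
  cc <- list(x = x, enc = vector("list", cfg$depth),
             dec = vector("list", cfg$depth))
  cur <- x
  for (l in seq_len(cfg$depth)) {
    z1 <- conv3_fw(cur, params[[paste0("enc", l, ".c1.w")]],
                   params[[paste0("enc", l, ".c1.b")]])
    a1 <- relu(z1)
    z2 <- conv3_fw(a1, params[[paste0("enc", l, ".c2.w")]],
                   params[[paste0("enc", l, ".c2.b")]])
    a2 <- relu(z2)
    pl <- maxpool2_fw(a2)
    cc$enc[[l]] <- list(input = cur, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                        pool = pl)
    cur <- pl$y
  }
  zb1 <- conv3_fw(cur, params[["bridge.c1.w"]], params[["bridge.c1.b"]])
  ab1 <- relu(zb1)
  zb2 <- conv3_fw(ab1, params[["bridge.c2.w"]], params[["bridge.c2.b"]])
  ab2 <- relu(zb2)
  cc$bridge <- list(input = cur, z1 = zb1, a1 = ab1, z2 = zb2, a2 = ab2)
  below <- ab2
  for (l in rev(seq_len(cfg$depth))) {
    up <- convt2_fw(below, params[[paste0("dec", l, ".up.w")]],
                    params[[paste0("dec", l, ".up.b")]])
    skip <- cc$enc[[l]]$a2
    if (cfg$attention_on_skips) {
      ap <- lapply(stats::setNames(att_names, att_names),
                   function(nm) params[[paste0("dec", l, ".att.", nm)]])
      at <- att_forward(skip, below, ap, cache = TRUE)
      gated <- at$xg
    } else {
      at <- NULL
      gated <- skip
    }
    catted <- cat3(gated, up)
    z1 <- conv3_fw(catted, params[[paste0("dec", l, ".c1.w")]],
                   params[[paste0("dec", l, ".c1.b")]])
    a1 <- relu(z1)
    z2 <- conv3_fw(a1, params[[paste0("dec", l, ".c2.w")]],
                   params[[paste0("dec", l, ".c2.b")]])
    a2 <- relu(z2)
    cc$dec[[l]] <- list(below = below, up = up, att = at, cat = catted,
                        z1 = z1, a1 = a1, z2 = z2, a2 = a2)
    below <- a2
  }
  d <- dim(below)
  logits <- matrix(matrix(below, d[1] * d[2]) %*% params[["out.w"]] +
                     params[["out.b"]], d[1], d[2])
  prob <- sigmoid(logits)
  out <- list(prob = prob, logits = logits)
  if (cache) out$cache <- cc
  out
}

# Backward from dlogits (H x W grad at the pre-sigmoid output).
unet_backward <- function(params, cfg, cc, dlogits) {
  g <- list()
  dec1_out <- cc$dec[[1]]$a2
  d <- dim(dec1_out)
  hw <- d[1] * d[2]
  dl <- as.vector(dlogits)
  g[["out.w"]] <- crossprod(matrix(dec1_out, hw), dl)
  g[["out.b"]] <- sum(dl)
  d_out <- array(tcrossprod(dl, params[["out.w"]]), d)
  dskip <- vector("list", cfg$depth)
  d_below_next <- NULL
  for (l in seq_len(cfg$depth)) {
    dc <- cc$dec[[l]]
    d_a2 <- if (l == 1) d_out else d_below_next
    bw2 <- conv3_bw(dc$a1, params[[paste0("dec", l, ".c2.w")]],
                    d_a2 * (dc$z2 > 0))
    g[[paste0("dec", l, ".c2.w")]] <- bw2$gw
    g[[paste0("dec", l, ".c2.b")]] <- as.vector(bw2$gb)
    bw1 <- conv3_bw(dc$cat, params[[paste0("dec", l, ".c1.w")]],
                    bw2$gx * (dc$z1 > 0))
    g[[paste0("dec", l, ".c1.w")]] <- bw1$gw
    g[[paste0("dec", l, ".c1.b")]] <- as.vector(bw1$gb)
    nf <- dim(dc$up)[3]
    dcat <- bw1$gx
    d_gated <- dcat[, , seq_len(nf), drop = FALSE]
    d_up <- dcat[, , nf + seq_len(nf), drop = FALSE]
    d_below <- 0
    if (cfg$attention_on_skips) {
      ap <- lapply(stats::setNames(att_names, att_names),
                   function(nm) params[[paste0("dec", l, ".att.", nm)]])
      ab <- att_backward(dc$att, ap, d_gated)
      for (nm in att_names)
        g[[paste0("dec", l, ".att.", nm)]] <- ab$grads[[nm]]
      dskip[[l]] <- ab$dx
      d_below <- ab$dg
    } else {
      dskip[[l]] <- d_gated
    }
    bwu <- convt2_bw(dc$below, params[[paste0("dec", l, ".up.w")]], d_up)
    g[[paste0("dec", l, ".up.w")]] <- bwu$gw
    g[[paste0("dec", l, ".up.b")]] <- as.vector(bwu$gb)
    d_below_next <- bwu$gx + d_below
  }
  br <- cc$bridge
  bwb2 <- conv3_bw(br$a1, params[["bridge.c2.w"]],
                   d_below_next * (br$z2 > 0))
  g[["bridge.c2.w"]] <- bwb2$gw
  g[["bridge.c2.b"]] <- as.vector(bwb2$gb)
  bwb1 <- conv3_bw(br$input, params[["bridge.c1.w"]], bwb2$gx * (br$z1 > 0))
  g[["bridge.c1.w"]] <- bwb1$gw
  g[["bridge.c1.b"]] <- as.vector(bwb1$gb)
  d_pool <- bwb1$gx
  for (l in rev(seq_len(cfg$depth))) {
    ec <- cc$enc[[l]]
    d_a2 <- maxpool2_bw(d_pool, ec$pool$idx, dim(ec$a2)[1], dim(ec$a2)[2]) +
      dskip[[l]]
    bw2 <- conv3_bw(ec$a1, params[[paste0("enc", l, ".c2.w")]],
                    d_a2 * (ec$z2 > 0))
    g[[paste0("enc", l, ".c2.w")]] <- bw2$gw
    g[[paste0("enc", l, ".c2.b")]] <- as.vector(bw2$gb)
    bw1 <- conv3_bw(ec$input, params[[paste0("enc", l, ".c1.w")]],
                    bw2$gx * (ec$z1 > 0))
    g[[paste0("enc", l, ".c1.w")]] <- bw1$gw
    g[[paste0("enc", l, ".c1.b")]] <- as.vector(bw1$gb)
    d_pool <- bw1$gx
  }
  g
}

seg_input <- function(rec) {
  if (inherits(rec, "seg_pair")) rec$image
  else if (is.array(rec) && length(dim(rec)) == 3L) rec
  else stop("expected a seg_pair or an H x W x C array in [0, 1]")
}

#' Train the attention U-Net
#'
#' Minimizes pixel-wise binary cross-entropy with Adam over minibatches.
#' When a validation set is supplied, per-epoch validation loss, pixel
#' accuracy and Dice (at the prediction threshold) are recorded alongside
#' the training loss.
#'
#' @param model a `gastroq_unet` from [build_attention_unet()].
#' @param pairs_train non-empty list of [seg_pair()] records.
#' @param cfg a [seg_train_config()].
#' @param validation optional list of [seg_pair()] records.
#' @return The trained model; `model$history` is a tibble with columns
#'   `epoch`, `loss` and, with validation, `val_loss`, `val_accuracy`,
#'   `val_dice`.
#' @export
train_segmenter <- function(model, pairs_train, cfg = seg_train_config(),
                            validation = NULL) {
  stopifnot(inherits(model, "gastroq_unet"),
            inherits(cfg, "seg_train_config"))
  if (!length(pairs_train)) stop("empty training set")
  params <- model$params
  ucfg <- model$config
  opt <- optimizer_new(params, lr = cfg$lr)
  n <- length(pairs_train)
  hist <- NULL
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        grads <- NULL
        for (i in idx) {
          pr <- pairs_train[[i]]
          fw <- unet_forward(params, ucfg, pr$image, cache = TRUE)
          ep_loss <- ep_loss + bce_mean(pr$mask, fw$prob)
          dlogits <- (fw$prob - pr$mask) / length(pr$mask)
          grads <- accum_grads(grads,
                               unet_backward(params, ucfg, fw$cache, dlogits))
        }
        st <- optimizer_step(opt, params, scale_grads(grads, 1 / length(idx)))
        opt <- st$opt
        params <- st$params
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n)
      if (!is.null(validation)) {
        vl <- 0; vacc <- 0; vdice <- 0
        for (pr in validation) {
          fw <- unet_forward(params, ucfg, pr$image)
          vl <- vl + bce_mean(pr$mask, fw$prob)
          pred <- ifelse(fw$prob >= cfg$threshold, 1, 0)
          vacc <- vacc + pixel_accuracy(pr$mask, pred)
          vdice <- vdice + dice_score(pr$mask, pred)
        }
        nv <- length(validation)
        row$val_loss <- vl / nv
        row$val_accuracy <- vacc / nv
        row$val_dice <- vdice / nv
      }
      hist <- rbind(hist, row)
    }
  })
  model$params <- params
  model$history <- if (is.null(hist)) tibble::tibble(epoch = integer(),
                                                     loss = numeric())
  else tibble::as_tibble(hist)
  model$trained <- TRUE
  model
}

#' Predict a segmentation mask
#'
#' Runs the network forward and thresholds the per-pixel foreground
#' probability at `threshold` (probabilities >= threshold become 1).
#'
#' @param model a `gastroq_unet`.
#' @param image a [seg_pair()] or an `H x W x C` array in `[0, 1]`.
#' @param threshold probability cut (0.5).
#' @return List with `prob` (`H x W` probabilities in (0, 1)) and `mask`
#'   (`H x W` binary matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  stopifnot(inherits(model, "gastroq_unet"))
  x <- seg_input(image)
  if (dim(x)[1] %% (2^model$config$depth) != 0 ||
      dim(x)[2] %% (2^model$config$depth) != 0)
    stop("input spatial dims must be divisible by 2^depth")
  if (dim(x)[3] != model$config$in_channels)
    stop("wrong channel count for this model")
  fw <- unet_forward(model$params, model$config, x)
  list(prob = fw$prob, mask = ifelse(fw$prob >= threshold, 1, 0))
}

#' Score a segmenter on held-out pairs
#'
#' @param model a trained `gastroq_unet`.
#' @param pairs list of [seg_pair()] records.
#' @param threshold probability cut.
#' @return Tibble from [segmentation_scores()], one row per pair.
#' @export
evaluate_segmenter <- function(model, pairs, threshold = 0.5) {
  preds <- lapply(pairs, function(p) predict_mask(model, p, threshold)$mask)
  segmentation_scores(lapply(pairs, `[[`, "mask"), preds,
                      ids = vapply(pairs, `[[`, character(1), "source_id"))
}

#' @export
print.gastroq_unet <- function(x, ...) {
  cfg <- x$config
  cat("<gastroq_unet> depth ", cfg$depth, ", base ", cfg$base_filters,
      ", input ", cfg$input_size, "x", cfg$input_size, "x", cfg$in_channels,
      ", attention ", if (cfg$attention_on_skips) "on" else "off",
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}
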