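#' Specify a synthetic fixture dataset
#'
#' Describes a deterministic synthetic dataset that emulates the statistical
#' structure the pipeline assumes: class-separable colour/texture populations
#' for classification, or bright elliptical "lesions" on textured noisy
#' backgrounds with exact binary masks for segmentation. The same spec and
#' seed always regenerate a bit-identical dataset.
#'
#' Defaults encode the study conditions used throughout the package's tests:
#' 64x64 classification images with pixel noise sd 8 on the 0--255 scale
#' (about 3\% of the dynamic range, typical sensor noise), and segmentation
#' images whose lesions sit `contrast = 0.4` above a background of base
#' intensity 0.35 with a +/-0.06 sinusoidal texture and additive noise sd
#' 0.02 on the `[0, 1]` scale, so that thresholding at the contrast midpoint
#' recovers the mask almost exactly.
#'
#' @param task `"classification"` or `"segmentation"`.
#' @param num_classes number of classes K (classification; K >= 2).
#' @param n_per_class images per class (classification) or `n` total pairs
#'   (segmentation, via `n`).
#' @param n total number of segmentation pairs.
#' @param image_size square side length in pixels.
#' @param noise_sd additive Gaussian pixel noise sd: 0--255 scale for
#'   classification, `[0, 1]` scale for segmentation.
#' @param contrast lesion brightness above the background (segmentation).
#' @param axes_range ellipse semi-axis range as fractions of `image_size`.
#' @param seed integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(task = c("classification", "segmentation"),
                         num_classes = 4, n_per_class = 50, n = 200,
                         image_size = if (match.arg(task) == "classification") 64 else 128,
                         noise_sd = if (match.arg(task) == "classification") 8 else 0.02,
                         contrast = 0.4, axes_range = c(0.08, 0.2),
                         seed = 1L) {
  task <- match.arg(task)
  if (task == "classification" && num_classes < 2) stop("need K >= 2 classes")
  if (any(axes_range <= 0) || max(axes_range) > 0.25)
    stop("ellipse axes must be positive and fit inside the image")
  structure(list(task = task, num_classes = as.integer(num_classes),
                 n_per_class = as.integer(n_per_class), n = as.integer(n),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 contrast = contrast, axes_range = axes_range,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Distinct mean-RGB anchors per class, spread over hue space; together with a
# class-specific sinusoidal texture frequency these make classes separable
# from low-order statistics alone.
class_palette <- function(K) {
  hues <- (seq_len(K) - 1) / K
  t(vapply(hues, function(h) grDevices::col2rgb(grDevices::hsv(h, 0.55, 0.7))[, 1],
           numeric(3)))
}

#' Generate classification fixture records in memory
#'
#' Class `c` images share one deterministic base pattern (a distinct mean
#' RGB plus a sinusoidal texture whose frequency grows with the class index)
#' to which independent Gaussian pixel noise is added, then clipped to
#' `[0, 255]`. With `noise_sd = 0` all images of a class are identical, and
#' a nearest-centroid rule on mean RGB separates the classes perfectly.
#'
#' @param spec a classification [fixture_spec()].
#' @return List of [labeled_image()] records (class-major order).
#' @export
generate_classification_records <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$task == "classification")
  K <- spec$num_classes
  s <- spec$image_size
  pal <- class_palette(K)
  grid_j <- matrix(seq_len(s), s, s, byrow = TRUE)
  withr::with_seed(spec$seed, {
    out <- vector("list", K * spec$n_per_class)
    pos <- 0L
    for (k in seq_len(K)) {
      tex <- 20 * sin(2 * pi * k * grid_j / s)
      base <- array(0, c(s, s, 3))
      for (ch in 1:3) base[, , ch] <- pal[k, ch] + tex
      for (i in seq_len(spec$n_per_class)) {
        px <- base + array(rnorm(s * s * 3, sd = spec$noise_sd), c(s, s, 3))
        px <- pmin(pmax(px, 0), 255)
        pos <- pos + 1L
        out[[pos]] <- labeled_image(px, k - 1L,
                                    sprintf("class%d_img%03d", k - 1L, i))
      }
    }
    out
  })
}

# Rasterize rotated ellipses into a binary indicator mask (union).
ellipse_mask <- function(size, centers, axes, angles) {
  xs <- matrix(seq_len(size), size, size)          # row coordinate
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  m <- matrix(0, size, size)
  for (e in seq_len(nrow(centers))) {
    dx <- xs - centers[e, 1]
    dy <- ys - centers[e, 2]
    ct <- cos(angles[e]); st <- sin(angles[e])
    u <- (dx * ct + dy * st) / axes[e, 1]
    v <- (-dx * st + dy * ct) / axes[e, 2]
    m[u * u + v * v <= 1] <- 1
  }
  m
}

#' Generate segmentation fixture records in memory
#'
#' Every pair is a textured background (base intensity 0.35 plus a seeded
#' sinusoidal pattern) on which 1--3 brighter ellipses are drawn at seeded
#' positions; the mask is the exact ellipse union indicator. The `contrast`
#' knob controls difficulty: at the default high-contrast setting,
#' thresholding the image at the contrast midpoint recovers the mask almost
#' perfectly, which fixes the achievable ceiling near Dice 1.
#'
#' @param spec a segmentation [fixture_spec()].
#' @return List of [seg_pair()] records.
#' @export
generate_segmentation_records <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$task == "segmentation")
  s <- spec$image_size
  xs <- matrix(seq_len(s), s, s)
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      f <- sample(1:3, 1)
      phase <- runif(2, 0, 2 * pi)
      bg <- 0.35 + 0.06 * sin(2 * pi * f * xs / s + phase[1]) *
        sin(2 * pi * f * ys / s + phase[2])
      n_ell <- sample(1:3, 1)
      centers <- cbind(runif(n_ell, 0.3 * s, 0.7 * s),
                       runif(n_ell, 0.3 * s, 0.7 * s))
      axes <- cbind(runif(n_ell, spec$axes_range[1] * s, spec$axes_range[2] * s),
                    runif(n_ell, spec$axes_range[1] * s, spec$axes_range[2] * s))
      angles <- runif(n_ell, 0, pi)
      mask <- ellipse_mask(s, centers, axes, angles)
      plane <- bg + spec$contrast * mask
      img <- array(0, c(s, s, 3))
      for (ch in 1:3)
        img[, , ch] <- pmin(pmax(plane + rnorm(s * s, sd = spec$noise_sd), 0), 1)
      seg_pair(img, mask, sprintf("pair%03d", i))
    })
  })
}

write_png_array <- function(a, path) {
  # png::writePNG expects [0,1]; our H x W x C convention matches its layout
  png::writePNG(pmin(pmax(a, 0), 1), target = path)
}

#' Write a classification fixture dataset tree to disk
#'
#' Materializes [generate_classification_records()] in the per-class-folder
#' layout read by [load_image_dataset()] (`root/<class_name>/*.png`), with a
#' JSON copy of the spec alongside for provenance.
#'
#' @param spec a classification [fixture_spec()].
#' @param root_dir output directory (created if needed).
#' @param class_names optional folder names; default `class0..class{K-1}`.
#' @return Invisibly, the vector of written file paths.
#' @export
make_classification_fixture <- function(spec, root_dir,
                                        class_names = NULL) {
  recs <- generate_classification_records(spec)
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(spec$num_classes) - 1L)
  dir.create(root_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in class_names)
    dir.create(file.path(root_dir, nm), showWarnings = FALSE)
  paths <- vapply(recs, function(r) {
    p <- file.path(root_dir, class_names[r$label + 1L],
                   paste0(r$source_id, ".png"))
    write_png_array(r$pixels / 255, p)
    p
  }, character(1))
  jsonlite::write_json(unclass(spec), file.path(root_dir, "fixture_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a segmentation fixture dataset tree to disk
#'
#' Materializes [generate_segmentation_records()] as matching `images/` and
#' `masks/` folders (stems equal), the layout read by
#' [load_segmentation_pairs()]; masks are written as 8-bit {0, 255} PNGs.
#'
#' @param spec a segmentation [fixture_spec()].
#' @param root_dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
make_segmentation_fixture <- function(spec, root_dir) {
  recs <- generate_segmentation_records(spec)
  img_dir <- file.path(root_dir, "images")
  msk_dir <- file.path(root_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(recs, function(r) {
    pi <- file.path(img_dir, paste0(r$source_id, ".png"))
    pm <- file.path(msk_dir, paste0(r$source_id, ".png"))
    write_png_array(r$image, pi)
    write_png_array(r$mask, pm)
    c(pi, pm)
  }))
  jsonlite::write_json(unclass(spec), file.path(root_dir, "fixture_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
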