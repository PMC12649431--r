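#' Construct a labeled image record
#'
#' A labeled image couples an `H x W x 3` pixel array on the 0--255 intensity
#' scale with an integer class label in `[0, K-1]`. Records of this shape are
#' the unit of the classification stream: loaders produce them, the flip
#' augmenter doubles them, and the hold-out splitter partitions them.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @param label integer class label, zero-based.
#' @param source_id character identifier (usually the file stem).
#' @param augmented logical; `TRUE` for records created by augmentation.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label, source_id, augmented = FALSE) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, label = as.integer(label),
         source_id = as.character(source_id), augmented = isTRUE(augmented)),
    class = "labeled_image"
  )
}

#' Construct an image/mask segmentation pair
#'
#' @param image numeric `H x W x C` array normalized to `[0, 1]`.
#' @param mask numeric or integer `H x W` matrix with values in `{0, 1}`.
#' @param source_id character identifier.
#' @param augmented logical augmentation flag.
#' @return An object of class `seg_pair`.
#' @export
seg_pair <- function(image, mask, source_id, augmented = FALSE) {
  stopifnot(is.array(image), length(dim(image)) == 3L, is.matrix(mask))
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask must share spatial dimensions")
  if (!all(mask %in% c(0, 1))) stop("mask values must be binary {0, 1}")
  if (min(image) < 0 || max(image) > 1)
    stop("segmentation images must be normalized to [0, 1]")
  structure(
    list(image = image, mask = mask, source_id = as.character(source_id),
         augmented = isTRUE(augmented)),
    class = "seg_pair"
  )
}

# Read one PNG/JPEG as an H x W x 3 array in [0, 1]. EBImage stores images
# (x, y, channel); we transpose to the row-major (row, col, channel)
# convention used throughout the package.
read_rgb <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  aperm(a, c(2L, 1L, 3L))
}

# Bilinear (images) or nearest-neighbour (masks) resize of an H x W [x C]
# array to size x size.
resize_array <- function(a, size, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  out <- EBImage::imageData(EBImage::resize(a, w = size, h = size,
                                            filter = filter))
  out
}

#' Load a per-class-folder image dataset
#'
#' Reads a dataset laid out as `root_dir/<class_name>/*.png` (or `.jpg`),
#' resizes every image bilinearly to `size x size x 3`, and assigns each
#' record the zero-based index of its class directory within `class_names`.
#' Pixels are returned on the 0--255 scale; see [normalize_intensity()] for
#' the model-input scaling.
#'
#' @param root_dir dataset root containing one sub-directory per class.
#' @param size target square side length in pixels (64 for classification).
#' @param class_names character vector fixing the label order; every name
#'   must exist as a sub-directory.
#' @return A list of [labeled_image()] records.
#' @export
load_image_dataset <- function(root_dir, size, class_names) {
  stopifnot(length(class_names) >= 1L, size >= 1L)
  if (!dir.exists(root_dir)) stop("dataset root does not exist: ", root_dir)
  missing <- class_names[!dir.exists(file.path(root_dir, class_names))]
  if (length(missing))
    stop("missing class director", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "))
  records <- list()
  for (k in seq_along(class_names)) {
    cls_dir <- file.path(root_dir, class_names[k])
    files <- sort(list.files(cls_dir, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("class directory is empty: ", cls_dir)
    for (f in files) {
      a <- resize_array(read_rgb(f), size, "bilinear")
      a <- pmin(pmax(a, 0), 1) * 255
      records[[length(records) + 1L]] <- labeled_image(
        a, label = k - 1L,
        source_id = tools::file_path_sans_ext(basename(f))
      )
    }
  }
  records
}

#' Rescale pixel intensities from 0--255 to 0--1
#'
#' Applies the exact linear map `I' = I / 255` used to prepare network
#' inputs, so 255 maps to 1 and 0 to 0.
#'
#' @param image numeric array with values in `[0, 255]`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(image) {
  if (min(image) < 0 || max(image) > 255)
    stop("intensities outside [0, 255]")
  image / 255
}

# Flip an H x W [x C] array left-right ("horizontal") or top-bottom
# ("vertical").
flip_array <- function(a, axis) {
  d <- dim(a)
  if (axis == "horizontal") {
    if (length(d) == 2L) a[, d[2]:1] else a[, d[2]:1, , drop = FALSE]
  } else {
    if (length(d) == 2L) a[d[1]:1, ] else a[d[1]:1, , , drop = FALSE]
  }
}

flip_record <- function(rec, axis) {
  if (inherits(rec, "labeled_image")) {
    labeled_image(flip_array(rec$pixels, axis), rec$label,
                  paste0(rec$source_id, "_flip"), augmented = TRUE)
  } else if (inherits(rec, "seg_pair")) {
    seg_pair(flip_array(rec$image, axis), flip_array(rec$mask, axis),
             paste0(rec$source_id, "_flip"), augmented = TRUE)
  } else stop("unsupported record type")
}

#' Flip augmentation (one flipped copy per record)
#'
#' Appends exactly one flipped copy of every record, doubling the dataset
#' size; the flip axis (horizontal or vertical) is drawn per record from a
#' seeded generator. Labels travel with the images and masks are flipped
#' together with their images, so pairs stay aligned. Copies carry
#' `augmented = TRUE` and a `_flip` suffix on the source id.
#'
#' @param records non-empty list of [labeled_image()] or [seg_pair()] records.
#' @param seed integer seed for the axis draws.
#' @return List of length `2 * length(records)`: originals then copies.
#' @export
augment_flip <- function(records, seed) {
  if (!length(records)) stop("records must be non-empty")
  axes <- withr::with_seed(as.integer(seed), {
    ifelse(runif(length(records)) < 0.5, "horizontal", "vertical")
  })
  copies <- mapply(flip_record, records, axes, SIMPLIFY = FALSE)
  c(records, copies)
}

record_label <- function(rec) if (!is.null(rec$label)) rec$label else NA_integer_

#' Stratified hold-out split
#'
#' Shuffles records with a seeded generator and partitions them into a
#' train and a test part. When records carry labels the split is stratified:
#' each class is divided at the same fraction, with per-class train counts
#' rounded half-up (`floor(fraction * n + 0.5)`). A class with fewer than two
#' members cannot be stratified and is assigned entirely to the training
#' part, with a warning.
#'
#' @param records non-empty list of records.
#' @param fraction training fraction in (0, 1); 0.5 reproduces the half/half
#'   hold-out protocol.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return A `dataset_split` list with elements `train`, `test`, `seed`,
#'   `fraction`.
#' @export
holdout_split <- function(records, fraction, seed) {
  if (!length(records)) stop("records must be non-empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  labels <- vapply(records, record_label, integer(1))
  strata <- if (all(is.na(labels))) rep(0L, length(records)) else labels
  train_idx <- integer(0)
  test_idx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      if (length(idx) < 2L && length(unique(strata)) > 1L) {
        warning("class ", s, " has fewer than 2 records; assigned to train")
        train_idx <- c(train_idx, idx)
        next
      }
      idx <- idx[sample.int(length(idx))]
      n_train <- floor(fraction * length(idx) + 0.5)
      train_idx <- c(train_idx, idx[seq_len(n_train)])
      test_idx <- c(test_idx, idx[setdiff(seq_along(idx), seq_len(n_train))])
    }
  })
  structure(
    list(train = records[train_idx], test = records[test_idx],
         seed = as.integer(seed), fraction = fraction),
    class = "dataset_split"
  )
}

#' Load paired image/mask segmentation data
#'
#' Reads matching files from `images_dir` and `masks_dir` (matched on file
#' stem), resizes images bilinearly and masks by nearest neighbour to
#' `size x size`, rescales images to `[0, 1]`, and binarizes masks at 0.5
#' after rescaling so anti-aliased edge pixels below 0.5 become background.
#'
#' @param images_dir directory of input images.
#' @param masks_dir directory of binary mask images with matching stems.
#' @param size target square side length (128 by default in the pipeline).
#' @return List of [seg_pair()] records, ordered by stem.
#' @export
load_segmentation_pairs <- function(images_dir, masks_dir, size = 128) {
  list_stems <- function(d) {
    f <- list.files(d, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
    stats::setNames(f, tools::file_path_sans_ext(f))
  }
  imgs <- list_stems(images_dir)
  msks <- list_stems(masks_dir)
  orphans <- c(setdiff(names(imgs), names(msks)),
               setdiff(names(msks), names(imgs)))
  if (length(orphans))
    stop("unmatched image/mask stems: ", paste(sort(orphans), collapse = ", "))
  stems <- sort(names(imgs))
  lapply(stems, function(s) {
    img <- resize_array(read_rgb(file.path(images_dir, imgs[[s]])), size,
                        "bilinear")
    img <- pmin(pmax(img, 0), 1)
    m <- read_rgb(file.path(masks_dir, msks[[s]]))[, , 1]
    m <- resize_array(m, size, "none")
    seg_pair(img, ifelse(m >= 0.5, 1, 0), source_id = s)
  })
}

#' Write a dataset manifest
#'
#' Produces (and optionally writes as CSV) a manifest tibble describing a
#' dataset split: one row per record with its source id, label, assigned
#' split and augmentation flag.
#'
#' @param split a `dataset_split` from [holdout_split()].
#' @param path optional CSV output path.
#' @param class_names optional character vector mapping labels to names.
#' @return A tibble with columns `source_id`, `label`, `class_name`,
#'   `split`, `augmented` (invisibly when `path` is given).
#' @export
write_manifest <- function(split, path = NULL, class_names = NULL) {
  stopifnot(inherits(split, "dataset_split"))
  row_of <- function(rec, part) {
    lab <- record_label(rec)
    tibble::tibble(
      source_id = rec$source_id, label = lab,
      class_name = if (!is.null(class_names) && !is.na(lab))
        class_names[lab + 1L] else NA_character_,
      split = part, augmented = rec$augmented
    )
  }
  man <- do.call(rbind, c(lapply(split$train, row_of, part = "train"),
                          lapply(split$test, row_of, part = "test")))
  if (!is.null(path)) {
    utils::write.csv(man, path, row.names = FALSE)
    return(invisible(man))
  }
  man
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train:", length(x$train), " test:", length(x$test),
      " fraction:", x$fraction, " seed:", x$seed, "\n")
  invisible(x)
}
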