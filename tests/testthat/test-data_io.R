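test_that("per-class-folder loading conserves counts and honors class order", {
  root <- withr::local_tempdir()
  spec <- fixture_spec("classification", num_classes = 2, n_per_class = 3,
                       image_size = 16, seed = 4)
  make_classification_fixture(spec, root, class_names = c("a", "b"))

  recs <- load_image_dataset(root, 16, c("a", "b"))
  expect_length(recs, 6)
  expect_true(all(vapply(recs, function(r) all(dim(r$pixels) == c(16, 16, 3)),
                         logical(1))))

  swapped <- load_image_dataset(root, 16, c("b", "a"))
  by_id <- function(rs) rs[order(vapply(rs, `[[`, character(1), "source_id"))]
  recs <- by_id(recs); swapped <- by_id(swapped)
  expect_identical(vapply(recs, `[[`, integer(1), "label"),
                   1L - vapply(swapped, `[[`, integer(1), "label"))
  expect_equal(recs[[1]]$pixels, swapped[[1]]$pixels)

  expect_error(load_image_dataset(root, 16, c("a", "missing")), "missing")
})

test_that("non-square inputs are resized to the exact target shape", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "only"))
  img <- array(runif(100 * 80 * 3), c(100, 80, 3))
  png::writePNG(img, file.path(root, "only", "odd.png"))
  recs <- load_image_dataset(root, 64, "only")
  expect_identical(dim(recs[[1]]$pixels), c(64L, 64L, 3L))
  # independent resize call agrees on shape
  ref <- EBImage::resize(img, w = 64, h = 64)
  expect_identical(dim(recs[[1]]$pixels), dim(EBImage::imageData(ref)))
})

test_that("intensity normalization is the exact linear map I/255", {
  expect_identical(normalize_intensity(255), 1)
  expect_identical(normalize_intensity(0), 0)
  expect_equal(normalize_intensity(128), 128 / 255)
  a <- array(seq(0, 255, length.out = 24), c(2, 4, 3))
  out <- normalize_intensity(a)
  expect_equal(out, a / 255)
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_error(normalize_intensity(array(256, c(1, 1, 1))), "255")
  expect_error(normalize_intensity(-1), "255")
})

test_that("flip augmentation doubles the set and flips are involutions", {
  recs <- bright_dark_records(3, s = 8)
  aug <- augment_flip(recs, seed = 9)
  expect_length(aug, 2 * length(recs))
  expect_true(all(vapply(aug[seq_along(recs)], function(r) !r$augmented,
                         logical(1))))
  expect_true(all(vapply(aug[-seq_along(recs)], function(r) r$augmented,
                         logical(1))))
  # label rides along with the copy
  expect_identical(vapply(aug, `[[`, integer(1), "label"),
                   rep(vapply(recs, `[[`, integer(1), "label"), 2))
  # flipping the copy again on either axis recovers some original: detect the
  # axis by trying both
  for (i in seq_along(recs)) {
    copy <- aug[[length(recs) + i]]
    back_h <- copy$pixels[, dim(copy$pixels)[2]:1, , drop = FALSE]
    back_v <- copy$pixels[dim(copy$pixels)[1]:1, , , drop = FALSE]
    expect_true(identical(back_h, recs[[i]]$pixels) ||
                  identical(back_v, recs[[i]]$pixels))
  }
  expect_error(augment_flip(list(), 1), "non-empty")
})

test_that("a horizontally flipped pair moves left-half mask foreground to the right", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  mask <- matrix(0, 8, 8)
  mask[, 1:3] <- 1  # foreground strictly in the left half (columns 1-3)
  pair <- seg_pair(img, mask, "p1")
  # brute-force pixel permutation oracle for a horizontal (left-right) flip
  flipped <- gastroq:::flip_record(pair, "horizontal")
  for (i in 1:8) for (j in 1:8) {
    expect_identical(flipped$mask[i, j], mask[i, 8 - j + 1])
  }
  expect_true(all(flipped$mask[, 1:5] == 0))
  expect_true(all(flipped$mask[, 6:8] == 1))
  expect_equal(flipped$image[, 8:1, ], img)
})

test_that("hold-out split is a seeded stratified partition with half-up rounding", {
  recs <- tiny_records(100, labels = rep(0:1, each = 50))
  sp <- holdout_split(recs, 0.5, seed = 3)
  expect_length(sp$train, 50)
  expect_length(sp$test, 50)
  lab <- function(part) table(vapply(part, `[[`, integer(1), "label"))
  expect_true(all(lab(sp$train) == 25))
  expect_true(all(lab(sp$test) == 25))
  # partition: every record exactly once
  ids <- c(vapply(sp$train, `[[`, character(1), "source_id"),
           vapply(sp$test, `[[`, character(1), "source_id"))
  expect_setequal(ids, vapply(recs, `[[`, character(1), "source_id"))
  expect_length(unique(ids), 100)
  # determinism
  sp2 <- holdout_split(recs, 0.5, seed = 3)
  expect_identical(vapply(sp2$train, `[[`, character(1), "source_id"),
                   vapply(sp$train, `[[`, character(1), "source_id"))
  # 7 records at 0.5 -> 4 train / 3 test (half-up)
  sp7 <- holdout_split(tiny_records(7), 0.5, seed = 1)
  expect_length(sp7$train, 4)
  expect_length(sp7$test, 3)
  # singleton class goes to train with a warning
  recs1 <- tiny_records(11, labels = c(rep(0L, 10), 1L))
  expect_warning(sp1 <- holdout_split(recs1, 0.5, seed = 1), "fewer than 2")
  expect_true(1L %in% vapply(sp1$train, `[[`, integer(1), "label"))
  expect_error(holdout_split(recs, 1.5, seed = 1), "fraction")
})

test_that("segmentation pairs load matched, normalized and binarized", {
  root <- withr::local_tempdir()
  spec <- fixture_spec("segmentation", n = 3, image_size = 16, seed = 2)
  make_segmentation_fixture(spec, root)
  pairs <- load_segmentation_pairs(file.path(root, "images"),
                                   file.path(root, "masks"), 16)
  expect_length(pairs, 3)
  for (p in pairs) {
    expect_identical(dim(p$image), c(16L, 16L, 3L))
    expect_identical(dim(p$mask), c(16L, 16L))
    expect_true(all(p$mask %in% c(0, 1)))
    expect_true(min(p$image) >= 0 && max(p$image) <= 1)
  }
  # greyscale {0,255} mask plus an anti-aliased 0.4 edge pixel binarizes to
  # {0,1} with the 0.4 pixel forced to background
  m <- matrix(0, 16, 16); m[4:9, 4:9] <- 1; m[4, 3] <- 0.4
  png::writePNG(m, file.path(root, "masks", "pair001.png"))
  pairs <- load_segmentation_pairs(file.path(root, "images"),
                                   file.path(root, "masks"), 16)
  p1 <- pairs[[which(vapply(pairs, `[[`, character(1), "source_id") == "pair001")]]
  expect_true(all(p1$mask %in% c(0, 1)))
  expect_identical(p1$mask[4, 3], 0)
  expect_identical(p1$mask[5, 5], 1)
  # orphan mask -> error naming the stem
  png::writePNG(m, file.path(root, "masks", "orphan.png"))
  expect_error(load_segmentation_pairs(file.path(root, "images"),
                                       file.path(root, "masks"), 16),
               "orphan")
})

test_that("manifest records every split member once with its metadata", {
  recs <- tiny_records(10, labels = rep(0:1, 5))
  sp <- holdout_split(recs, 0.5, seed = 1)
  man <- write_manifest(sp, class_names = c("healthy", "ulcer"))
  expect_identical(nrow(man), 10L)
  expect_setequal(man$split, c("train", "test"))
  # 5 per class at fraction 0.5 -> 3 train each (half-up)
  expect_identical(sum(man$split == "train"), 6L)
  expect_setequal(man$class_name, c("healthy", "ulcer"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(sp, path)
  expect_identical(nrow(utils::read.csv(path)), 10L)
})
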