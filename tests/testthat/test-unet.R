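test_that("attention gate shape contract and coefficient range hold", {
  withr::with_seed(6, {
    x <- array(runif(32 * 32 * 4), c(32, 32, 4))
    g <- array(runif(16 * 16 * 6), c(16, 16, 6))
  })
  pr <- attention_params(cx = 4, cg = 6, init = "he", seed = 2)
  out <- attention_gate(x, g, pr)
  expect_identical(dim(out$gated), dim(x))
  expect_identical(dim(out$alpha), c(32L, 32L))
  expect_true(all(out$alpha > 0 & out$alpha < 1))
  expect_equal(out$gated, x * as.vector(out$alpha))
  # channel mismatch is rejected
  expect_error(attention_gate(x, array(0, c(16, 16, 3)), pr), "wg")
  # non-adjacent resolutions are rejected
  expect_error(attention_gate(x, array(0, c(4, 4, 6)), pr), "adjacent")
})

test_that("a zero-parameter gate is exactly a 0.5 scaling (sigma(0) = 1/2)", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  g <- array(runif(4 * 4 * 5), c(4, 4, 5))
  pr <- attention_params(cx = 3, cg = 5, init = "zero")
  out <- attention_gate(x, g, pr)
  expect_identical(unique(as.vector(out$alpha)), 0.5)
  expect_equal(out$gated, 0.5 * x, tolerance = 1e-15)
})

test_that("the network maps inputs to full-resolution probabilities through the pooling chain", {
  cfg <- unet_config(input_size = 32, depth = 4, base_filters = 4)
  m <- build_attention_unet(cfg, seed = 4)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- gastroq:::unet_forward(m$params, cfg, x, cache = TRUE)
  expect_identical(dim(fw$prob), c(32L, 32L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # each pooling halves spatial dims down to the bridge: 32 -> 16 -> 8 -> 4 -> 2
  sizes <- vapply(fw$cache$enc, function(e) dim(e$pool$y)[1], integer(1))
  expect_identical(sizes, c(16L, 8L, 4L, 2L))
  expect_identical(dim(fw$cache$bridge$a2)[1:2], c(2L, 2L))
  # attention off: plain U-Net with identical shapes
  cfg0 <- unet_config(input_size = 32, depth = 4, base_filters = 4,
                      attention_on_skips = FALSE)
  m0 <- build_attention_unet(cfg0, seed = 4)
  fw0 <- gastroq:::unet_forward(m0$params, cfg0, x)
  expect_identical(dim(fw0$prob), dim(fw$prob))
  expect_error(unet_config(input_size = 100, depth = 4), "divisible")
})

test_that("binary cross-entropy hits its closed forms", {
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  # flat 0.5 prediction costs ln 2 per pixel
  expect_equal(gastroq:::bce_mean(y, matrix(0.5, 8, 8)), log(2),
               tolerance = 1e-12)
  # a clipped perfect prediction costs ~0
  expect_lt(gastroq:::bce_mean(y, y), 1e-6)
})

test_that("one training step decreases loss on a tiny problem and records history", {
  cfg <- unet_config(input_size = 16, depth = 2, base_filters = 4)
  m <- build_attention_unet(cfg, seed = 1)
  spec <- fixture_spec("segmentation", n = 6, image_size = 16, seed = 3)
  pairs <- generate_segmentation_records(spec)
  tr <- train_segmenter(m, pairs[1:4], seg_train_config(epochs = 3,
                                                        batch_size = 2,
                                                        seed = 1),
                        validation = pairs[5:6])
  expect_identical(nrow(tr$history), 3L)
  expect_lt(tr$history$loss[3], tr$history$loss[1])
  expect_true(all(c("val_loss", "val_accuracy", "val_dice") %in%
                    names(tr$history)))
  expect_error(train_segmenter(m, list(), seg_train_config()), "empty")
})

test_that("mask prediction thresholds probabilities at 0.5 and is self-consistent", {
  cfg <- unet_config(input_size = 16, depth = 2, base_filters = 2)
  m <- build_attention_unet(cfg, seed = 9)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pred <- predict_mask(m, x)
  expect_identical(dim(pred$mask), c(16L, 16L))
  expect_true(all(pred$mask %in% c(0, 1)))
  expect_identical(pred$mask, ifelse(pred$prob >= 0.5, 1, 0))
  # threshold boundary semantics
  expect_true(all(ifelse(matrix(0.9, 2, 2) >= 0.5, 1, 0) == 1))
  expect_true(all(ifelse(matrix(0.5 - 1e-6, 2, 2) >= 0.5, 1, 0) == 0))
  # pipeline identity: a predicted mask scores Dice 1 against itself
  expect_identical(dice_score(pred$mask, pred$mask), 1)
  expect_error(predict_mask(m, array(0.5, c(15, 15, 3))), "divisible")
  expect_error(predict_mask(m, array(0.5, c(16, 16, 2))), "channel")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- unet_config(input_size = 16, depth = 2, base_filters = 2)
  spec <- fixture_spec("segmentation", n = 4, image_size = 16, seed = 5)
  pairs <- generate_segmentation_records(spec)
  run <- function() train_segmenter(build_attention_unet(cfg, seed = 2),
                                    pairs,
                                    seg_train_config(epochs = 2,
                                                     batch_size = 2,
                                                     seed = 7))
  m1 <- run(); m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})
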