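test_that("segmenter maps frames to per-class score maps of matching size", {
  cfg <- seg_config(base_channels = 2, seed = 5)
  m <- build_segmenter(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  lg <- surgskill:::seg_forward(m, x)$logits
  expect_equal(dim(lg), c(64, 64, 8))
  m2 <- build_segmenter(cfg)
  expect_identical(m$params, m2$params)
  # parameter count strictly increases with base width
  expect_lt(n_parameters(build_segmenter(seg_config(base_channels = 8))),
            n_parameters(build_segmenter(seg_config(base_channels = 16))))
  expect_error(surgskill:::seg_forward(m, array(0, c(48, 64, 3))),
               "pad")
})

test_that("predicted masks are deterministic argmax labelings", {
  m <- build_segmenter(seg_config(base_channels = 2, seed = 1))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_mask(m, x)
  expect_identical(p1, predict_mask(m, x))
  expect_equal(dim(p1), c(32, 32))
  expect_true(all(p1 %in% 0:7))
})

test_that("IoU matches hand-counted overlaps and is a symmetric bounded score", {
  a <- matrix(0L, 6, 6)
  expect_equal(iou(a, a)$mean, 1)           # identical masks
  b <- a
  a[1:2, 1:3] <- 1L                         # 2x3 rectangle
  b[2:3, 2:4] <- 1L                         # 2x3 rectangle, 2 pixels overlap
  expect_equal(sum(a == 1 & b == 1), 2)
  expect_equal(sum(a == 1 | b == 1), 10)
  expect_equal(iou(a, b)$per_class[["1"]], 2 / 10)
  # disjoint single-class regions
  d1 <- matrix(0L, 4, 4); d2 <- matrix(0L, 4, 4)
  d1[1, 1] <- 2L; d2[4, 4] <- 2L
  expect_equal(iou(d1, d2)$per_class[["2"]], 0)
  # absent classes are excluded, not counted as perfect
  expect_true(is.na(iou(d1, d2)$per_class[["5"]]))
  set.seed(6)
  for (i in 1:10) {
    m1 <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    m2 <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    r12 <- iou(m1, m2)
    expect_equal(r12$per_class, iou(m2, m1)$per_class)
    expect_true(all(r12$per_class >= 0 & r12$per_class <= 1, na.rm = TRUE))
    expect_equal(iou(m1, m1)$mean, 1)
  }
  expect_error(iou(matrix(0L, 4, 4), matrix(0L, 5, 5)), "mismatch")
})

test_that("augmentation applies one transform to both frame and mask", {
  s <- generate_scene(scene_spec(seed = 14))
  idp <- list(scale = c(1, 1), rotation = 0, shift = 0)
  out <- augment_pair(s$frame, s$mask, idp, seed = 2)
  expect_identical(out$mask, s$mask)
  expect_equal(out$frame, s$frame)
  rp <- list(scale = c(0.8, 1.2), rotation = 30, shift = 0.15)
  for (sd in 1:5) {
    aug <- augment_pair(s$frame, s$mask, rp, seed = sd)
    expect_true(all(aug$mask %in% c(0L, sort(unique(as.vector(s$mask))))))
    expect_true(all(dim(aug$frame) == dim(s$frame)))
  }
})

test_that("a 90-degree rotation moves a one-pixel class to the rotated spot", {
  H <- 33
  mask <- matrix(0L, H, H)
  frame <- array(0.5, c(H, H, 3))
  r <- 5L; c <- 9L                      # 0-based (row, col) = (4, 8)
  mask[r, c] <- 3L
  out <- augment_pair(frame, mask, list(scale = c(1, 1),
                                        rotation = c(90, 90), shift = 0),
                      seed = 1)
  # forward map with theta = +90 about the center (x=col, y=row, 0-based):
  # (x', y') = (cx - (y - cy), cy + (x - cx))
  ctr <- (H - 1) / 2
  x0 <- c - 1L; y0 <- r - 1L
  xr <- ctr - (y0 - ctr); yr <- ctr + (x0 - ctr)
  expect_equal(out$mask[yr + 1L, xr + 1L], 3L)
  expect_equal(sum(out$mask == 3L), 1)
})

test_that("training logs one curve row per optimizer step and checkpoints", {
  set.seed(31)
  scenes <- lapply(1:8, function(i)
    generate_scene(scene_spec(parts_present = c(1, 4), seed = 40 + i)))
  res <- train_segmenter(scenes[1:6], seg_config(base_channels = 2, seed = 2),
                         epochs = 2, batch_size = 3, lr = 3e-3,
                         eval_data = scenes[7:8], eval_every = 2, seed = 3)
  expect_equal(nrow(res$curve), 2 * 2)      # 6 examples / batch 3 * 2 epochs
  expect_named(res$curve, c("batch", "train_iou", "eval_iou"))
  expect_false(is.na(res$best_eval_iou))
  expect_error(train_segmenter(list(), seg_config()), "empty")
  neg <- list(generate_scene(scene_spec(parts_present = integer(0),
                                        seed = 1)))
  expect_warning(train_segmenter(neg, seg_config(base_channels = 2),
                                 epochs = 1, batch_size = 1),
                 "positive")
})

test_that("a single example can be memorized by a small network", {
  s <- generate_scene(scene_spec(parts_present = c(2, 5), seed = 77))
  res <- train_segmenter(list(s), seg_config(base_channels = 4, seed = 4),
                         epochs = 200, batch_size = 1, lr = 1e-2, seed = 5)
  expect_gt(tail(res$curve$train_iou, 1), 0.9)
})

test_that("checkpoints round-trip segmenter parameters and config", {
  p <- withr::local_tempfile(fileext = ".ckpt")
  m <- build_segmenter(seg_config(base_channels = 2, seed = 9))
  m$params$out_b <- m$params$out_b + 1   # distinguish from fresh build
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config$base_channels, 2L)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_mask(m, x), predict_mask(m2, x))
})
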