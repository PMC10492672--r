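test_that("scene generation is deterministic and covers requested classes", {
  sp <- scene_spec(parts_present = 1:7, seed = 12)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$frame, s2$frame)
  expect_identical(s1$mask, s2$mask)
  expect_equal(sort(unique(as.vector(s1$mask))), 0:7)
  expect_true(all(dim(s1$frame)[1:2] == dim(s1$mask)))
  expect_true(all(s1$frame >= 0 & s1$frame <= 1))
})

test_that("negative examples have all-background masks", {
  s <- generate_scene(scene_spec(parts_present = integer(0), seed = 3))
  expect_true(all(s$mask == 0L))
})

test_that("impossible shape placement names the offending class", {
  sp <- scene_spec(image_height = 32, image_width = 32, parts_present = 4,
                   shape_params = list(len_range = c(200, 220),
                                       width_range = c(2, 3)), seed = 1)
  expect_error(generate_scene(sp), "class 4")
})

test_that("mask PNG round trip preserves labels exactly", {
  p <- withr::local_tempfile(fileext = ".png")
  s <- generate_scene(scene_spec(seed = 8))
  write_mask_png(s$mask, p)
  expect_identical(read_mask_png(p), s$mask)
  pf <- withr::local_tempfile(fileext = ".png")
  write_frame_png(s$frame, pf)
  expect_equal(read_frame_png(pf), s$frame, tolerance = 1 / 254)
})

test_that("trajectory cases are deterministic with rule-consistent labels", {
  spec <- trajectory_spec(seed = 33)
  rule <- calibrate_score_rule(trajectory_spec(), n = 60, seed = 21)
  c1 <- generate_trajectory_case(spec, rule)
  c2 <- generate_trajectory_case(spec, rule)
  expect_identical(c1$sequence, c2$sequence)
  expect_identical(c1$record$gears, c2$record$gears)
  T_ <- nrow(c1$sequence)
  expect_gte(T_, spec$length_range[1])
  expect_lte(T_, spec$length_range[2])
  expect_true(all(is.finite(c1$sequence)))
  # labels equal the rule applied to the noise-free latent trajectory
  lab <- apply_score_rule(rule, c1$latent)
  expect_equal(c1$record$gears, lab$gears)
  expect_equal(c1$record$osats, lab$osats)
  expect_equal(c1$record$task, lab$task)
})

test_that("a static trajectory gets the rule's designated degenerate scores", {
  rule <- calibrate_score_rule(trajectory_spec(), n = 60, seed = 21)
  spec <- trajectory_spec(smoothness = 0, idle_fraction = 0, noise_sd = 0,
                          seed = 5)
  cs <- generate_trajectory_case(spec, rule)
  st <- trajectory_stats(cs$latent)
  expect_equal(st[["mean_speed"]], 0)
  expect_equal(st[["jerk"]], 0)
  expect_equal(st[["idle_frac"]], 1)
  expect_equal(st[["asymmetry"]], 0)
  # zero speed falls in the lowest bin: forward-mapped subcats score 1,
  # reversed ones 5; idle sits in the top bin
  expect_equal(cs$record$gears[["autonomy"]], 1L)
  expect_equal(cs$record$gears[["robotic_control"]], 5L)
  expect_equal(cs$record$gears[["depth_perception"]], 5L)
  expect_equal(cs$record$gears[["efficiency"]], 1L)
})

test_that("sampled cases reach at least three levels per subcategory", {
  rule <- calibrate_score_rule(trajectory_spec(), n = 400, seed = 20)
  seeds <- with_seed(77, sample.int(1e6, 500))
  labs <- sapply(seeds, function(s) {
    sp <- trajectory_spec(seed = s)
    lat <- surgskill:::simulate_latent_trajectory(sp)
    lab <- apply_score_rule(rule, lat$latent)
    c(lab$gears, lab$osats)
  })
  lvls <- apply(labs, 1, function(r) length(unique(r)))
  expect_true(all(lvls >= 3))
  expect_true(all(labs >= 1 & labs <= 5))
})

test_that("dataset generation writes a deterministic manifest per surgery", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rule <- calibrate_score_rule(trajectory_spec(), n = 60, seed = 21)
  mf <- generate_dataset(5, d1, rule = rule, frames_per_surgery = 2,
                         seed = 9)
  expect_length(mf$surgeries, 5)
  generate_dataset(5, d2, rule = rule, frames_per_surgery = 2, seed = 9)
  expect_identical(readBin(file.path(d1, "manifest.json"), "raw", 1e5),
                   readBin(file.path(d2, "manifest.json"), "raw", 1e5))
  ds <- load_dataset(d1)
  expect_length(ds, 5)
  expect_equal(ncol(ds[[1]]$sequence), 21)
  expect_s3_class(ds[[1]]$record, "rating_record")
  expect_length(ds[[1]]$frame_paths, 2)
  # frames and masks agree: features from stored mask equal features from
  # the regenerated scene
  m <- read_mask_png(ds[[1]]$mask_paths[1])
  expect_true(all(m %in% 0:7))
})
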