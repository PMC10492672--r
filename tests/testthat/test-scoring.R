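make_case <- function(T_ = 30, seed = 1) {
  with_seed(seed, {
    list(sequence = matrix(runif(T_ * 21), T_, 21),
         record = make_record(g = random_scores(6), o = random_scores(7),
                              task = sample(task_labels(), 1)))
  })
}

test_that("scorer outputs are normalized distributions of fixed shape", {
  for (v in c("WG", "SA", "DP")) {
    cfg <- score_config(v, trunk_channels = c(8, 8, 8), n_weights = 2,
                        attn_dim = 4, head_hidden = 6, seed = 2)
    m <- build_scorer(cfg)
    m2 <- build_scorer(cfg)
    expect_identical(m$params, m2$params)
    o50 <- score_sequence(m, matrix(runif(50 * 21), 50, 21))
    o500 <- score_sequence(m, matrix(runif(500 * 21), 500, 21))
    expect_identical(lengths(o50), lengths(o500))
    expect_equal(lengths(o50)[["task"]], 3L)
    expect_equal(unname(lengths(o50)[gears_subcategories()]), rep(5L, 6))
    for (hn in names(o50)) {
      expect_equal(sum(o50[[hn]]), 1, tolerance = 1e-5)
      expect_true(all(o50[[hn]] >= 0))
    }
    # determinism of the forward pass
    x <- matrix(runif(40 * 21), 40, 21)
    expect_identical(score_sequence(m, x), score_sequence(m, x))
  }
})

test_that("all three variants share the same trunk structure", {
  cfgs <- lapply(c("WG", "SA", "DP"), function(v)
    build_scorer(score_config(v, trunk_channels = c(8, 8), seed = 3)))
  trunk_names <- lapply(cfgs, function(m)
    grep("^trunk", names(m$params), value = TRUE))
  expect_identical(trunk_names[[1]], trunk_names[[2]])
  expect_identical(trunk_names[[2]], trunk_names[[3]])
  # heads exist for all 14 tasks in every variant
  for (m in cfgs) {
    expect_length(grep("^head_", names(m$params)), 14 * 4)
  }
})

test_that("temporal attention weights are normalized over time", {
  for (v in c("WG", "SA")) {
    m <- build_scorer(score_config(v, trunk_channels = c(8, 8),
                                   n_weights = 3, seed = 4))
    x <- matrix(runif(37 * 21), 37, 21)
    aw <- attention_weights(m, x)
    expect_equal(dim(aw), c(37, 3))
    expect_equal(colSums(aw), rep(1, 3), tolerance = 1e-6)
    expect_true(all(aw >= 0))
  }
  m <- build_scorer(score_config("DP", n_weights = 3, attn_dim = 5,
                                 trunk_channels = c(8, 8), seed = 4))
  dp <- attention_weights(m, matrix(runif(37 * 21), 37, 21))
  expect_equal(dim(dp$attention), c(3, 37))
  expect_equal(rowSums(dp$attention), rep(1, 3), tolerance = 1e-6)
  expect_equal(dim(dp$pooled), c(3, 5))
})

test_that("constant sequences receive uniform weight-gated attention", {
  m <- build_scorer(score_config("WG", trunk_channels = c(8, 8), seed = 6))
  xc <- matrix(rep(runif(21), each = 41), 41, 21)
  aw <- attention_weights(m, xc)
  expect_equal(aw, matrix(1 / 41, 41, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("short sequences are padded and masked out of attention", {
  m <- build_scorer(score_config("SA", trunk_channels = c(8, 8),
                                 min_length = 16, seed = 7))
  x <- matrix(runif(6 * 21), 6, 21)
  o <- score_sequence(m, x)
  expect_equal(sum(o$task), 1, tolerance = 1e-6)
  aw <- attention_weights(m, x)
  expect_equal(nrow(aw), 16)
  expect_equal(aw[1:10, ], matrix(0, 10, 4), ignore_attr = TRUE)
})

test_that("feature columns are positional, not exchangeable", {
  m <- build_scorer(score_config("SA", trunk_channels = c(8, 8), seed = 8))
  x <- matrix(runif(30 * 21), 30, 21)
  o1 <- unlist(score_sequence(m, x))
  o2 <- unlist(score_sequence(m, x[, c(2:21, 1)]))
  expect_gt(max(abs(o1 - o2)), 1e-6)
})

test_that("label prediction takes the argmax with low-score tie-breaks", {
  oneh <- function(i, n = 5) { v <- numeric(n); v[i] <- 1; v }
  out <- c(lapply(c(2, 5, 1, 3, 4, 2), oneh),
           lapply(c(1, 2, 3, 4, 5, 1, 2), oneh),
           list(oneh(3, 3)))
  head_names <- c(gears_subcategories(), osats_subcategories(), "task")
  names(out) <- head_names
  lab <- predict_labels(structure(out, class = "model_outputs"))
  expect_equal(unname(lab$gears), c(2, 5, 1, 3, 4, 2))
  expect_equal(unname(lab$osats), c(1, 2, 3, 4, 5, 1, 2))
  expect_equal(lab$task, "bolster")
  # uniform distribution ties break to the lowest score
  unif <- structure(c(lapply(1:13, function(i) rep(0.2, 5)),
                      list(rep(1 / 3, 3))),
                    class = "model_outputs")
  names(unif) <- names(out)
  expect_equal(unname(predict_labels(unif)$gears), rep(1, 6))
  expect_equal(predict_labels(unif)$task, "cut")
})

test_that("multitask loss is near zero for confident correct predictions", {
  rec <- make_record(g = c(1, 2, 3, 4, 5, 1), o = c(5, 4, 3, 2, 1, 5, 4),
                     task = "recon")
  oneh <- function(i, n = 5) {
    v <- rep(1e-9, n); v[i] <- 1 - 1e-9 * (n - 1); v
  }
  out <- structure(c(lapply(rec$gears, oneh), lapply(rec$osats, oneh),
                     list(oneh(2, 3))),
                   class = "model_outputs")
  names(out) <- c(gears_subcategories(), osats_subcategories(), "task")
  expect_lt(multitask_loss(list(out), list(rec), "CE"), 1e-6)
  # WK with a perfect batch: each subcategory head contributes log(eps)
  recs <- lapply(1:6, function(i)
    make_record(g = random_scores(6), o = random_scores(7), task = "cut"))
  outs <- lapply(recs, function(r)
    structure(stats::setNames(c(lapply(r$gears, oneh), lapply(r$osats, oneh),
                                list(oneh(1, 3))),
                              c(gears_subcategories(), osats_subcategories(),
                                "task")),
              class = "model_outputs"))
  wk <- multitask_loss(outs, recs, "WK", epsilon = 1e-6)
  expect_equal(wk, 13 * log(1e-6 / (1 + 1e-6)) + 0, tolerance = 1e-3)
  bad <- make_record(valid = FALSE)
  expect_error(multitask_loss(list(out), list(bad), "CE"), "invalid")
})

test_that("training reduces the loss on a small overfit set", {
  set.seed(9)
  cases <- lapply(1:10, function(i) make_case(T_ = 24, seed = i))
  for (lo in c("CE", "WK")) {
    fit <- train_scorer(cases, score_config("SA", trunk_channels = c(8, 8),
                                            n_weights = 2, attn_dim = 4,
                                            head_hidden = 6, seed = 10),
                        loss = lo, epochs = 8, batch_size = 5, lr = 3e-3,
                        weight_decay = 0, crop_range = NULL, seed = 11)
    expect_lt(mean(tail(fit$history, 2)), fit$history[1])
  }
})

test_that("invalid records are dropped before training", {
  cases <- lapply(1:6, function(i) make_case(seed = i))
  cases[[3]]$record$valid <- FALSE
  fit <- train_scorer(cases, score_config("SA", trunk_channels = c(8, 8),
                                          n_weights = 2, attn_dim = 4,
                                          head_hidden = 6, seed = 1),
                      epochs = 1, batch_size = 4, seed = 1)
  expect_equal(fit$dropped_invalid, 1)
})
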