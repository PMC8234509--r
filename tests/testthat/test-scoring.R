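test_that("visible fraction maps to the 5-point scale with fixed boundaries", {
  expect_equal(fraction_to_score(0.10), 1L)
  expect_equal(fraction_to_score(0.95), 5L)
  # lower-inclusive bin edges; score 5 strictly above 90%
  expect_equal(
    fraction_to_score(c(0.25, 0.50, 0.75, 0.90, 0.900001)),
    c(2L, 3L, 4L, 4L, 5L)
  )
  expect_equal(fraction_to_score(c(0, 1)), c(1L, 5L))
  # monotone non-decreasing over a fine grid
  grid <- seq(0, 1, by = 0.001)
  expect_true(all(diff(fraction_to_score(grid)) >= 0))
  expect_error(fraction_to_score(1.01), class = "cescore_validation_error")
  expect_error(fraction_to_score(-0.01), class = "cescore_validation_error")
})

test_that("argmax score assignment breaks ties toward the lower score", {
  expect_equal(assign_score(c(0.1, 0.6, 0.1, 0.1, 0.1)), 2L)
  expect_equal(assign_score(rep(0.2, 5)), 1L)
  expect_equal(assign_score(c(0, 0, 0.49, 0.51, 0)), 4L)
  # one-hot identity
  for (k in 1:5) {
    expect_equal(assign_score(as.numeric(1:5 == k)), k)
  }
  # matrix form, one column per frame
  m <- cbind(c(0, 0, 0, 0, 1), rep(0.2, 5))
  expect_equal(assign_score(m), c(5L, 1L))
  expect_error(assign_score(c(0.5, 0.5)), class = "cescore_validation_error")
  expect_error(assign_score(c(0.5, 0.2, 0.1, 0.1, 0.2)),
               class = "cescore_validation_error")
})

test_that("adjacent-score smoothing builds the documented soft targets", {
  one_hot <- cescore:::smooth_targets(c(1L, 3L, 5L), 0)
  expect_equal(one_hot, cbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 0),
                              c(0, 0, 0, 0, 1)))
  y <- cescore:::smooth_targets(c(5L, 3L, 1L), 0.1)
  expect_equal(y[, 1], c(0, 0, 0, 0.1, 0.9))      # edge keeps unused mass
  expect_equal(y[, 2], c(0, 0.1, 0.8, 0.1, 0))    # interior symmetric
  expect_equal(y[, 3], c(0.9, 0.1, 0, 0, 0))
  expect_equal(colSums(y), rep(1, 3))
})

test_that("rule-based estimator is calibrated at the extremes", {
  clean <- render_frame(frame_spec(visible_fraction = 1, seed = 2L))
  expect_gte(estimate_visible_fraction(stack_channels(clean$frame)), 0.97)
  dirty <- render_frame(frame_spec(visible_fraction = 0, seed = 2L))
  expect_lte(estimate_visible_fraction(stack_channels(dirty$frame)), 0.05)
})

test_that("rule-based estimator tracks ground truth on mixed frames", {
  set.seed(77)
  fr <- runif(40)
  err <- vapply(seq_along(fr), function(i) {
    o <- render_frame(frame_spec(visible_fraction = fr[i], seed = 7000L + i))
    estimate_visible_fraction(stack_channels(o$frame)) -
      o$ground_truth$true_visible_fraction
  }, 0)
  expect_lte(mean(abs(err)), 0.10)
})

test_that("rule-based frame scoring emits a one-hot score table", {
  out <- generate_case(case_spec(
    n_frames = 5, trajectory = list(type = "constant", value = 0.95), seed = 3L
  ))
  tab <- score_frames_rule_based(out$frames)
  expect_equal(names(tab),
               c("frame_index", paste0("p", 1:5), "score", "estimated_fraction"))
  expect_equal(tab$score, rep(5L, 5))
  expect_equal(rowSums(tab[, paste0("p", 1:5)]), rep(1, 5))
  expect_equal(tab$frame_index, 0:4)
})

test_that("classifier training validates its inputs", {
  x <- array(runif(16 * 16 * 3 * 4), dim = c(16, 16, 3, 4))
  expect_error(train_classifier(x, c(2, 2, 2, 2)),
               class = "cescore_validation_error")   # one class
  expect_error(train_classifier(x, c(1, 2, 3, 6)),
               class = "cescore_validation_error")   # label out of scale
  expect_error(train_classifier(x, c(1, 2)),
               class = "cescore_validation_error")   # length mismatch
  expect_error(train_config(initial_lr = 0),
               class = "cescore_validation_error")
  expect_error(train_config(adjacent_smoothing = 0.5),
               class = "cescore_validation_error")
})

test_that("training is reproducible and prediction is deterministic", {
  set.seed(9)
  x <- array(runif(16 * 16 * 3 * 30), dim = c(16, 16, 3, 30))
  y <- rep(c(1L, 4L, 5L), each = 10)
  cfg <- train_config(epochs_initial = 3L, epochs_fine_tune = 1L,
                      batch_size = 10L, seed = 11L)
  m1 <- train_classifier(x, y, cfg)
  m2 <- train_classifier(x, y, cfg)
  expect_identical(m1$params, m2$params)
  p1 <- predict_scores(m1, x)
  expect_identical(p1, predict_scores(m1, x))
  expect_equal(colSums(p1), rep(1, 30), tolerance = 1e-6)
  # single stack accepted; shape mismatch rejected
  one <- predict_scores(m1, x[, , , 1])
  expect_equal(dim(one), c(5L, 1L))
  bad <- array(0.5, dim = c(24, 24, 3, 2))
  expect_error(predict_scores(m1, bad), class = "cescore_validation_error")
})

test_that("a tiny training run learns to separate clean from dirty frames", {
  set.seed(12)
  dat <- list(
    clean = lapply(1:12, function(i) {
      render_frame(frame_spec(visible_fraction = runif(1, 0.92, 1),
                              seed = 500L + i))$frame
    }),
    dirty = lapply(1:12, function(i) {
      render_frame(frame_spec(visible_fraction = runif(1, 0, 0.2),
                              seed = 600L + i))$frame
    })
  )
  x <- stack_frames(c(dat$clean, dat$dirty))
  y <- rep(c(5L, 1L), each = 12)
  m <- train_classifier(x, y, train_config(
    epochs_initial = 8L, epochs_fine_tune = 1L, batch_size = 8L, seed = 4L
  ))
  pred <- assign_score(predict_scores(m, x))
  expect_gte(mean((pred >= 4) == (y == 5L)), 0.9)
})

test_that("models round-trip through disk with a JSON sidecar", {
  set.seed(13)
  x <- array(runif(16 * 16 * 3 * 10), dim = c(16, 16, 3, 10))
  y <- rep(c(1L, 5L), each = 5)
  m <- train_classifier(x, y, train_config(
    epochs_initial = 1L, epochs_fine_tune = 1L, batch_size = 5L
  ))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(predict_scores(back, x), predict_scores(m, x))
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$architecture$conv_channels, c(16, 32, 64))
})
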