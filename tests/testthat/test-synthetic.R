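test_that("frame rendering is deterministic under a fixed spec and seed", {
  spec <- frame_spec(visible_fraction = 0.55, seed = 42L)
  a <- render_frame(spec)
  b <- render_frame(spec)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed produces a different frame
  d <- render_frame(frame_spec(visible_fraction = 0.55, seed = 43L))
  expect_false(identical(a$frame$pixels, d$frame$pixels))
})

test_that("fully visible and fully occluded frames are exact", {
  clean <- render_frame(frame_spec(visible_fraction = 1, seed = 7L))
  expect_true(all(clean$occlusion_types == 0L))
  expect_equal(clean$ground_truth$true_visible_fraction, 1)
  expect_equal(clean$ground_truth$true_score, 5L)

  dirty <- render_frame(frame_spec(visible_fraction = 0, seed = 7L))
  expect_true(all(dirty$occlusion_types > 0L))
  expect_equal(dirty$ground_truth$true_visible_fraction, 0)
  expect_equal(dirty$ground_truth$true_score, 1L)
})

test_that("achieved fraction tracks the requested fraction", {
  out <- render_frame(frame_spec(visible_fraction = 0.60, seed = 11L))
  ach <- out$ground_truth$true_visible_fraction
  expect_gte(ach, 0.58)
  expect_lte(ach, 0.62)
  expect_equal(out$ground_truth$true_score, 3L)
  # the recorded truth is the union-mask fraction, not the request
  expect_equal(ach, mean(out$occlusion_types == 0L))

  for (i in 1:10) {
    vf <- (i - 0.5) / 10
    o <- render_frame(frame_spec(visible_fraction = vf, seed = 100L + i))
    expect_lte(abs(o$ground_truth$true_visible_fraction - vf), 0.02)
  }
})

test_that("invalid frame specs are rejected", {
  expect_error(frame_spec(visible_fraction = 1.2), class = "cescore_validation_error")
  expect_error(frame_spec(visible_fraction = -0.1), class = "cescore_validation_error")
  expect_error(frame_spec(visible_fraction = 0.5, occluder_mix = c(0.5, 0.5, 0.5)),
               class = "cescore_validation_error")
  expect_error(frame_spec(visible_fraction = 0.5, occluder_mix = c(-0.2, 0.6, 0.6)),
               class = "cescore_validation_error")
  expect_error(frame_spec(image_size = 8, visible_fraction = 0.5),
               class = "cescore_validation_error")
})

test_that("occluder classes separate from mucosa on the intended channels", {
  out <- render_frame(frame_spec(
    visible_fraction = 0.5, seed = 9L,
    occluder_mix = c(bubble = 0.4, bile = 0.4, debris = 0.2)
  ))
  st <- stack_channels(out$frame)
  tm <- out$occlusion_types
  mucosa_sat <- median(st[, , "hsv_s"][tm == 0L])
  mucosa_b <- median(st[, , "lab_b"][tm == 0L])
  expect_true(all(st[, , "hsv_s"][tm == 1L] < mucosa_sat))  # bubbles desaturated
  expect_true(all(st[, , "lab_b"][tm == 2L] > mucosa_b))    # bile yellow
})

test_that("case trajectories shape the emitted ground truth", {
  const <- generate_case(case_spec(
    n_frames = 30, trajectory = list(type = "constant", value = 0.95), seed = 5L
  ))
  expect_true(all(const$ground_truth$true_score == 5L))
  expect_equal(final_score(const$ground_truth$true_score), 5.0)

  lin <- generate_case(case_spec(
    n_frames = 100, trajectory = list(type = "linear", from = 1, to = 0),
    image_size = 32L, seed = 6L
  ))
  expect_equal(lin$requested_fractions, seq(1, 0, length.out = 100))
  expect_true(all(diff(lin$ground_truth$true_score) <= 0))

  pw <- generate_case(case_spec(
    n_frames = 10, trajectory = list(type = "piecewise", values = c(0.9, 0.3)),
    image_size = 32L, seed = 6L
  ))
  expect_equal(pw$requested_fractions, rep(c(0.9, 0.3), c(5, 5)))

  rw <- generate_case(case_spec(
    n_frames = 12, trajectory = list(type = "random-walk", start = 0.7, sd = 0.1),
    image_size = 32L, seed = 8L
  ))
  expect_true(all(rw$ground_truth$true_visible_fraction >= 0 &
                    rw$ground_truth$true_visible_fraction <= 1))
})

test_that("case generation round-trips deterministically through files", {
  spec <- case_spec(
    n_frames = 6, trajectory = list(type = "random-walk", start = 0.8, sd = 0.08),
    image_size = 32L, seed = 21L
  )
  d1 <- file.path(tempdir(), "case-run1")
  d2 <- file.path(tempdir(), "case-run2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_case(spec, out_dir = d1)
  generate_case(spec, out_dir = d2)
  expect_identical(readLines(file.path(d1, "ground_truth.csv")),
                   readLines(file.path(d2, "ground_truth.csv")))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  f1 <- list.files(file.path(d1, "frames"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "frames"), full.names = TRUE)
  expect_identical(lapply(f1, readBin, what = "raw", n = 1e6),
                   lapply(f2, readBin, what = "raw", n = 1e6))
  # written frames reload to the rendered ground truth's frame count
  m <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(m), 6L)
  expect_error(case_spec(n_frames = 2), class = "cescore_validation_error")
})
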