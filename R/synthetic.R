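# Synthetic capsule-endoscopy frames with known ground-truth mucosal
# visibility. Frames are square RGB images of a textured reddish-pink
# mucosa partially covered by three occluder classes: bright
# low-saturation air bubbles, yellow-green translucent bile, and dark
# brown debris. Occlusion is tracked on a per-pixel type map, and the
# ground-truth visible fraction is computed from the final union mask —
# the achieved occlusion, not the request, is the label of record.

#' Specification of one synthetic frame
#'
#' @param image_size Pixels per side of the square frame (default 64;
#'   minimum 16).
#' @param visible_fraction Target fraction of mucosa pixels left
#'   unoccluded, in `[0, 1]`.
#' @param occluder_mix Named or unnamed weights over the three occluder
#'   classes `(bubble, bile, debris)`; non-negative, summing to 1.
#' @param seed Integer RNG seed; identical spec + seed yields a
#'   bit-identical frame.
#'
#' @return A `synthetic_frame_spec` object.
#' @seealso [render_frame()]
#' @export
frame_spec <- function(image_size = 64L, visible_fraction,
                       occluder_mix = c(bubble = 1, bile = 1, debris = 1) / 3,
                       seed = 1L) {
  if (!is_scalar_number(image_size) || image_size < 16 ||
      image_size != round(image_size)) {
    stop_validation("image_size must be a whole number >= 16")
  }
  if (!is_scalar_number(visible_fraction) ||
      visible_fraction < 0 || visible_fraction > 1) {
    stop_validation("visible_fraction must be a number in [0, 1]")
  }
  if (!is.numeric(occluder_mix) || length(occluder_mix) != 3L ||
      any(occluder_mix < 0) || abs(sum(occluder_mix) - 1) > 1e-9) {
    stop_validation(
      "occluder_mix must be 3 non-negative weights (bubble, bile, debris) ",
      "summing to 1"
    )
  }
  if (!is_scalar_number(seed)) stop_validation("seed must be a single number")
  structure(
    list(
      image_size = as.integer(image_size),
      visible_fraction = as.numeric(visible_fraction),
      occluder_mix = stats::setNames(
        as.numeric(occluder_mix), c("bubble", "bile", "debris")
      ),
      seed = as.integer(seed)
    ),
    class = "synthetic_frame_spec"
  )
}

# Smooth low-frequency noise field: bilinear upsampling of a coarse
# Gaussian grid. Only relative channel statistics matter downstream.
smooth_noise <- function(n, coarse = 8L, sd = 1) {
  g <- matrix(stats::rnorm((coarse + 1L)^2, 0, sd), coarse + 1L, coarse + 1L)
  t <- seq(0, coarse, length.out = n)
  i0 <- pmin(floor(t), coarse - 1L)
  fr <- t - i0
  i0 <- i0 + 1L
  a <- g[i0, i0, drop = FALSE]
  b <- g[i0 + 1L, i0, drop = FALSE]
  cc <- g[i0, i0 + 1L, drop = FALSE]
  d <- g[i0 + 1L, i0 + 1L, drop = FALSE]
  w1 <- matrix(1 - fr, n, n)
  w2 <- matrix(fr, n, n)
  u1 <- matrix(1 - fr, n, n, byrow = TRUE)
  u2 <- matrix(fr, n, n, byrow = TRUE)
  a * w1 * u1 + b * w2 * u1 + cc * w1 * u2 + d * w2 * u2
}

# Linear pixel indices of a disc; coordinates are matrix row/col.
disc_indices <- function(n, cx, cy, r) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(n, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(n, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  inside <- outer(dx2, dy2, "+") <= r^2
  idx <- which(inside)
  (rep(ys, each = length(xs))[idx] - 1L) * n + rep(xs, length(ys))[idx]
}

# One occluder shape as linear pixel indices. Bubbles are single discs
# (with a rim ring reported separately), bile patches are short chains of
# overlapping discs, debris are irregular clusters of small discs.
occluder_shape <- function(type, n, r) {
  cx <- stats::runif(1, 1, n)
  cy <- stats::runif(1, 1, n)
  if (type == 1L) {                                   # bubble
    body <- disc_indices(n, cx, cy, r)
    core <- disc_indices(n, cx, cy, max(r - 1.5, 0))
    list(pix = body, rim = setdiff(body, core))
  } else if (type == 2L) {                            # bile
    ang <- stats::runif(1, 0, 2 * pi)
    k <- 2L + (stats::runif(1) < 0.5)
    pix <- integer(0)
    for (j in seq_len(k) - 1L) {
      pix <- c(pix, disc_indices(
        n,
        cx + j * 0.7 * r * cos(ang) + stats::rnorm(1, 0, r / 6),
        cy + j * 0.7 * r * sin(ang) + stats::rnorm(1, 0, r / 6),
        r * stats::runif(1, 0.7, 1)
      ))
    }
    list(pix = unique(pix), rim = integer(0))
  } else {                                            # debris
    k <- 3L + sample.int(3L, 1L)
    pix <- integer(0)
    for (j in seq_len(k)) {
      pix <- c(pix, disc_indices(
        n,
        cx + stats::rnorm(1, 0, r * 0.5),
        cy + stats::rnorm(1, 0, r * 0.5),
        r * stats::runif(1, 0.35, 0.6)
      ))
    }
    list(pix = unique(pix), rim = integer(0))
  }
}

#' Render one synthetic capsule-endoscopy frame
#'
#' Draws a textured mucosa background and places occluders greedily
#' (largest first, overlap allowed) until the occluded-pixel budget
#' implied by `visible_fraction` is met on the union mask; the last shape
#' is trimmed pixel-wise so the achieved fraction matches the request to
#' within one pixel. The returned ground truth records the achieved
#' fraction computed from the final occlusion type map.
#'
#' @param spec A [frame_spec()].
#' @param case_id Case identifier stored on the frame.
#' @param frame_index 0-based position of the frame within its case.
#'
#' @return A list with elements `frame` (a [ce_frame()]) and
#'   `ground_truth` (one-row data frame: `frame_index`,
#'   `true_visible_fraction`, `true_score`).
#' @examples
#' out <- render_frame(frame_spec(visible_fraction = 0.6, seed = 11))
#' out$ground_truth
#' @export
render_frame <- function(spec, case_id = "case", frame_index = 0L) {
  if (!inherits(spec, "synthetic_frame_spec")) {
    spec <- do.call(frame_spec, spec)
  }
  n <- spec$image_size
  npix <- n * n
  with_seed(spec$seed, {
    # --- mucosa background -------------------------------------------
    base <- c(0.78, 0.45, 0.43)
    shade <- smooth_noise(n, 8L, 0.055)
    rgb <- vector("list", 3L)
    for (ch in 1:3) {
      rgb[[ch]] <- base[ch] + shade + smooth_noise(n, 12L, 0.02)
    }
    ctr <- (n + 1) / 2
    d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") /
      (2 * (n / 2)^2)
    vig <- 1 - 0.08 * d2                       # mild corner fall-off
    for (ch in 1:3) rgb[[ch]] <- rgb[[ch]] * vig
    mucosa <- rgb

    # --- occluder placement on the union type map --------------------
    type_map <- matrix(0L, n, n)               # 0 mucosa, 1 bubble, 2 bile, 3 debris
    rim_map <- logical(npix)
    target <- round((1 - spec$visible_fraction) * npix)
    occupied <- 0L
    iter <- 0L
    rmax <- n / 4
    while (occupied < target) {
      iter <- iter + 1L
      remaining <- target - occupied
      if (remaining <= 30L || iter > 200L) {
        # dust pass: occlude exactly the remaining pixels one by one
        vis <- which(type_map == 0L)
        pick <- if (length(vis) > remaining) sample(vis, remaining) else vis
        type_map[pick] <- sample(
          1:3, length(pick), replace = TRUE, prob = spec$occluder_mix
        )
        occupied <- sum(type_map > 0L)
        next
      }
      type <- sample.int(3L, 1L, prob = spec$occluder_mix)
      r <- min(rmax, max(2, sqrt(remaining / pi))) * stats::runif(1, 0.75, 1)
      sh <- occluder_shape(type, n, r)
      new <- sh$pix[type_map[sh$pix] == 0L]
      if (length(new) > remaining) new <- sample(new, remaining)
      type_map[new] <- type
      rim_map[intersect(sh$rim, new)] <- TRUE
      occupied <- occupied + length(new)
    }

    # --- render occluders over the mucosa ----------------------------
    pixnoise <- function(k) stats::rnorm(k, 0, 0.015)
    idx <- which(type_map == 1L)
    if (length(idx)) {
      bub <- c(0.87, 0.83, 0.81)
      for (ch in 1:3) rgb[[ch]][idx] <- bub[ch] + pixnoise(length(idx))
      rim <- which(rim_map & type_map == 1L)
      for (ch in 1:3) rgb[[ch]][rim] <- rgb[[ch]][rim] + 0.07
    }
    idx <- which(type_map == 2L)
    if (length(idx)) {
      bile <- c(0.70, 0.66, 0.08)
      for (ch in 1:3) {
        rgb[[ch]][idx] <- 0.2 * mucosa[[ch]][idx] + 0.8 * bile[ch] +
          pixnoise(length(idx))
      }
    }
    idx <- which(type_map == 3L)
    if (length(idx)) {
      deb <- c(0.22, 0.14, 0.07)
      for (ch in 1:3) rgb[[ch]][idx] <- deb[ch] + pixnoise(length(idx))
    }
    px <- array(0, dim = c(n, n, 3L))
    for (ch in 1:3) px[, , ch] <- pmin(pmax(rgb[[ch]], 0), 1)

    achieved <- 1 - sum(type_map > 0L) / npix
    list(
      frame = ce_frame(px, case_id = case_id, frame_index = frame_index),
      ground_truth = data.frame(
        frame_index = as.integer(frame_index),
        true_visible_fraction = achieved,
        true_score = fraction_to_score(achieved)
      ),
      occlusion_types = type_map
    )
  })
}

#' Specification of a synthetic capsule-endoscopy case
#'
#' A case is a time-ordered frame sequence whose ground-truth visible
#' fraction follows a cleanliness trajectory along the small bowel.
#'
#' @param n_frames Number of frames (at least 3, so the proximal, middle,
#'   and distal thirds are all non-empty).
#' @param trajectory A list describing the cleanliness curve:
#'   * `list(type = "constant", value = f)`
#'   * `list(type = "linear", from = f0, to = f1)`
#'   * `list(type = "piecewise", values = c(...))` — equal-length pieces
#'   * `list(type = "random-walk", start = f0, sd = s)` — reflected
#'     into `[0, 1]`
#' @param image_size,occluder_mix Per-frame parameters, see [frame_spec()].
#' @param seed Integer seed; per-frame seeds are derived from it.
#' @param case_id Case identifier.
#'
#' @return A `synthetic_case_spec` object.
#' @export
case_spec <- function(n_frames, trajectory = list(type = "constant", value = 0.8),
                      image_size = 64L,
                      occluder_mix = c(bubble = 1, bile = 1, debris = 1) / 3,
                      seed = 1L, case_id = "case01") {
  if (!is_scalar_number(n_frames) || n_frames < 3 ||
      n_frames != round(n_frames)) {
    stop_validation("n_frames must be a whole number >= 3")
  }
  if (!is.list(trajectory) || is.null(trajectory$type) ||
      !trajectory$type %in% c("constant", "linear", "piecewise", "random-walk")) {
    stop_validation(
      "trajectory$type must be one of constant, linear, piecewise, random-walk"
    )
  }
  structure(
    list(
      n_frames = as.integer(n_frames), trajectory = trajectory,
      image_size = as.integer(image_size),
      occluder_mix = occluder_mix, seed = as.integer(seed),
      case_id = as.character(case_id)
    ),
    class = "synthetic_case_spec"
  )
}

trajectory_fractions <- function(trajectory, n, seed) {
  f <- switch(trajectory$type,
    constant = rep(trajectory$value, n),
    linear = seq(trajectory$from, trajectory$to, length.out = n),
    piecewise = {
      v <- trajectory$values
      rep(v, times = segment_sizes(n, length(v)))
    },
    `random-walk` = with_seed(seed, {
      sd <- if (is.null(trajectory$sd)) 0.05 else trajectory$sd
      x <- trajectory$start + c(0, cumsum(stats::rnorm(n - 1, 0, sd)))
      r <- x %% 2
      ifelse(r > 1, 2 - r, r)                 # reflect into [0, 1]
    })
  )
  if (any(f < 0 | f > 1)) {
    stop_validation("trajectory produced fractions outside [0, 1]")
  }
  f
}

#' Generate a synthetic case: frames plus ground truth
#'
#' Renders `n_frames` frames whose true visible fractions follow the
#' requested trajectory. Deterministic under a fixed seed. When
#' `out_dir` is given, writes 8-bit RGB PNG frames, a frame manifest
#' (`manifest.csv`: `case_id`, `frame_index`, `filename`) and the ground
#' truth (`ground_truth.csv`: `frame_index`, `true_visible_fraction`,
#' `true_score`).
#'
#' @param spec A [case_spec()].
#' @param out_dir Optional output directory.
#'
#' @return A list with `frames` (list of [ce_frame()]), `ground_truth`
#'   (data frame), and `requested_fractions`.
#' @export
generate_case <- function(spec, out_dir = NULL) {
  if (!inherits(spec, "synthetic_case_spec")) spec <- do.call(case_spec, spec)
  n <- spec$n_frames
  fractions <- trajectory_fractions(spec$trajectory, n, spec$seed)
  seeds <- derive_seeds(spec$seed, n)
  frames <- vector("list", n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    out <- render_frame(
      frame_spec(
        image_size = spec$image_size, visible_fraction = fractions[i],
        occluder_mix = spec$occluder_mix, seed = seeds[i]
      ),
      case_id = spec$case_id, frame_index = i - 1L
    )
    frames[[i]] <- out$frame
    gt[[i]] <- out$ground_truth
  }
  gt <- do.call(rbind, gt)
  if (!is.null(out_dir)) {
    write_case(frames, gt, out_dir)
  }
  list(frames = frames, ground_truth = gt, requested_fractions = fractions)
}

write_case <- function(frames, ground_truth, out_dir) {
  frame_dir <- file.path(out_dir, "frames")
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  filenames <- sprintf("frame_%05d.png", vapply(frames, `[[`, 0L, "frame_index"))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]]$pixels, file.path(frame_dir, filenames[i]))
  }
  manifest <- data.frame(
    case_id = vapply(frames, `[[`, "", "case_id"),
    frame_index = vapply(frames, `[[`, 0L, "frame_index"),
    filename = file.path("frames", filenames)
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
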