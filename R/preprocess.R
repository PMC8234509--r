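# Frame container and channel preprocessing. Scorers never see raw RGB:
# each frame is reduced to three channels in [0,1] — gray luminance,
# HSV saturation, and the CIELAB yellow-blue opponent b* — chosen so
# that bubbles (bright, desaturated), bile (strongly yellow) and debris
# (dark) separate from mucosa on at least one channel each.

#' Construct a capsule-endoscopy frame
#'
#' @param pixels H x W x 3 numeric array. Values in `[0, 1]` are taken
#'   as-is; 8-bit values in `[0, 255]` are rescaled.
#' @param case_id Case identifier.
#' @param frame_index 0-based time order within the case.
#'
#' @return A `ce_frame` object.
#' @export
ce_frame <- function(pixels, case_id = "case", frame_index = 0L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_validation("pixels must be an H x W x 3 array (RGB)")
  }
  d <- dim(pixels)
  if (d[1] != d[2] || d[1] < 16L) {
    stop_validation("frames must be square with side >= 16 pixels")
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0) {
    stop_validation("pixel values must be finite and non-negative")
  }
  if (max(pixels) > 1) {
    if (max(pixels) > 255) stop_validation("pixel values must be <= 255")
    pixels <- pixels / 255
  }
  structure(
    list(pixels = pixels, case_id = as.character(case_id),
         frame_index = as.integer(frame_index)),
    class = "ce_frame"
  )
}

#' Read a frame from a PNG or JPEG file
#'
#' @param path Path to an RGB image (PNG; JPEG is accepted when the
#'   jpeg package is installed).
#' @param case_id,frame_index Metadata stored on the frame.
#' @return A [ce_frame()].
#' @export
read_frame <- function(path, case_id = "case", frame_index = 0L) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop_validation("reading JPEG requires the jpeg package")
    }
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  ce_frame(px, case_id = case_id, frame_index = frame_index)
}

as_frame <- function(x) {
  if (inherits(x, "ce_frame")) x else ce_frame(x)
}

#' Gray luminance channel (input type 1)
#'
#' Rec. 601 weighting `0.299 R + 0.587 G + 0.114 B`, in `[0, 1]`.
#'
#' @param frame A [ce_frame()] or H x W x 3 array.
#' @return H x W matrix in `[0, 1]`.
#' @export
to_gray <- function(frame) {
  px <- as_frame(frame)$pixels
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' HSV saturation channel (input type 2)
#'
#' `S = (max - min) / max` per pixel, with 0 where `max = 0`.
#'
#' @inheritParams to_gray
#' @return H x W matrix in `[0, 1]`.
#' @export
to_hsv_s <- function(frame) {
  px <- as_frame(frame)$pixels
  d <- dim(px)
  m <- t(matrix(px, ncol = 3L))               # 3 x N, rows = R, G, B
  s <- grDevices::rgb2hsv(m, maxColorValue = 1)[2L, ]
  matrix(s, d[1], d[2])
}

#' CIELAB b* channel (input type 3)
#'
#' sRGB is converted to CIELAB under the D65 white point via the
#' standard linearisation, sRGB-to-XYZ matrix and cube-root encoding,
#' and the b* yellow-blue axis is rescaled affinely from its
#' representable range `[-128, 127]` to `[0, 1]` (so achromatic pixels
#' map to 128/255, about 0.502, yellows above and blues below).
#'
#' @inheritParams to_gray
#' @return H x W matrix in `[0, 1]`.
#' @export
to_lab_b <- function(frame) {
  px <- as_frame(frame)$pixels
  d <- dim(px)
  rgb <- matrix(px, ncol = 3L)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  # sRGB (D65) linear RGB -> XYZ, Y and Z rows only
  y <- lin %*% c(0.2126729, 0.7151522, 0.0721750)
  z <- lin %*% c(0.0193339, 0.1191920, 0.9503041)
  enc <- function(t) {
    ifelse(t > (6 / 29)^3, t^(1 / 3), t * (29 / 6)^2 / 3 + 4 / 29)
  }
  bstar <- 200 * (enc(y / 1.0) - enc(z / 1.08883))
  matrix(pmin(pmax((bstar + 128) / 255, 0), 1), d[1], d[2])
}

#' Stack the three scorer input channels
#'
#' Computes the gray, HSV-S and Lab-b channels and stacks them in that
#' fixed order. When `circular_mask = TRUE`, pixels outside the largest
#' centred disc are zeroed on all channels — real capsule frames carry a
#' dark circular border; synthetic frames do not need it.
#'
#' @inheritParams to_gray
#' @param circular_mask Zero out corners outside the inscribed disc.
#' @return A `channel_stack`: H x W x 3 array with channels
#'   `gray`, `hsv_s`, `lab_b`, all values in `[0, 1]`.
#' @examples
#' f <- ce_frame(array(0.5, dim = c(16, 16, 3)))
#' st <- stack_channels(f)
#' range(st[, , "hsv_s"])   # achromatic: saturation identically 0
#' @export
stack_channels <- function(frame, circular_mask = FALSE) {
  frame <- as_frame(frame)
  d <- dim(frame$pixels)
  st <- array(0, dim = c(d[1], d[2], 3L),
              dimnames = list(NULL, NULL, c("gray", "hsv_s", "lab_b")))
  st[, , 1L] <- to_gray(frame)
  st[, , 2L] <- to_hsv_s(frame)
  st[, , 3L] <- to_lab_b(frame)
  if (circular_mask) {
    ctr <- (d[1] + 1) / 2
    outside <- outer((seq_len(d[1]) - ctr)^2, (seq_len(d[2]) - ctr)^2, "+") >
      (d[1] / 2)^2
    for (ch in 1:3) {
      plane <- st[, , ch]
      plane[outside] <- 0
      st[, , ch] <- plane
    }
  }
  structure(st, class = c("channel_stack", class(st)))
}

#' Stack many frames into the 4-d array consumed by the classifier
#'
#' @param frames List of [ce_frame()] objects (same size).
#' @param circular_mask Passed to [stack_channels()].
#' @return An `H x W x 3 x N` array.
#' @export
stack_frames <- function(frames, circular_mask = FALSE) {
  stacks <- lapply(frames, stack_channels, circular_mask = circular_mask)
  d <- dim(stacks[[1L]])
  x <- array(0, dim = c(d[1], d[2], 3L, length(stacks)))
  for (i in seq_along(stacks)) x[, , , i] <- stacks[[i]]
  x
}
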