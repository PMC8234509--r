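# Cleansing-score semantics and the rule-based scorer.
#
# The 5-point scale is defined by the proportion of mucosa visible:
#   score 1: < 25%   visible      score 4: 75-90%
#   score 2: 25-50%               score 5: > 90%
#   score 3: 50-75%
# Boundaries are lower-inclusive (0.25 -> 2, 0.50 -> 3, 0.75 -> 4); score
# 5 requires strictly more than 90% visible, so 0.90 -> 4.

#' Map a visible-mucosa fraction to a cleansing score
#'
#' @param visible_fraction Numeric vector of fractions in `[0, 1]`.
#' @return Integer scores in 1..5 (vectorised).
#' @examples
#' fraction_to_score(c(0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
#' @export
fraction_to_score <- function(visible_fraction) {
  if (!is.numeric(visible_fraction) ||
      any(!is.finite(visible_fraction)) ||
      any(visible_fraction < 0 | visible_fraction > 1)) {
    stop_validation("visible_fraction must be numeric in [0, 1]")
  }
  score <- ifelse(visible_fraction < 0.25, 1L,
           ifelse(visible_fraction < 0.50, 2L,
           ifelse(visible_fraction < 0.75, 3L,
           ifelse(visible_fraction <= 0.90, 4L, 5L))))
  as.integer(score)
}

#' Default channel thresholds of the rule-based scorer
#'
#' A pixel is called an occluder when it matches any of the three channel
#' rules; the remainder is visible mucosa. Thresholds are on the
#' normalised `[0, 1]` channels of [stack_channels()].
#'
#' @param bubble_gray,bubble_sat Bubble: `gray > bubble_gray` and
#'   `hsv_s < bubble_sat` (bright and desaturated).
#' @param bile_lab_b Bile: `lab_b > bile_lab_b` (strongly yellow).
#' @param debris_gray Debris: `gray < debris_gray` (dark).
#' @return A named list of thresholds.
#' @export
rule_thresholds <- function(bubble_gray = 0.75, bubble_sat = 0.25,
                            bile_lab_b = 0.65, debris_gray = 0.20) {
  list(bubble_gray = bubble_gray, bubble_sat = bubble_sat,
       bile_lab_b = bile_lab_b, debris_gray = debris_gray)
}

#' Rule-based estimate of the visible-mucosa fraction
#'
#' Classifies every pixel with fixed channel rules — bubble if bright and
#' desaturated, bile if high Lab-b, debris if dark — and returns the
#' fraction of pixels left over as visible mucosa.
#'
#' @param stack A [stack_channels()] result (or a frame, which is
#'   stacked first).
#' @param thresholds See [rule_thresholds()].
#' @return A fraction in `[0, 1]`.
#' @export
estimate_visible_fraction <- function(stack, thresholds = rule_thresholds()) {
  if (!inherits(stack, "channel_stack")) stack <- stack_channels(stack)
  gray <- stack[, , 1L]; sat <- stack[, , 2L]; lab_b <- stack[, , 3L]
  occluded <- (gray > thresholds$bubble_gray & sat < thresholds$bubble_sat) |
    lab_b > thresholds$bile_lab_b |
    gray < thresholds$debris_gray
  1 - mean(occluded)
}

#' Assign the cleansing score from a score distribution
#'
#' The score with the highest predicted probability is assigned; ties are
#' broken toward the lower score (conservative: flags worse cleansing).
#'
#' @param dist Numeric vector of 5 probabilities (`P(G1)..P(G5)`) summing
#'   to 1, or a 5-row matrix with one column per frame.
#' @return Integer score(s) in 1..5.
#' @examples
#' assign_score(c(0.1, 0.6, 0.1, 0.1, 0.1))
#' @export
assign_score <- function(dist) {
  if (is.matrix(dist)) {
    if (nrow(dist) != 5L) stop_validation("distribution matrix must have 5 rows")
    return(vapply(seq_len(ncol(dist)), function(j) assign_score(dist[, j]), 1L))
  }
  if (!is.numeric(dist) || length(dist) != 5L ||
      any(dist < -1e-9) || abs(sum(dist) - 1) > 1e-6) {
    stop_validation("dist must be 5 probabilities summing to 1")
  }
  as.integer(which.max(dist))   # which.max returns the first (lowest) maximum
}

#' Score frames with the rule-based path
#'
#' Estimates the visible fraction of each frame and bins it to a score.
#' The emitted probability columns are one-hot (the rule-based path is
#' deterministic), so the output schema matches [predict_scores()].
#'
#' @param frames List of [ce_frame()] objects.
#' @param thresholds See [rule_thresholds()].
#' @param circular_mask Passed to [stack_channels()].
#' @return Data frame: `frame_index`, `p1..p5`, `score`,
#'   `estimated_fraction`.
#' @export
score_frames_rule_based <- function(frames, thresholds = rule_thresholds(),
                                    circular_mask = FALSE) {
  est <- vapply(frames, function(f) {
    estimate_visible_fraction(
      stack_channels(f, circular_mask = circular_mask), thresholds
    )
  }, 0)
  score <- fraction_to_score(est)
  probs <- matrix(0, length(frames), 5L)
  probs[cbind(seq_along(frames), score)] <- 1
  colnames(probs) <- paste0("p", 1:5)
  data.frame(
    frame_index = vapply(frames, `[[`, 0L, "frame_index"),
    probs,
    score = score,
    estimated_fraction = est
  )
}
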