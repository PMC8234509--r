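# Case-level aggregation and clinical grading.
#
# The case's final cleansing score is the arithmetic mean of its frame
# scores. For grading, the case is split into proximal/middle/distal
# thirds by time order; each third is graded 1-4 from the fraction of
# its frames showing >50% invisible mucosa, and the sum of the three
# segmental grades maps to overall grade A (3-5), B (6-8) or C (9-12),
# with A or B counted as clinically adequate preparation.

validate_scores <- function(scores) {
  if (length(scores) == 0L) stop_validation("score sequence is empty")
  if (any(is.na(scores)) || any(scores != round(scores)) ||
      any(scores < 1 | scores > 5)) {
    stop_validation("scores must be integers in 1..5")
  }
  as.integer(scores)
}

#' Final (average) cleansing score of a case
#'
#' Arithmetic mean of the per-frame cleansing scores, full precision
#' (round to 1 decimal for display).
#'
#' @param scores Integer frame scores in 1..5, in time order.
#' @return The mean score in `[1, 5]`.
#' @examples
#' final_score(c(3, 3, 3))
#' @export
final_score <- function(scores) {
  mean(validate_scores(scores))
}

# Sizes of k contiguous segments of n frames; the first n %% k segments
# take the extra frame (remainders go proximal).
segment_sizes <- function(n, k = 3L) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Split a case into proximal, middle, and distal thirds
#'
#' Contiguous thirds in time order; when the frame count is not
#' divisible by 3 the earlier (proximal) segments receive one extra
#' frame. The three segments partition the case exactly.
#'
#' @param scores Frame scores (or any per-frame vector) in time order;
#'   length at least 3.
#' @return A list of 3 sub-vectors `(seg1, seg2, seg3)`.
#' @examples
#' lengths(split_segments(1:10))   # 4 3 3
#' @export
split_segments <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop_validation("a case needs at least 3 frames to split")
  sizes <- segment_sizes(n)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-3L] + 1L)
  lapply(1:3, function(k) scores[starts[k]:ends[k]])
}

#' Fraction of frames with more than 50% invisible mucosa
#'
#' With integer scores, visible < 50% is exactly score 1 or 2 under the
#' score bins, so the fraction of frames scoring at most 2 is returned.
#' When raw estimated visible fractions are supplied instead
#' (`fractions`), the direct test `visible < 0.5` is used.
#'
#' @param segment Frame scores of one segment.
#' @param fractions Optional per-frame estimated visible fractions; when
#'   given they take precedence over the binned scores.
#' @return Fraction in `[0, 1]`.
#' @examples
#' invisible_fraction(c(1, 2, 3, 4, 5))   # 0.4
#' @export
invisible_fraction <- function(segment, fractions = NULL) {
  if (!is.null(fractions)) {
    if (length(fractions) == 0L) stop_validation("segment is empty")
    return(mean(fractions < 0.5))
  }
  mean(validate_scores(segment) <= 2L)
}

#' Segmental grade from the invisible-frame fraction
#'
#' Grade 1: less than 5% of the segment's frames show >50% invisible
#' mucosa; grade 2: 5-15%; grade 3: 15-25%; grade 4: more than 25%.
#' Bins are lower-inclusive, and grade 4 is strictly above 25%.
#'
#' @param fraction Fraction of frames with >50% invisible mucosa,
#'   vectorised.
#' @return Integer grade(s) 1..4.
#' @examples
#' segmental_grade(c(0.04, 0.10, 0.30))
#' @export
segmental_grade <- function(fraction) {
  if (!is.numeric(fraction) || any(!is.finite(fraction)) ||
      any(fraction < 0 | fraction > 1)) {
    stop_validation("fraction must be numeric in [0, 1]")
  }
  as.integer(
    ifelse(fraction < 0.05, 1L,
    ifelse(fraction < 0.15, 2L,
    ifelse(fraction <= 0.25, 3L, 4L)))
  )
}

#' Overall grade from the three segmental grades
#'
#' The segmental grades are summed; a total of 3-5 is grade A, 6-8 grade
#' B, and 9-12 grade C. Grades A and B are clinically adequate.
#'
#' @param segmental_grades Integer vector of 3 grades in 1..4.
#' @return A `grading_result`: list with `segmental_grades`,
#'   `grade_sum`, `overall_grade` (`"A"`, `"B"` or `"C"`), `adequate`.
#' @examples
#' overall_grade(c(2, 3, 3))
#' @export
overall_grade <- function(segmental_grades) {
  if (length(segmental_grades) != 3L || any(is.na(segmental_grades)) ||
      any(segmental_grades != round(segmental_grades)) ||
      any(segmental_grades < 1 | segmental_grades > 4)) {
    stop_validation("segmental_grades must be 3 integers in 1..4")
  }
  g <- as.integer(segmental_grades)
  s <- sum(g)
  letter <- if (s <= 5L) "A" else if (s <= 8L) "B" else "C"
  structure(
    list(segmental_grades = g, grade_sum = s, overall_grade = letter,
         adequate = letter %in% c("A", "B")),
    class = "grading_result"
  )
}

#' @export
print.grading_result <- function(x, ...) {
  cat("Segmental grades:", paste(x$segmental_grades, collapse = " / "),
      " (sum ", x$grade_sum, ")\n", sep = "")
  cat("Overall grade:   ", x$overall_grade,
      if (x$adequate) " (adequate preparation)\n" else
        " (inadequate preparation)\n", sep = "")
  invisible(x)
}

#' Grade a whole case from its frame scores
#'
#' Computes the final average cleansing score, splits the case into
#' thirds, and derives segmental grades, the overall A/B/C grade, and
#' the adequacy call.
#'
#' @param scores Integer frame scores 1..5 in time order (at least 3).
#' @param fractions Optional per-frame estimated visible fractions; when
#'   given, the >50%-invisible test is applied to them directly rather
#'   than to the binned scores.
#' @param case_id Identifier carried into the report.
#' @return A `case_grading`: list with `case_id`, `n_frames`,
#'   `final_score`, `segment_invisible_fractions`, `segmental_grades`,
#'   `grade_sum`, `overall_grade`, `adequate`.
#' @examples
#' grade_case(rep(5, 30))
#' @export
grade_case <- function(scores, fractions = NULL, case_id = "case") {
  scores <- validate_scores(scores)
  if (length(scores) < 3L) stop_validation("a case needs at least 3 frames")
  if (!is.null(fractions) && length(fractions) != length(scores)) {
    stop_validation("fractions must match scores in length")
  }
  segs <- split_segments(scores)
  fsegs <- if (is.null(fractions)) vector("list", 3L) else
    split_segments(fractions)
  inv <- vapply(1:3, function(k) {
    invisible_fraction(segs[[k]], fractions = fsegs[[k]])
  }, 0)
  og <- overall_grade(segmental_grade(inv))
  structure(
    list(case_id = case_id, n_frames = length(scores),
         final_score = final_score(scores),
         segment_invisible_fractions = inv,
         segmental_grades = og$segmental_grades,
         grade_sum = og$grade_sum,
         overall_grade = og$overall_grade,
         adequate = og$adequate),
    class = "case_grading"
  )
}

#' @export
print.case_grading <- function(x, ...) {
  cat("Case ", x$case_id, ": ", x$n_frames, " frames\n", sep = "")
  cat(sprintf("Final cleansing score: %.1f\n", x$final_score))
  cat(sprintf(
    "Segment >50%%-invisible fractions: %.3f / %.3f / %.3f\n",
    x$segment_invisible_fractions[1], x$segment_invisible_fractions[2],
    x$segment_invisible_fractions[3]
  ))
  cat("Segmental grades:", paste(x$segmental_grades, collapse = " / "),
      "-> overall", x$overall_grade,
      if (x$adequate) "(adequate)\n" else "(inadequate)\n")
  invisible(x)
}
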