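embed_2x2 <- function(m) {
  cm <- matrix(0L, 5, 5)
  cm[1:2, 1:2] <- m
  cm
}

test_that("distribution means reproduce the published score tables", {
  dist_path <- system.file("extdata", "clinical_score_distribution.csv",
                           package = "cescore")
  d <- read.csv(dist_path)
  algo <- as.numeric(d[d$reader == "algorithm", paste0("s", 1:5)])
  clin <- as.numeric(d[d$reader == "clinicians", paste0("s", 1:5)])
  expect_equal(round(mean_score_from_distribution(algo), 1), 2.9)
  expect_equal(round(mean_score_from_distribution(clin), 1), 3.1)
  expect_equal(mean_score_from_distribution(rep(7L, 5)), 3.0)
  expect_error(mean_score_from_distribution(rep(0L, 5)),
               class = "cescore_validation_error")
  expect_error(mean_score_from_distribution(c(-1, 1, 1, 1, 1)),
               class = "cescore_validation_error")
})

test_that("top-1 accuracy is the confusion-matrix trace over total", {
  expect_equal(top1_accuracy(diag(c(5L, 3L, 2L, 8L, 1L))), 1)
  zero_diag <- matrix(1L, 5, 5) - diag(1L, 5)
  expect_equal(top1_accuracy(zero_diag), 0)
  expect_equal(top1_accuracy(embed_2x2(matrix(c(10, 5, 0, 5), 2))), 0.75)
})

test_that("kappa matches the hand-computed two-class example", {
  res <- cohen_kappa(embed_2x2(matrix(c(20, 10, 5, 15), 2)))
  expect_equal(res$po, 0.7)
  expect_equal(res$pe, 0.5)
  expect_equal(res$kappa, 0.4)
  expect_equal(res$underestimation, 10 / 50)  # predicted below reference
  expect_equal(res$overestimation, 5 / 50)
  expect_equal(res$misclassification,
               res$underestimation + res$overestimation)
})

test_that("kappa is 1 under perfect agreement and 0 under independence", {
  expect_equal(cohen_kappa(diag(c(4L, 9L, 2L, 7L, 3L)))$kappa, 1)
  # counts exactly proportional to the marginals
  r <- c(1, 2, 3, 4, 5)
  cc <- c(2, 1, 3, 1, 3)
  expect_equal(cohen_kappa(outer(r, cc))$kappa, 0)
  # degenerate single-cell matrix has Pe = 1
  single <- matrix(0L, 5, 5)
  single[2, 2] <- 10L
  expect_error(cohen_kappa(single), class = "cescore_validation_error")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(101)
  for (i in 1:50) {
    cm <- random_cm()
    if (abs(1 - cohen_kappa_pe(cm)) < 1e-9) next
    res <- cohen_kappa(cm)
    ref <- e1071::classAgreement(cm)
    expect_equal(res$kappa, ref$kappa, tolerance = 1e-12)
    expect_equal(res$top1, ref$diag, tolerance = 1e-12)
    expect_equal(res$top1 + res$misclassification, 1)
  }
})

test_that("kappa is invariant under simultaneous score relabelling", {
  set.seed(102)
  cm <- random_cm()
  perm <- sample(5)
  expect_equal(cohen_kappa(cm[perm, perm])$kappa, cohen_kappa(cm)$kappa)
})

test_that("confusion matrices are built with reference rows", {
  cm <- confusion_matrix(reference = c(1, 1, 2, 5), predicted = c(1, 2, 2, 4))
  expect_equal(sum(cm), 4)
  expect_equal(cm["S1", "S2"], 1L)
  expect_equal(cm["S5", "S4"], 1L)
  expect_equal(sum(diag(cm)), 2L)
  expect_error(confusion_matrix(1:3, 1:2), class = "cescore_validation_error")
})

test_that("group comparison recovers simulated grade means", {
  # identical groups: no between-group variance, F exactly 0
  flat <- compare_groups(list(A = c(3, 4, 5), B = c(3, 4, 5)))
  expect_equal(flat$f_statistic, 0)
  two <- compare_groups(list(A = c(4, 4.2), C = c(2, 2.2)))
  expect_equal(two$groups$mean, c(4.1, 2.1))

  set.seed(103)
  sim <- list(
    A = rnorm(20, 3.9, 0.3),
    B = rnorm(20, 3.2, 0.5),
    C = rnorm(20, 2.5, 0.5)
  )
  res <- compare_groups(sim)
  se <- c(0.3, 0.5, 0.5) / sqrt(20)
  expect_true(all(abs(res$groups$mean - c(3.9, 3.2, 2.5)) <= 2 * se))
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_display, "<0.001")
  # a singleton group reports undefined dispersion but keeps its mean
  one <- compare_groups(list(A = c(4, 4, 4.2), B = 3))
  expect_true(is.na(one$groups$sd[one$groups$grade == "B"]))
  expect_error(compare_groups(list(A = c(1, 2))),
               class = "cescore_validation_error")
})

test_that("ROC analysis reproduces the midpoint cut-off convention", {
  roc <- roc_analysis(c(3.4, 3.8, 3.1, 2.4, 2.8),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auc, 1)
  expect_equal(roc$cutoff, 2.95)
  expect_equal(roc$cutoff_sensitivity, 1)
  expect_equal(roc$cutoff_specificity, 1)
  expect_error(roc_analysis(c(3, 4), c(TRUE, TRUE)),
               class = "cescore_validation_error")
})

test_that("AUC is 1 for separated groups and near 0.5 for random labels", {
  set.seed(104)
  sep <- roc_analysis(c(runif(10, 3, 5), runif(10, 1, 2.9)),
                      rep(c(TRUE, FALSE), each = 10))
  expect_equal(sep$auc, 1)
  null <- roc_analysis(runif(500, 1, 5), sample(c(TRUE, FALSE), 500, TRUE))
  expect_gt(null$auc, 0.4)
  expect_lt(null$auc, 0.6)
})

test_that("trapezoidal AUC equals the concordant-pair statistic", {
  skip_if_not_installed("pROC")
  set.seed(105)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    scores <- round(runif(n, 1, 5), sample(1:2, 1))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- roc_analysis(scores, labels)
    pos <- scores[labels]
    neg <- scores[!labels]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
    expect_equal(roc$auc,
                 as.numeric(pROC::auc(labels, scores, direction = "<",
                                      quiet = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity decreases as the threshold rises", {
  set.seed(106)
  scores <- runif(60, 1, 5)
  labels <- scores + rnorm(60, 0, 0.8) > 3
  if (length(unique(labels)) == 2) {
    roc <- roc_analysis(scores, labels)
    expect_true(all(diff(rev(roc$sensitivity)) <= 0))
    expect_gte(roc$auc, 0)
    expect_lte(roc$auc, 1)
  }
})
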