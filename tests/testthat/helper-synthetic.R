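# Shared fixture builders (all fixtures are generated in code).

# Balanced synthetic frame set: n_per_class frames per score, fractions
# uniform within each score bin, labels from the generator's own ground
# truth.
make_frame_set <- function(n_per_class, seed, image_size = 64L) {
  set.seed(seed)
  bins <- rbind(c(0, 0.25), c(0.25, 0.50), c(0.50, 0.75),
                c(0.75, 0.90), c(0.90, 1))
  fracs <- unlist(lapply(1:5, function(k) {
    stats::runif(n_per_class, bins[k, 1], bins[k, 2])
  }))
  seeds <- sample.int(2^31 - 2, length(fracs))
  frames <- vector("list", length(fracs))
  labels <- integer(length(fracs))
  truth <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    o <- render_frame(frame_spec(image_size = image_size,
                                 visible_fraction = fracs[i],
                                 seed = seeds[i]))
    frames[[i]] <- o$frame
    labels[i] <- o$ground_truth$true_score
    truth[i] <- o$ground_truth$true_visible_fraction
  }
  list(frames = frames, labels = labels, truth = truth)
}

# Random 5x5 confusion matrix with positive total.
random_cm <- function() {
  cm <- matrix(rpois(25, lambda = sample(1:8, 1)), 5, 5)
  if (sum(cm) == 0) cm[sample(25, 1)] <- 1L
  cm
}

# Chance agreement of a confusion matrix, computed independently.
cohen_kappa_pe <- function(cm) {
  total <- sum(cm)
  sum((rowSums(cm) / total) * (colSums(cm) / total))
}

# A uniform random RGB frame.
random_frame <- function(n = 16L) {
  ce_frame(array(stats::runif(n * n * 3), dim = c(n, n, 3)))
}
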