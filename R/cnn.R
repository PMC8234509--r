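# Trainable 5-class convolutional scorer.
#
# Architecture (fixed small net, CPU-friendly at 64x64): three blocks of
# 3x3 convolution (16/32/64 channels) -> ReLU -> 2x2 max pooling, global
# average pooling, dense 5-way layer, softmax. Trained with RMSProp on
# categorical cross-entropy in two phases: a first phase at the initial
# learning rate, then all layers at the (much smaller) fine-tuning rate.
# Uncertainty between adjacent scores can be expressed as symmetric
# label smoothing toward the neighbouring classes.

#' Training configuration for the convolutional scorer
#'
#' @param initial_lr Learning rate of the first training phase
#'   (default 0.001).
#' @param fine_tune_lr Learning rate of the all-layer fine-tuning phase
#'   (default 0.00001).
#' @param epochs_initial,epochs_fine_tune Epochs per phase (defaults 10
#'   and 5).
#' @param batch_size Minibatch size (default 32).
#' @param adjacent_smoothing Label-smoothing mass `s` in `[0, 0.5)`
#'   moved to each adjacent score (default 0.1); interior classes get
#'   `1 - 2s`, edge classes keep the unused neighbour mass (`1 - s`).
#' @param warmup_scope Layers updated during the first phase: `"all"`
#'   (default) or `"head"` (dense layer only, convolutional features
#'   frozen until fine-tuning).
#' @param seed Integer seed for weight initialisation and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(initial_lr = 0.001, fine_tune_lr = 0.00001,
                         epochs_initial = 10L, epochs_fine_tune = 5L,
                         batch_size = 32L, adjacent_smoothing = 0.1,
                         warmup_scope = c("all", "head"), seed = 1L) {
  if (!is_scalar_number(initial_lr) || initial_lr <= 0 ||
      !is_scalar_number(fine_tune_lr) || fine_tune_lr <= 0) {
    stop_validation("learning rates must be positive")
  }
  if (!is_scalar_number(adjacent_smoothing) ||
      adjacent_smoothing < 0 || adjacent_smoothing >= 0.5) {
    stop_validation("adjacent_smoothing must be in [0, 0.5)")
  }
  warmup_scope <- match.arg(warmup_scope)
  structure(
    list(initial_lr = initial_lr, fine_tune_lr = fine_tune_lr,
         epochs_initial = as.integer(epochs_initial),
         epochs_fine_tune = as.integer(epochs_fine_tune),
         batch_size = as.integer(batch_size),
         adjacent_smoothing = adjacent_smoothing,
         warmup_scope = warmup_scope, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Soft targets with adjacent-score smoothing: the true class gets
# 1 - 2s, each existing neighbour s; at the scale's edges the missing
# neighbour's mass stays with the true class (e.g. s = 0.1, class 5 ->
# (0, 0, 0, 0.1, 0.9)).
smooth_targets <- function(labels, s) {
  y <- matrix(0, 5L, length(labels))
  for (i in seq_along(labels)) {
    k <- labels[i]
    y[k, i] <- 1 - 2 * s
    if (k > 1L) y[k - 1L, i] <- s
    if (k < 5L) y[k + 1L, i] <- s
    y[k, i] <- y[k, i] + (1 - sum(y[, i]))
  }
  y
}

# He-style initialisation for the fixed architecture.
cnn_init <- function(in_channels = 3L, channels = c(16L, 32L, 64L), seed = 1L) {
  with_seed(seed, {
    fan <- function(n) 9L * n
    list(
      W1 = matrix(stats::rnorm(channels[1] * fan(in_channels), 0,
                               sqrt(2 / fan(in_channels))),
                  channels[1], fan(in_channels)),
      b1 = numeric(channels[1]),
      W2 = matrix(stats::rnorm(channels[2] * fan(channels[1]), 0,
                               sqrt(2 / fan(channels[1]))),
                  channels[2], fan(channels[1])),
      b2 = numeric(channels[2]),
      W3 = matrix(stats::rnorm(channels[3] * fan(channels[2]), 0,
                               sqrt(2 / fan(channels[2]))),
                  channels[3], fan(channels[2])),
      b3 = numeric(channels[3]),
      Wd = matrix(stats::rnorm(5L * channels[3], 0, sqrt(1 / channels[3])),
                  5L, channels[3]),
      bd = numeric(5L)
    )
  })
}

# One RMSProp phase over the data. `scope` limits which tensors move.
rmsprop_phase <- function(params, x, y, lr, epochs, batch_size, scope,
                          rho = 0.9, eps = 1e-8) {
  n <- dim(x)[4]
  tensors <- if (scope == "head") c("Wd", "bd") else names(params)
  state <- lapply(params, function(p) p * 0)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s0 in starts) {
      take <- perm[s0:min(s0 + batch_size - 1L, n)]
      out <- .cnn_pass(params, x[, , , take, drop = FALSE],
                       y[, take, drop = FALSE], TRUE)
      g <- out$grads
      for (nm in tensors) {
        state[[nm]] <- rho * state[[nm]] + (1 - rho) * g[[nm]]^2
        params[[nm]] <- params[[nm]] - lr * g[[nm]] / (sqrt(state[[nm]]) + eps)
      }
    }
  }
  params
}

#' Train the convolutional cleansing-score classifier
#'
#' Trains the small CNN on preprocessed channel stacks in two phases —
#' first at `initial_lr`, then all layers at `fine_tune_lr` — using
#' RMSProp on categorical cross-entropy with softmax outputs and
#' optional adjacent-score label smoothing. Training is fully seeded and
#' reproducible on fixed hardware.
#'
#' @param x Training inputs: an `H x W x 3 x N` array of
#'   [stack_channels()] outputs, or a list of [ce_frame()] objects
#'   (stacked automatically). `H = W` must be divisible by 8.
#' @param labels Integer cleansing scores 1..5, length `N`; at least two
#'   distinct classes must be present.
#' @param config A [train_config()].
#' @return A `ce_model` object.
#' @export
train_classifier <- function(x, labels, config = train_config()) {
  if (is.list(x) && !is.array(x)) x <- stack_frames(x)
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop_validation("x must be an H x W x C x N array or a list of frames")
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(x)[4]) {
    stop_validation("labels must match the number of training frames")
  }
  if (length(labels) == 0L) stop_validation("training set is empty")
  if (any(is.na(labels)) || any(labels < 1L | labels > 5L)) {
    stop_validation("labels must be integers in 1..5")
  }
  if (length(unique(labels)) < 2L) {
    stop_validation("training needs at least 2 distinct classes")
  }
  if (!inherits(config, "train_config")) config <- do.call(train_config, config)

  y <- smooth_targets(labels, config$adjacent_smoothing)
  with_seed(config$seed, {
    params <- cnn_init(in_channels = dim(x)[3], seed = NULL)
    params <- rmsprop_phase(params, x, y, config$initial_lr,
                            config$epochs_initial, config$batch_size,
                            config$warmup_scope)
    params <- rmsprop_phase(params, x, y, config$fine_tune_lr,
                            config$epochs_fine_tune, config$batch_size,
                            "all")
    structure(
      list(params = params, config = config,
           input_size = dim(x)[1], in_channels = dim(x)[3],
           channels = c(nrow(params$W1), nrow(params$W2), nrow(params$W3)),
           classes = 1:5),
      class = "ce_model"
    )
  })
}

#' Predict per-frame score distributions
#'
#' Runs the trained classifier and returns the softmax probability of
#' each score (`P(G1)..P(G5)`); inference is deterministic.
#'
#' @param model A [train_classifier()] result.
#' @param x An `H x W x 3 x N` array of channel stacks, a single stack,
#'   or a list of frames.
#' @return A 5 x N matrix of probabilities; columns sum to 1.
#' @seealso [assign_score()]
#' @export
predict_scores <- function(model, x) {
  if (!inherits(model, "ce_model")) stop_validation("model must be a ce_model")
  if (is.list(x) && !is.array(x)) x <- stack_frames(x)
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 4L || dim(x)[1] != model$input_size ||
      dim(x)[2] != model$input_size || dim(x)[3] != model$in_channels) {
    stop_validation(
      "input shape does not match the model (expected ",
      model$input_size, "x", model$input_size, "x", model$in_channels, ")"
    )
  }
  probs <- matrix(0, 5L, dim(x)[4])
  # bounded batches keep the peak working set small
  starts <- seq(1L, dim(x)[4], by = 256L)
  for (s0 in starts) {
    take <- s0:min(s0 + 255L, dim(x)[4])
    probs[, take] <- .cnn_pass(model$params, x[, , , take, drop = FALSE],
                               matrix(0, 0L, 0L), FALSE)$probs
  }
  rownames(probs) <- paste0("p", 1:5)
  probs
}

#' Score frames with a trained model
#'
#' @param frames List of [ce_frame()] objects.
#' @param model A `ce_model`.
#' @param circular_mask Passed to [stack_channels()].
#' @return Data frame: `frame_index`, `p1..p5`, `score`.
#' @export
score_frames_model <- function(frames, model, circular_mask = FALSE) {
  probs <- predict_scores(model, stack_frames(frames, circular_mask))
  out <- data.frame(
    frame_index = vapply(frames, `[[`, 0L, "frame_index"),
    t(probs)
  )
  names(out)[2:6] <- paste0("p", 1:5)
  out$score <- assign_score(probs)
  out
}

#' Save / load a trained model
#'
#' The model is serialised to a single file plus a JSON sidecar
#' (`<path>.json`) recording the architecture, training configuration
#' and seed.
#'
#' @param model A `ce_model`.
#' @param path Destination file (e.g. `model.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `ce_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ce_model")) stop_validation("model must be a ce_model")
  saveRDS(model, path)
  sidecar <- list(
    format = "cescore-cnn-v1",
    architecture = list(
      input_size = model$input_size, in_channels = model$in_channels,
      conv_channels = model$channels, kernel = 3L, pool = 2L,
      head = "global-average-pool + dense-5 + softmax"
    ),
    class_order = model$classes,
    train_config = unclass(model$config)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ce_model")) stop_validation("file is not a ce_model")
  model
}
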