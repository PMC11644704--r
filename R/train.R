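# Training loop, prediction, and cross-validation protocols.

#' Training configuration
#'
#' Optimization settings: Adam with cosine-annealed learning rate (one
#' period over the full run, no restarts), mini-batches, cross-entropy
#' loss, and an exponential-moving-average (EMA) shadow copy of all
#' parameters updated every step and used for evaluation (zero-debiased,
#' so short runs are not dominated by the zero initialization).
#'
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param ema_decay EMA decay in `[0, 1)`; 0 makes the shadow equal the
#'   current weights after every step.
#' @param seed Seed for shuffling and dropout.
#' @param split_mode `"trial"` (default; all windows of a trial share a CV
#'   fold, preventing window leakage) or `"sample"`.
#' @param cosine Use cosine annealing (else constant `lr`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 300L, batch_size = 64L,
                         ema_decay = 0.999, seed = 1L,
                         split_mode = c("trial", "sample"), cosine = TRUE) {
  split_mode <- match.arg(split_mode)
  stopifnot(lr > 0, batch_size >= 1, ema_decay >= 0, ema_decay < 1,
            epochs >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), ema_decay = ema_decay,
                 seed = as.integer(seed), split_mode = split_mode,
                 cosine = isTRUE(cosine)),
            class = "train_config")
}

check_sampleset_for_model <- function(samples, cfg) {
  d <- dim(samples$data)
  if (d[2] != cfg$C || d[3] != cfg$T)
    stop(sprintf("sample shape %d x %d does not match model C=%d, T=%d",
                 d[2], d[3], cfg$C, cfg$T), call. = FALSE)
  if (any(samples$labels < 1L | samples$labels > cfg$n_classes))
    stop("labels must lie in 1..n_classes", call. = FALSE)
}

#' Train a model
#'
#' Mini-batch Adam with cosine-annealed learning rate, batch-normalization
#' running statistics, per-step EMA shadow weights, and a per-epoch mean
#' cross-entropy loss history.  Fully seeded: identical inputs and seeds
#' give identical trained weights.
#'
#' @param model A `macnet` from [macnet_init()].
#' @param samples A normalized `sample_set`.
#' @param cfg A [train_config()].
#' @return The trained `macnet`, with `history` (per-epoch loss), `ema`
#'   (bias-corrected shadow weights) and updated `bn` statistics.
#' @export
macnet_train <- function(model, samples, cfg = train_config()) {
  stopifnot(inherits(model, "macnet"), inherits(samples, "sample_set"),
            inherits(cfg, "train_config"))
  check_sampleset_for_model(samples, model$cfg)
  res <- cpp_train(model$params, unclass(model$cfg), samples$data,
                   samples$labels - 1L,
                   list(lr = cfg$lr, epochs = cfg$epochs,
                        batch_size = cfg$batch_size,
                        ema_decay = cfg$ema_decay, seed = cfg$seed,
                        cosine = cfg$cosine),
                   model$bn)
  model$params <- res$params
  model$ema <- res$ema
  model$bn <- res$bn
  model$history <- as.numeric(res$history)
  model$trained <- TRUE
  model
}

#' Forward pass (evaluation mode)
#'
#' @param model A `macnet`.
#' @param x N x C x T array (or a single C x T matrix).
#' @param use_ema Evaluate the EMA shadow weights when available.
#' @return List with `logits` and `probs` (N x M matrices).
#' @export
macnet_forward <- function(model, x, use_ema = TRUE) {
  stopifnot(inherits(model, "macnet"))
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  params <- if (use_ema && !is.null(model$ema)) model$ema else model$params
  if (!model$cfg$square_before_pool)
    warning("square disabled: negative pool inputs are clamped by safe log")
  logits <- cpp_forward(params, unclass(model$cfg), x, model$bn)
  probs <- softmax(logits)
  list(logits = logits, probs = probs)
}

#' @export
predict.macnet <- function(object, newdata, type = c("class", "prob"),
                           use_ema = TRUE, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "sample_set")) newdata$data else newdata
  fw <- suppressWarnings(macnet_forward(object, x, use_ema = use_ema))
  if (type == "prob") return(fw$probs)
  max.col(fw$logits, ties.method = "first")
}

#' Gradients of the batch loss (for diagnostics)
#'
#' Runs one forward/backward pass (batch statistics, no dropout) and
#' returns the gradient of the mean cross-entropy loss for every learnable
#' parameter, with the loss as an attribute.
#'
#' @param model A `macnet`.
#' @param x N x C x T array.
#' @param labels Integer labels in `1..M`.
#' @param batch_stats Normalize with batch statistics (training semantics).
#'   Note the spatial-conv bias has an exactly zero gradient under batch
#'   statistics (batch normalization cancels constant shifts); use
#'   `FALSE` to differentiate through the running statistics instead.
#' @return Named list of gradient arrays; attribute `loss`.
#' @export
macnet_gradients <- function(model, x, labels, batch_stats = TRUE) {
  stopifnot(inherits(model, "macnet"))
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  cpp_grads(model$params, unclass(model$cfg), x, as.integer(labels) - 1L,
            model$bn, training = isTRUE(batch_stats))
}

#' Seeded cross-validation folds
#'
#' Partitions units (trials by default, so that all windows of a trial
#' share a fold; or individual samples) into `k` near-equal groups,
#' stratified by class.
#'
#' @param samples A `sample_set`.
#' @param k Number of folds.
#' @param split_mode `"trial"` or `"sample"`.
#' @param seed Seed for the random partition.
#' @return List of `k` integer vectors of sample indices (disjoint, their
#'   union is all samples).
#' @export
make_folds <- function(samples, k = 10L, split_mode = c("trial", "sample"),
                       seed = 1L) {
  split_mode <- match.arg(split_mode)
  with_seed(seed, {
    if (split_mode == "trial") {
      tr <- samples$lineage$trial
      units <- unique(tr)
      unit_lab <- samples$labels[match(units, tr)]
    } else {
      units <- seq_along(samples$labels)
      unit_lab <- samples$labels
    }
    # stratified and globally balanced: shuffle within class, then cycle
    # fold ids continuously across the class-grouped unit list, so per-class
    # counts differ by at most one AND fold sizes stay near-equal
    ord <- unlist(lapply(sample(unique(unit_lab)), function(cl) {
      sample(which(unit_lab == cl))
    }))
    fold_of_unit <- integer(length(units))
    fold_of_unit[ord] <- rep(seq_len(k), length.out = length(units))
    if (split_mode == "trial") {
      lapply(seq_len(k), function(f) {
        which(tr %in% units[fold_of_unit == f])
      })
    } else {
      lapply(seq_len(k), function(f) which(fold_of_unit == f))
    }
  })
}

subset_samples <- function(samples, idx) {
  new_sample_set(samples$data[idx, , , drop = FALSE], samples$labels[idx],
                 samples$classes, samples$channel_names, samples$sfreq,
                 samples$lineage[idx, , drop = FALSE])
}

eval_fold <- function(model, samples, idx) {
  test <- subset_samples(samples, idx)
  pred <- predict(model, test)                       # EMA weights
  pred_raw <- predict(model, test, use_ema = FALSE)  # raw weights
  truth <- samples$labels[idx]
  cm <- confusion_matrix(truth, pred, model$cfg$n_classes)
  list(acc = accuracy_pct(truth, pred),
       acc_raw = accuracy_pct(truth, pred_raw),
       kappa = cohens_kappa(cm), confusion = cm)
}

new_eval_report <- function(per_fold, confusion, split_mode) {
  structure(list(per_fold = per_fold,
                 mean_acc = mean(per_fold$acc), sd_acc = sd(per_fold$acc),
                 mean_acc_raw = mean(per_fold$acc_raw),
                 mean_kappa = mean(per_fold$kappa),
                 confusion = confusion, split_mode = split_mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d fold(s), %s-level split\n",
              nrow(x$per_fold), x$split_mode))
  cat(sprintf("  accuracy %.2f%% +/- %.2f, kappa %.3f\n",
              x$mean_acc, ifelse(is.na(x$sd_acc), 0, x$sd_acc),
              x$mean_kappa))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Seeded random partition into `k` groups (trial-level by default); each
#' fold trains a freshly initialized model on the other `k - 1` groups and
#' evaluates accuracy, Cohen's kappa and the confusion matrix on the held
#' fold.  [tenfold_cv()] is the `k = 10` protocol (90% train / 10% test).
#'
#' @param samples A normalized `sample_set`.
#' @param model_cfg A [macnet_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param init_seed Seed for weight initialization (per fold: `init_seed +
#'   fold - 1`).
#' @return An `eval_report`: per-fold metrics, mean +/- SD accuracy, and
#'   the summed confusion matrix.
#' @export
kfold_cv <- function(samples, model_cfg = macnet_config(),
                     train_cfg = train_config(), k = 10L, init_seed = 1L) {
  stopifnot(inherits(samples, "sample_set"))
  folds <- make_folds(samples, k, train_cfg$split_mode, train_cfg$seed)
  per <- vector("list", k)
  cm_total <- matrix(0L, model_cfg$n_classes, model_cfg$n_classes)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(samples$labels), test_idx)
    train_lab <- samples$labels[train_idx]
    if (length(unique(train_lab)) < model_cfg$n_classes)
      warning(sprintf("fold %d: not all classes present in training data", f))
    model <- macnet_init(model_cfg, seed = init_seed + f - 1L)
    model <- macnet_train(model, subset_samples(samples, train_idx),
                          train_cfg)
    ev <- eval_fold(model, samples, test_idx)
    per[[f]] <- data.frame(fold = f, acc = ev$acc, acc_raw = ev$acc_raw,
                           kappa = ev$kappa, n_test = length(test_idx))
    cm_total <- cm_total + ev$confusion
  }
  new_eval_report(do.call(rbind, per), cm_total, train_cfg$split_mode)
}

#' @rdname kfold_cv
#' @export
tenfold_cv <- function(samples, model_cfg = macnet_config(),
                       train_cfg = train_config(), init_seed = 1L) {
  kfold_cv(samples, model_cfg, train_cfg, k = 10L, init_seed = init_seed)
}

#' Hold-out evaluation
#'
#' Partitions like [kfold_cv()] but holds out a single random fold as the
#' test set and trains once on the remaining `k - 1` folds (with `k = 10`:
#' a 90:10 split).
#'
#' @inheritParams kfold_cv
#' @param holdout_fold Which fold to hold out (seeded-random folds, so any
#'   index is a random fold).
#' @return An `eval_report` with a single row.
#' @export
holdout_eval <- function(samples, model_cfg = macnet_config(),
                         train_cfg = train_config(), k = 10L,
                         holdout_fold = 1L, init_seed = 1L) {
  folds <- make_folds(samples, k, train_cfg$split_mode, train_cfg$seed)
  test_idx <- folds[[holdout_fold]]
  train_idx <- setdiff(seq_along(samples$labels), test_idx)
  model <- macnet_init(model_cfg, seed = init_seed)
  model <- macnet_train(model, subset_samples(samples, train_idx), train_cfg)
  ev <- eval_fold(model, samples, test_idx)
  per <- data.frame(fold = holdout_fold, acc = ev$acc, acc_raw = ev$acc_raw,
                    kappa = ev$kappa, n_test = length(test_idx))
  new_eval_report(per, ev$confusion, train_cfg$split_mode)
}
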