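# Subject-dependent training with the staged learning-rate schedule, and
# stratified ten-fold cross-validation at the trial level (windows within a
# trial are dependent, so trials are the CV unit).

#' Training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 32).
#' @param lr_initial Initial Adam learning rate (default 1e-4).
#' @param lr_stage2 Rate after validation accuracy first reaches
#'   `acc_stage2` (default 5e-5).
#' @param lr_stage3 Rate after validation accuracy first reaches
#'   `acc_stage3` (default 1e-5).
#' @param acc_stage2,acc_stage3 Accuracy thresholds for the two rate drops
#'   (defaults 0.70 and 0.85). The schedule is monotone: the rate never
#'   increases.
#' @param folds Cross-validation folds (default 10).
#' @param val_fraction Fraction of each training class held out for the
#'   schedule's validation accuracy (default 0.1).
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and fold assignment.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, lr_initial = 1e-4,
                         lr_stage2 = 5e-5, lr_stage3 = 1e-5,
                         acc_stage2 = 0.70, acc_stage3 = 0.85, folds = 10L,
                         val_fraction = 0.1, seed = 1L) {
  if (!(lr_initial > lr_stage2 && lr_stage2 > lr_stage3 && lr_stage3 > 0)) {
    stop("need lr_initial > lr_stage2 > lr_stage3 > 0")
  }
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_stage2 = lr_stage2,
                 lr_stage3 = lr_stage3, acc_stage2 = acc_stage2,
                 acc_stage3 = acc_stage3, folds = as.integer(folds),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

cpp_cfg <- function(cfg, params) {
  list(g = cfg$grid_size, f1 = cfg$cnn_filters[1], f2 = cfg$cnn_filters[2],
       f3 = cfg$cnn_filters[3], k = length(params$we))
}

# list of topo_sequence -> list of per-trial band-matrix lists for C++
as_cpp_trials <- function(topo_list) {
  lapply(topo_list, function(tp) unname(topo_matrices(tp)[band_names()]))
}

#' Predict class probabilities for a list of trials
#'
#' @param topo_list List of `topo_sequence` objects.
#' @param params An `ssam_params`.
#' @param cfg A [model_config()].
#' @return Matrix, trials x classes.
#' @export
predict_probs <- function(topo_list, params, cfg = attr(params, "config")) {
  mats <- as_cpp_trials(topo_list)
  out <- ssam_batch_cpp(mats, rep(-1L, length(mats)), unclass(params),
                        cpp_cfg(cfg, params), NULL, FALSE)
  t(out$probs)
}

accuracy_from_probs <- function(probs, labels) {
  mean((probs[, 2] > probs[, 1]) == (labels == 1))
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

# Accepts an eeg_dataset (features are extracted) or a prepared list with
# $topo and $labels.
resolve_features <- function(x, labels = NULL, window_s = 1) {
  if (inherits(x, "eeg_dataset")) {
    prep <- prepare_trials(x, window_s = window_s)
  } else if (is.list(x) && !is.null(x$topo)) {
    prep <- x
  } else if (is.list(x) && inherits(x[[1]], "topo_sequence")) {
    prep <- list(topo = x, labels = labels)
  } else stop("x must be an eeg_dataset, prepared features, or a list of topo_sequence")
  if (!is.null(labels)) prep$labels <- as.integer(labels)
  if (is.null(prep$labels)) stop("labels are required")
  prep
}

#' Train the SSAM network on one subject's trials
#'
#' Adam optimization of the regularized negative log-likelihood for
#' `epochs` epochs. The learning rate starts at `lr_initial` and drops to
#' `lr_stage2`/`lr_stage3` the first time held-out validation accuracy
#' reaches 70%/85%; it never increases. Dropout is applied to the
#' flattened feature vector in training only.
#'
#' @param x An `eeg_dataset`, a [prepare_trials()] result, or a list of
#'   `topo_sequence`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param labels Optional labels (when `x` is a bare list of trials).
#' @param params_init Optional initial `ssam_params` (e.g. a warm start);
#'   defaults to a fresh [init_params()] seeded from `train_cfg$seed`.
#' @param verbose Print per-epoch progress.
#' @return List with `params` (trained `ssam_params`) and `history`
#'   (data.frame epoch/loss/train_acc/val_acc/lr).
#' @export
train_subject <- function(x, model_cfg = model_config(),
                          train_cfg = train_config(), labels = NULL,
                          params_init = NULL, verbose = FALSE) {
  prep <- resolve_features(x, labels)
  labels <- prep$labels
  if (length(unique(labels)) < 2) stop("dataset must contain both classes")
  set.seed(train_cfg$seed)
  params <- if (is.null(params_init)) {
    init_params(model_cfg, seed = train_cfg$seed)
  } else params_init
  mats <- as_cpp_trials(prep$topo)
  n_all <- length(mats)
  D <- ncol(params$Wd)

  # stratified validation split for the schedule
  val_idx <- integer(0)
  if (train_cfg$val_fraction > 0) {
    for (cl in c(0L, 1L)) {
      ids <- which(labels == cl)
      n_val <- max(1L, round(train_cfg$val_fraction * length(ids)))
      val_idx <- c(val_idx, sample(ids, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(n_all), val_idx)

  theta <- flatten_params(params)
  w_mask <- l2_mask(params)
  state <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0,
                theta = theta)
  lr <- train_cfg$lr_initial
  drop_rate <- model_cfg$dropout_rate
  lam <- model_cfg$l2_lambda
  ccfg <- cpp_cfg(model_cfg, params)
  hist <- vector("list", train_cfg$epochs)

  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    epoch_nll <- 0
    correct <- 0
    for (batch in batches) {
      B <- length(batch)
      mask <- if (drop_rate > 0) {
        matrix((stats::runif(D * B) >= drop_rate) / (1 - drop_rate), D, B)
      } else NULL
      params_now <- unflatten_params(state$theta, params)
      out <- ssam_batch_cpp(mats[batch], labels[batch], unclass(params_now),
                            ccfg, mask, TRUE)
      grad <- unlist(out$grads, use.names = FALSE) / B +
        2 * lam * state$theta * w_mask
      state <- adam_step(state$theta, grad, state, lr)
      epoch_nll <- epoch_nll + sum(out$nll)
      correct <- correct +
        sum((out$probs[2, ] > out$probs[1, ]) == (labels[batch] == 1))
    }
    params_now <- unflatten_params(state$theta, params)
    train_acc <- correct / length(tr_idx)
    val_acc <- if (length(val_idx)) {
      accuracy_from_probs(
        predict_probs(prep$topo[val_idx], params_now, model_cfg),
        labels[val_idx])
    } else train_acc
    loss <- epoch_nll / length(tr_idx) +
      lam * sum((state$theta * w_mask)^2)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = loss,
                                train_acc = train_acc, val_acc = val_acc,
                                lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f  lr %g",
                      epoch, loss, train_acc, val_acc, lr))
    }
    # Staged, monotone learning-rate schedule. The recognition rate that
    # triggers a drop is the minimum of training and held-out accuracy: a
    # drop requires both fit and generalization. On a small validation
    # split a single lucky epoch would otherwise collapse the rate while
    # the model is still at chance.
    sched_acc <- min(train_acc, val_acc)
    if (sched_acc >= train_cfg$acc_stage3) {
      lr <- min(lr, train_cfg$lr_stage3)
    } else if (sched_acc >= train_cfg$acc_stage2) {
      lr <- min(lr, train_cfg$lr_stage2)
    }
  }
  final <- unflatten_params(state$theta, params)
  list(params = final, history = do.call(rbind, hist))
}

# Stratified fold assignment: per class, shuffled indices dealt cyclically.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- sample(which(labels == cl))
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Confusion counts from predictions
#'
#' Class 1 (recall/create) is the positive class.
#'
#' @param predicted,actual Integer vectors of 0/1 labels.
#' @return Named list TP/TN/FP/FN.
#' @export
confusion_counts <- function(predicted, actual) {
  list(TP = sum(predicted == 1 & actual == 1),
       TN = sum(predicted == 0 & actual == 0),
       FP = sum(predicted == 1 & actual == 0),
       FN = sum(predicted == 0 & actual == 1))
}

#' Accuracy, precision and specificity from confusion counts
#'
#' `ACC = (TP+TN)/total`, `Precision = TP/(TP+FP)`,
#' `Specificity = TN/(FP+TN)`. Undefined ratios are returned as `NaN` with
#' a warning.
#'
#' @param c Named list or vector with TP, TN, FP, FN.
#' @return List with `accuracy`, `precision`, `specificity`.
#' @export
compute_metrics <- function(c) {
  c <- as.list(c)
  total <- c$TP + c$TN + c$FP + c$FN
  if (total <= 0) stop("empty confusion table")
  prec <- if (c$TP + c$FP == 0) {
    warning("precision undefined: no positive predictions")
    NaN
  } else c$TP / (c$TP + c$FP)
  spec <- if (c$FP + c$TN == 0) {
    warning("specificity undefined: no negative trials")
    NaN
  } else c$TN / (c$FP + c$TN)
  list(accuracy = (c$TP + c$TN) / total, precision = prec, specificity = spec)
}

#' ROC points from scores
#'
#' Standard threshold sweep over the unique class-1 scores; the curve
#' starts at (0,0), ends at (1,1), and is monotone in both coordinates.
#'
#' @param scores Per-trial probabilities of class 1.
#' @param labels True 0/1 labels (both classes required).
#' @return data.frame with columns `fpr`, `tpr`; trapezoidal AUC in
#'   attribute `"auc"`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required for a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  pts <- t(vapply(thr, function(th) {
    pred <- as.integer(scores >= th)
    c(fpr = sum(pred == 1 & labels == 0) / n_neg,
      tpr = sum(pred == 1 & labels == 1) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  df <- as.data.frame(pts)
  auc <- sum(diff(df$fpr) * (head(df$tpr, -1) + df$tpr[-1]) / 2)
  attr(df, "auc") <- auc
  df
}

#' Stratified k-fold cross-validation
#'
#' Each trial appears in exactly one test fold; a fresh model is trained
#' per fold with a fold-specific seed derived from `train_cfg$seed`.
#'
#' @param x An `eeg_dataset`, a [prepare_trials()] result, or a list of
#'   `topo_sequence`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param labels Optional labels.
#' @param verbose Print fold progress.
#' @return Object of class `cv_report`: per-fold confusion counts, metrics
#'   and histories; aggregate means; pooled confusion and ROC.
#' @export
crossvalidate <- function(x, model_cfg = model_config(),
                          train_cfg = train_config(), labels = NULL,
                          verbose = FALSE) {
  prep <- resolve_features(x, labels)
  labels <- prep$labels
  k <- train_cfg$folds
  min_per_class <- min(table(labels))
  if (length(unique(labels)) < 2 || min_per_class < k) {
    stop("need at least ", k, " trials per class for ", k,
         "-fold stratified CV (have ", min_per_class, ")")
  }
  fold <- stratified_folds(labels, k, train_cfg$seed)
  folds <- vector("list", k)
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    tc <- train_cfg
    tc$seed <- as.integer((train_cfg$seed + 1000L * f) %% .Machine$integer.max)
    fit <- train_subject(list(topo = prep$topo[train_idx],
                              labels = labels[train_idx]),
                         model_cfg, tc)
    probs <- predict_probs(prep$topo[test_idx], fit$params, model_cfg)
    scores[test_idx] <- probs[, 2]
    pred <- as.integer(probs[, 2] > probs[, 1])
    conf <- confusion_counts(pred, labels[test_idx])
    folds[[f]] <- list(test_idx = test_idx, confusion = conf,
                       metrics = suppressWarnings(compute_metrics(conf)),
                       history = fit$history, params = fit$params)
    if (verbose) {
      message(sprintf("fold %2d/%d  acc %.3f", f, k,
                      folds[[f]]$metrics$accuracy))
    }
  }
  pooled <- list(
    TP = sum(vapply(folds, function(z) z$confusion$TP, 0)),
    TN = sum(vapply(folds, function(z) z$confusion$TN, 0)),
    FP = sum(vapply(folds, function(z) z$confusion$FP, 0)),
    FN = sum(vapply(folds, function(z) z$confusion$FN, 0)))
  agg <- list(
    accuracy = mean(vapply(folds, function(z) z$metrics$accuracy, 0)),
    precision = mean(vapply(folds, function(z) z$metrics$precision, 0),
                     na.rm = TRUE),
    specificity = mean(vapply(folds, function(z) z$metrics$specificity, 0),
                       na.rm = TRUE))
  structure(list(folds = folds, fold_assignment = fold, aggregate = agg,
                 pooled_confusion = pooled,
                 pooled_metrics = suppressWarnings(compute_metrics(pooled)),
                 roc = roc_points(scores, labels), scores = scores,
                 labels = labels),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %d folds | mean accuracy %.3f, precision ",
                     "%.3f, specificity %.3f | AUC %.3f\n"),
              length(x$folds), x$aggregate$accuracy, x$aggregate$precision,
              x$aggregate$specificity, attr(x$roc, "auc")))
  invisible(x)
}

#' Write a CV report as JSON + CSV files (plus per-fold checkpoints)
#'
#' @param report A `cv_report`.
#' @param dir Output directory.
#' @param checkpoints Also save each fold's trained parameters (default
#'   TRUE).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir, checkpoints = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (checkpoints) {
    for (f in seq_along(report$folds)) {
      save_checkpoint(report$folds[[f]]$params,
                      file.path(dir, sprintf("fold%02d.ckpt", f)))
    }
  }
  per_fold <- do.call(rbind, lapply(seq_along(report$folds), function(f) {
    z <- report$folds[[f]]
    data.frame(fold = f, TP = z$confusion$TP, TN = z$confusion$TN,
               FP = z$confusion$FP, FN = z$confusion$FN,
               accuracy = z$metrics$accuracy,
               precision = z$metrics$precision,
               specificity = z$metrics$specificity)
  }))
  utils::write.csv(per_fold, file.path(dir, "folds.csv"), row.names = FALSE)
  utils::write.csv(report$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  jsonlite::write_json(list(aggregate = report$aggregate,
                            pooled_confusion = report$pooled_confusion,
                            pooled_metrics = report$pooled_metrics,
                            auc = attr(report$roc, "auc")),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
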