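#' Training configuration
#'
#' Mirrors the published training recipe: Adam at learning rate 0.001,
#' cross-entropy loss, batch size 64, 15 epochs per fold, dropout 0.2,
#' four-fold cross-validation.
#'
#' @param lr learning rate (> 0).
#' @param batch_size mini-batch size.
#' @param epochs_per_fold epochs of training per CV fold.
#' @param dropout dropout rate on the pooled representation.
#' @param n_folds number of cross-validation folds (>= 2).
#' @param seed integer seed driving fold assignment, initialization,
#'   batch shuffling and dropout.
#' @param group_by fold granularity: `"trial"` (default; all segments of
#'   a trial share a fold, so overlapping windows cannot leak),
#'   `"subject"`, or `"none"` (segment-level splits).
#' @param positive_class class anchoring precision/recall/F1
#'   (`"left"`, the default, or `"right"`).
#' @return a `train_config` list.  Optimizer is Adam with the canonical
#'   constants (beta1 0.9, beta2 0.999, eps 1e-8); loss is softmax
#'   cross-entropy.
#' @export
train_config <- function(lr = 0.001, batch_size = 64L,
                         epochs_per_fold = 15L, dropout = 0.2,
                         n_folds = 4L, seed = 1L,
                         group_by = c("trial", "subject", "none"),
                         positive_class = c("left", "right")) {
  group_by <- match.arg(group_by)
  positive_class <- match.arg(positive_class)
  if (lr < 0) stop("lr must be nonnegative")  # 0 = evaluation-only sanity
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (epochs_per_fold < 1) stop("epochs_per_fold must be >= 1")
  structure(list(lr = lr, optimizer = "adam", loss = "cross_entropy",
                 batch_size = as.integer(batch_size),
                 epochs_per_fold = as.integer(epochs_per_fold),
                 dropout = dropout, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), group_by = group_by,
                 positive_class = positive_class),
            class = "train_config")
}

#' Split samples into k cross-validation folds
#'
#' Deterministic given `seed`.  With `group_by = "none"` the sample
#' indices are shuffled and dealt round-robin, so fold sizes differ by
#' at most one.  With `"trial"` (or `"subject"`) whole trials (subjects)
#' are assigned to folds greedily by current fold size, keeping every
#' segment of a group in a single fold.
#'
#' @param samples list of `graph_sample`s (or an integer sample count
#'   when `group_by = "none"`).
#' @param k number of folds.
#' @param seed integer seed.
#' @param group_by `"none"`, `"trial"` or `"subject"`.
#' @return list of `k` disjoint integer index vectors partitioning the
#'   samples.
#' @export
kfold_split <- function(samples, k, seed = 1L,
                        group_by = c("none", "trial", "subject")) {
  group_by <- match.arg(group_by)
  n <- if (is.numeric(samples)) as.integer(samples) else length(samples)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  set.seed(seed)
  if (group_by == "none") {
    idx <- sample.int(n)
    return(lapply(seq_len(k), function(f) sort(idx[seq(f, n, by = k)])))
  }
  key <- vapply(samples, function(s) {
    if (group_by == "trial")
      paste(s$source$subject_id, s$source$trial_id, sep = "/")
    else s$source$subject_id
  }, "")
  groups <- split(seq_len(n), key)
  if (k > length(groups))
    stop("k = ", k, " exceeds the number of ", group_by, " groups (",
         length(groups), ")")
  ord <- sample(length(groups))
  folds <- vector("list", k)
  sizes <- integer(k)
  for (gi in ord) {
    f <- which.min(sizes)
    folds[[f]] <- c(folds[[f]], groups[[gi]])
    sizes[f] <- sizes[f] + length(groups[[gi]])
  }
  lapply(folds, sort)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from the four confusion-matrix
#' counts.  Undefined ratios (zero denominators) are reported as 0 and
#' flagged rather than propagating `NaN`.
#'
#' @param c list or named vector with `TP`, `TN`, `FP`, `FN`.
#' @return list with `accuracy`, `precision`, `recall`, `f1` and a
#'   character vector `flags` naming any undefined metric.
#' @examples
#' compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
#' @export
compute_metrics <- function(c) {
  tp <- c[["TP"]]; tn <- c[["TN"]]; fp <- c[["FP"]]; fn <- c[["FN"]]
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated samples")
  flags <- character()
  acc <- (tp + tn) / total
  if (tp + fp == 0) { prec <- 0; flags <- c(flags, "precision_undefined") }
  else prec <- tp / (tp + fp)
  if (tp + fn == 0) { rec <- 0; flags <- c(flags, "recall_undefined") }
  else rec <- tp / (tp + fn)
  f1 <- f1_score(prec, rec)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       flags = flags)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 p r / (p + r)`, defined as 0 when both are 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @return the F1 score.
#' @examples
#' f1_score(0.46, 1.00)  # 0.6301...
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# confusion counts with class `pos` (0/1) as positive
.confusion <- function(truth, pred, pos = 1L) {
  list(TP = sum(truth == pos & pred == pos),
       TN = sum(truth != pos & pred != pos),
       FP = sum(truth != pos & pred == pos),
       FN = sum(truth == pos & pred != pos))
}

.adam_step <- function(p, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(p)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  p
}

#' Train on one fold and evaluate on its validation set
#'
#' Mini-batch Adam on softmax cross-entropy for
#' `train_config$epochs_per_fold` epochs, dropout active during training
#' only, fully seeded.  Returns the trained parameters, the per-epoch
#' mean training loss and the validation confusion counts.
#'
#' @param train_samples,val_samples nonempty lists of `graph_sample`s;
#'   the training set must contain both classes.
#' @param model_config a [model_config()] (`window_samples` may be
#'   `NULL`; it is then inferred from the data).
#' @param train_config a [train_config()].
#' @param fold fold index, used in error messages and seeding.
#' @return list with `params`, `loss_curve` (length
#'   `epochs_per_fold`), `confusion`, `metrics`.
#' @export
train_fold <- function(train_samples, val_samples, model_config,
                       train_config, fold = 1L) {
  if (!length(train_samples) || !length(val_samples))
    stop("empty train or validation set (fold ", fold, ")")
  ytr <- vapply(train_samples, function(s) s$label, 0L)
  if (length(unique(ytr)) < 2L)
    stop("training set contains a single class (fold ", fold, ")")
  if (is.null(model_config$window_samples))
    model_config$window_samples <- ncol(train_samples[[1]]$x)
  cfg <- model_config
  cfg$dropout <- train_config$dropout
  seed <- train_config$seed + 101L * fold
  prep_tr <- lapply(train_samples, .prep_sample)
  prep_va <- lapply(val_samples, .prep_sample)
  params <- init_params(cfg, seed = seed)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(params, function(x) x * 0)
  state$v <- lapply(params, function(x) x * 0)
  set.seed(seed + 1L)
  n <- length(prep_tr)
  loss_curve <- numeric(train_config$epochs_per_fold)
  for (ep in seq_len(train_config$epochs_per_fold)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = train_config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + train_config$batch_size - 1L, n)]
      gsum <- NULL
      lsum <- 0
      for (i in idx) {
        dropmask <- NULL
        if (cfg$dropout > 0) {
          keep <- stats::runif(cfg$gat_head_dim) >= cfg$dropout
          dropmask <- keep / (1 - cfg$dropout)
        }
        r <- .loss_grad_sample(prep_tr[[i]], params, cfg, dropmask)
        lsum <- lsum + r$loss
        gsum <- .add_grads(gsum, r$grads)
      }
      nb <- length(idx)
      for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] / nb
      if (train_config$lr > 0)
        params <- .adam_step(params, gsum, state, train_config$lr)
      batch_losses[bi] <- lsum / nb
    }
    loss_curve[ep] <- mean(batch_losses)
  }
  truth <- vapply(prep_va, function(pr) pr$y, 0L)
  pred <- vapply(prep_va, function(pr) {
    lg <- .model_fwd(pr, params, cfg)$logits
    which.max(lg) - 1L
  }, 0L)
  pos <- if (train_config$positive_class == "left") 1L else 0L
  conf <- .confusion(truth, pred, pos)
  list(params = params, loss_curve = loss_curve, confusion = conf,
       metrics = compute_metrics(conf))
}

#' Cross-validated training and evaluation
#'
#' Trains one fresh model per held-out fold (fold-specific seeded
#' initialization) and aggregates the confusion-matrix metrics across
#' folds.  Every sample is used for validation exactly once.
#'
#' @param dataset a [build_dataset()] result (or any list of
#'   `graph_sample`s).
#' @param model_config a [model_config()].
#' @param train_config a [train_config()].
#' @return An object of class `cv_report`: list with `per_fold` (each
#'   entry: `confusion`, `accuracy`, `precision`, `recall`, `f1`,
#'   `loss_curve`, `n_val`) and `aggregate` (mean and sd of each metric
#'   across folds).
#' @export
run_cv <- function(dataset, model_config, train_config) {
  samples <- if (inherits(dataset, "graph_dataset")) dataset$samples
             else dataset
  if (!length(samples)) stop("empty dataset")
  folds <- kfold_split(samples, train_config$n_folds, train_config$seed,
                       group_by = train_config$group_by)
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    val_idx <- folds[[f]]
    tr_idx <- setdiff(seq_along(samples), val_idx)
    res <- tryCatch(
      train_fold(samples[tr_idx], samples[val_idx], model_config,
                 train_config, fold = f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    per_fold[[f]] <- list(confusion = res$confusion,
                          accuracy = res$metrics$accuracy,
                          precision = res$metrics$precision,
                          recall = res$metrics$recall,
                          f1 = res$metrics$f1,
                          loss_curve = res$loss_curve,
                          n_val = length(val_idx))
  }
  metric_names <- c("accuracy", "precision", "recall", "f1")
  agg <- lapply(metric_names, function(m) {
    v <- vapply(per_fold, `[[`, 0, m)
    c(mean = mean(v), sd = stats::sd(v))
  })
  names(agg) <- metric_names
  structure(list(per_fold = per_fold, aggregate = agg,
                 n_folds = length(folds)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$n_folds, "folds\n")
  for (m in names(x$aggregate))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$aggregate[[m]]["mean"],
                x$aggregate[[m]]["sd"]))
  invisible(x)
}

#' Write a cross-validation report as JSON
#'
#' @param report a [run_cv()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Performance as a function of segment duration
#'
#' Re-windows the recordings at each requested duration, rebuilds the
#' correlation graphs and runs a full cross-validation per duration.
#' Durations producing zero usable segments are flagged and skipped;
#' duplicates are removed with a warning.
#'
#' @param recordings list of labeled [eeg_recording()]s.
#' @param durations numeric vector of window durations in seconds.
#' @param model_config a [model_config()] (`window_samples` is set per
#'   duration).
#' @param train_config a [train_config()].
#' @param dataset_config a [dataset_config()]; its `window_s` is
#'   overridden per duration.
#' @return data.frame with one row per duration: sample count, mean and
#'   sd of each metric across folds, and a `flagged` column for
#'   durations that produced no data.  The per-duration `cv_report`s are
#'   attached as attribute `"reports"`.
#' @export
duration_sweep <- function(recordings, durations, model_config,
                           train_config, dataset_config = dataset_config()) {
  if (any(durations <= 0)) stop("durations must be positive")
  if (anyDuplicated(durations)) {
    warning("duplicate durations removed")
    durations <- unique(durations)
  }
  rows <- list()
  reports <- list()
  for (d in durations) {
    dc <- dataset_config
    dc$window_s <- d
    ds <- tryCatch(suppressWarnings(build_dataset(recordings, dc)),
                   error = function(e) NULL)
    if (is.null(ds) || !length(ds$samples)) {
      rows[[length(rows) + 1L]] <- data.frame(
        duration_s = d, n_samples = 0L, accuracy_mean = NA_real_,
        accuracy_sd = NA_real_, precision_mean = NA_real_,
        recall_mean = NA_real_, f1_mean = NA_real_, flagged = TRUE)
      next
    }
    mc <- model_config
    mc$window_samples <- ncol(ds$samples[[1]]$x)
    rep_ <- run_cv(ds, mc, train_config)
    reports[[as.character(d)]] <- rep_
    rows[[length(rows) + 1L]] <- data.frame(
      duration_s = d, n_samples = length(ds$samples),
      accuracy_mean = rep_$aggregate$accuracy["mean"],
      accuracy_sd = rep_$aggregate$accuracy["sd"],
      precision_mean = rep_$aggregate$precision["mean"],
      recall_mean = rep_$aggregate$recall["mean"],
      f1_mean = rep_$aggregate$f1["mean"], flagged = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
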