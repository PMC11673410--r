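test_that("kfold_split partitions indices with balanced sizes, deterministically", {
  f <- kfold_split(10, 4, seed = 1)
  expect_length(f, 4)
  expect_setequal(unlist(f), 1:10)
  expect_equal(sum(lengths(f)), 10)
  expect_true(max(lengths(f)) - min(lengths(f)) <= 1)
  expect_identical(f, kfold_split(10, 4, seed = 1))
  expect_false(identical(f, kfold_split(10, 4, seed = 2)))
  expect_error(kfold_split(3, 4, seed = 1), "exceeds")
})

test_that("trial-grouped folds never split a trial", {
  samples <- list()
  for (tr in 1:3)
    for (seg in 1:5)
      samples[[length(samples) + 1L]] <-
        make_toy_sample(3, seed = tr * 10 + seg)
  for (i in seq_along(samples))
    samples[[i]]$source$trial_id <- paste0("T", ceiling(i / 5))
  f <- kfold_split(samples, 3, seed = 1, group_by = "trial")
  expect_setequal(unlist(f), seq_along(samples))
  for (fold in f) {
    trials <- unique(vapply(samples[fold], function(s) s$source$trial_id, ""))
    expect_length(trials, 1)     # exactly one trial per fold here
    expect_length(fold, 5)
  }
})

test_that("confusion metrics implement the accuracy/precision/recall/F1 formulas", {
  m <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  m2 <- compute_metrics(list(TP = 3, TN = 2, FP = 1, FN = 4))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 3 / 7)
  expect_equal(m2$f1, 2 * 0.75 * (3 / 7) / (0.75 + 3 / 7))
  # undefined ratios: flagged zeros, not NaN
  m3 <- compute_metrics(list(TP = 0, TN = 4, FP = 0, FN = 0))
  expect_equal(m3$precision, 0)
  expect_true(all(c("precision_undefined", "recall_undefined") %in% m3$flags))
  expect_equal(m3$f1, 0)
})

test_that("F1 is the harmonic mean, bounded by min and max of p and r", {
  expect_equal(round(f1_score(0.46, 1.00), 2), 0.63)
  set.seed(51)
  for (i in 1:100) {
    cts <- as.list(rmultinom(1, 40, rep(0.25, 4))[, 1])
    names(cts) <- c("TP", "TN", "FP", "FN")
    m <- compute_metrics(cts)
    if (m$precision + m$recall > 0) {
      expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
      expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    }
    expect_equal(m$recall == 1, cts$FN == 0 && cts$TP > 0)
    expect_equal(m$precision == 1, cts$FP == 0 && cts$TP > 0)
  }
})

# quickly separable toy task: class encoded in the sign of node features
toy_task_samples <- function(n_per_class = 8, seed = 1) {
  set.seed(seed)
  samples <- list()
  for (i in seq_len(2 * n_per_class)) {
    lab <- i %% 2L
    s <- make_toy_sample(3, T_ = 8, n_montage = 6, seed = 60 + i,
                         edges = cbind(1:2, 2:3), label = lab)
    s$x <- s$x * 0.2 + (if (lab == 1L) 2 else -2)
    s$source$trial_id <- paste0("T", i)
    samples[[i]] <- s
  }
  samples
}

test_that("training reduces the loss on a separable toy problem", {
  samples <- toy_task_samples()
  mc <- tiny_model_config()
  tc <- train_config(batch_size = 8, epochs_per_fold = 15, dropout = 0.2,
                     seed = 1)
  r <- train_fold(samples[1:12], samples[13:16], mc, tc)
  expect_length(r$loss_curve, 15)
  expect_lt(r$loss_curve[15], r$loss_curve[1])
  total <- with(r$confusion, TP + TN + FP + FN)
  expect_equal(total, 4)
})

test_that("lr = 0 leaves the parameters bitwise unchanged", {
  samples <- toy_task_samples(4)
  mc <- tiny_model_config()
  tc <- train_config(lr = 0, batch_size = 4, epochs_per_fold = 2, seed = 2)
  r <- train_fold(samples[1:6], samples[7:8], mc, tc)
  mc2 <- mc
  mc2$window_samples <- 8L
  mc2$dropout <- tc$dropout
  expect_identical(r$params, init_params(mc2, seed = tc$seed + 101L))
})

test_that("a single-class training set is an error naming the fold", {
  samples <- toy_task_samples(4)
  onecls <- Filter(function(s) s$label == 1L, samples)
  mc <- tiny_model_config()
  tc <- train_config(seed = 1)
  expect_error(train_fold(onecls, samples[1:2], mc, tc, fold = 3),
               "single class.*fold 3")
})

test_that("cross-validation covers every sample once and aggregates by the mean", {
  samples <- toy_task_samples(8)
  mc <- tiny_model_config()
  tc <- train_config(batch_size = 8, epochs_per_fold = 3, n_folds = 4,
                     seed = 3, group_by = "none")
  rep_ <- run_cv(samples, mc, tc)
  expect_s3_class(rep_, "cv_report")
  expect_length(rep_$per_fold, 4)
  expect_equal(sum(vapply(rep_$per_fold, `[[`, 0, "n_val")),
               length(samples))
  accs <- vapply(rep_$per_fold, `[[`, 0, "accuracy")
  expect_equal(rep_$aggregate$accuracy[["mean"]], mean(accs),
               tolerance = 1e-12)
  expect_equal(rep_$aggregate$f1[["sd"]],
               sd(vapply(rep_$per_fold, `[[`, 0, "f1")), tolerance = 1e-12)
})

test_that("identical seed and config reproduce the CV report exactly", {
  samples <- toy_task_samples(6)
  mc <- tiny_model_config()
  tc <- train_config(batch_size = 8, epochs_per_fold = 2, n_folds = 3,
                     seed = 7, group_by = "none")
  d <- withr::local_tempdir()
  r1 <- run_cv(samples, mc, tc)
  r2 <- run_cv(samples, mc, tc)
  p1 <- file.path(d, "a.json"); p2 <- file.path(d, "b.json")
  write_cv_report(r1, p1); write_cv_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("duration_sweep builds one row per duration and flags empty ones", {
  cfg <- synth_config(n_subjects = 1, trials_per_subject = 4, fs = 16,
                      trial_s = 20, seed = 5)
  gen <- generate_dataset(cfg)
  mc <- model_config(n_channels = 16, d_model = 8, n_heads_temporal = 2,
                     d_ff = 8, d_node = 8, sage_hidden = 8, gcn_hidden = 8,
                     gat_heads = 2, gat_head_dim = 4, dropout = 0)
  tc <- train_config(batch_size = 8, epochs_per_fold = 2, n_folds = 2,
                     seed = 5)
  dc <- dataset_config(montage = cfg$montage)
  expect_warning(
    tab <- duration_sweep(gen$recordings, c(10, 5, 5), mc, tc, dc),
    "duplicate")
  expect_equal(tab$duration_s, c(10, 5))
  expect_false(any(tab$flagged))
  expect_true(all(tab$n_samples > 0))
  # a duration longer than the trials is flagged, the sweep continues
  tab2 <- suppressWarnings(
    duration_sweep(gen$recordings, c(30, 10), mc, tc, dc))
  expect_true(tab2$flagged[tab2$duration_s == 30])
  expect_false(tab2$flagged[tab2$duration_s == 10])
})
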