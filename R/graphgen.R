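#' Pearson correlation coefficient (sum form)
#'
#' Computes the correlation of two equal-length vectors in the classic
#' sum form
#' \deqn{r = \frac{n\sum x_i y_i - \sum x_i \sum y_i}{
#'   \sqrt{n\sum x_i^2 - (\sum x_i)^2}\,\sqrt{n\sum y_i^2 - (\sum y_i)^2}}}
#' clamped to \[-1, 1\] only against floating-point overshoot.  If either
#' vector has zero variance the coefficient is defined as 0 and flagged
#' (attribute `degenerate`), so a flat channel can never pass an edge
#' threshold and never divides by zero.
#'
#' @param x,y numeric vectors of the same length `n >= 2`.
#' @return correlation in \[-1, 1\]; attribute `degenerate` is `TRUE` for
#'   the zero-variance case.
#' @examples
#' pearson_corr(c(1, 2, 3), c(2, 4, 6))   #  1
#' pearson_corr(c(1, 2, 3), c(3, 2, 1))   # -1
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 2L) stop("need at least 2 samples")
  sx <- sum(x); sy <- sum(y)
  vx <- n * sum(x^2) - sx^2
  vy <- n * sum(y^2) - sy^2
  if (vx <= 0 || vy <= 0)
    return(structure(0, degenerate = TRUE))
  r <- (n * sum(x * y) - sx * sy) / (sqrt(vx) * sqrt(vy))
  structure(min(1, max(-1, r)), degenerate = FALSE)
}

#' Pairwise correlation matrix of a segment
#'
#' Evaluates the same sum-form coefficient as [pearson_corr()] for every
#' channel pair, vectorized over the whole matrix.  The result is exactly
#' symmetric (computed once per pair), has unit diagonal for
#' non-degenerate channels, and rows/columns of zero-variance channels
#' are all zero (attribute `degenerate_channels`).
#'
#' @param x an [eeg_segment()], or a plain numeric matrix with channels
#'   in rows.
#' @return symmetric correlation matrix with entries in \[-1, 1\].
#' @export
pcc_matrix <- function(x) {
  if (inherits(x, "eeg_segment")) x <- x$data
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 channels")
  n <- ncol(x)
  s1 <- rowSums(x)
  cp <- tcrossprod(x)              # sum x_i y_i for every pair (symmetric)
  num <- n * cp - tcrossprod(s1)
  v <- n * diag(cp) - s1^2
  degen <- v <= 0
  d <- sqrt(ifelse(degen, 1, v))
  r <- num / tcrossprod(d)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  if (any(degen)) {
    r[degen, ] <- 0
    r[, degen] <- 0
  }
  structure(r, degenerate_channels = which(degen))
}

#' Build a pruned electrode graph from a segment
#'
#' Electrodes are nodes; an edge is kept between two electrodes when the
#' Pearson correlation of their windowed time series exceeds `threshold`
#' (`r > threshold` in signed mode, the literal pruning rule; `|r| >
#' threshold` in absolute mode).  Nodes left without any surviving edge
#' are removed from the graph.  Node order is the montage order
#' restricted to survivors; self-edges are never created.
#'
#' When every edge is pruned an empty graph is returned with
#' `empty = TRUE`; callers (see [build_dataset()]) decide whether to skip
#' the sample.
#'
#' @param segment an [eeg_segment()].
#' @param montage a [standard_montage()] layout; channels not resolvable
#'   in the montage are excluded from the graph universe.
#' @param threshold edge threshold (default 0.7).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return An object of class `correlation_graph`: list with
#'   `node_labels`, `node_index` (positions in the montage-ordered
#'   channel universe), `pcc` (full matrix over that universe),
#'   `adjacency` (binary, survivors only), `edges` (m x 2 matrix, i < j,
#'   survivor indexing), `channel_labels` (the universe), `empty`.
#' @examples
#' seg <- eeg_segment(matrix(rnorm(3 * 64), 3), c("Cz", "Pz", "Oz"),
#'                    1, 64, "left", list(subject_id = "S1",
#'                    trial_id = "T1", start_sample = 1))
#' g <- build_graph(seg, standard_montage("reduced16"), threshold = 0.5)
#' @export
build_graph <- function(segment, montage, threshold = 0.7,
                        mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  keep <- montage_resolves(segment$channel_names, montage)
  if (sum(keep) < 2L)
    stop("fewer than 2 segment channels resolvable in montage")
  # channel universe in montage order
  univ <- montage$labels[montage$labels %in% segment$channel_names[keep]]
  ord <- match(univ, segment$channel_names)
  x <- segment$data[ord, , drop = FALSE]
  r <- pcc_matrix(x)
  passes <- if (mode == "signed") r > threshold else abs(r) > threshold
  diag(passes) <- FALSE
  deg <- rowSums(passes)
  surv <- which(deg >= 1L)
  if (length(surv) == 0L) {
    return(structure(list(node_labels = character(), node_index = integer(),
                          pcc = r, adjacency = matrix(0, 0, 0),
                          edges = matrix(0L, 0, 2),
                          channel_labels = univ, empty = TRUE),
                     class = "correlation_graph"))
  }
  a <- (passes[surv, surv, drop = FALSE]) * 1
  dimnames(a) <- list(univ[surv], univ[surv])
  e <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  edges <- matrix(as.integer(e), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(node_labels = univ[surv], node_index = surv,
                 pcc = r, adjacency = a, edges = edges,
                 channel_labels = univ, empty = FALSE),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph> %d/%d nodes, %d edges%s\n",
              length(x$node_labels), length(x$channel_labels),
              nrow(x$edges), if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Dataset configuration for graph construction
#'
#' @param window_s window duration in seconds (default 10).
#' @param overlap fractional window overlap (default 0).
#' @param resample_hz optional working sampling rate; recordings at a
#'   different rate are anti-alias resampled before windowing.
#' @param threshold correlation edge threshold (default 0.7).
#' @param mode `"signed"` or `"absolute"` pruning.
#' @param min_nodes minimum surviving node count for a usable sample
#'   (default 2).
#' @param montage a [standard_montage()] layout.
#' @return a `dataset_config` list.
#' @export
dataset_config <- function(window_s = 10, overlap = 0, resample_hz = NULL,
                           threshold = 0.7, mode = "signed", min_nodes = 2L,
                           montage = standard_montage()) {
  structure(list(window_s = window_s, overlap = overlap,
                 resample_hz = resample_hz, threshold = threshold,
                 mode = mode, min_nodes = as.integer(min_nodes),
                 montage = montage),
            class = "dataset_config")
}

#' Convert labeled recordings into a graph dataset
#'
#' The full graph-based dataset generation stage: per recording,
#' normalize (z-score per channel) then window (Hann taper) then build a
#' pruned correlation graph per segment.  Segments whose graph is empty
#' or has fewer than `min_nodes` survivors are skipped and recorded in
#' the manifest.  Deterministic given inputs and config.
#'
#' Each usable segment becomes a graph sample: the node-feature matrix
#' `x` holds the surviving electrodes' windowed, normalized series
#' (nodes x window samples, aligned with the graph's node order), and
#' `label` is the class index (attend-left = 1, attend-right = 0).
#'
#' @param recordings list of labeled [eeg_recording()]s.
#' @param config a [dataset_config()].
#' @return An object of class `graph_dataset`: list with `samples` (list
#'   of `graph_sample`), `manifest` (one data.frame row per segment,
#'   including skipped ones), `montage`, `config`.
#' @export
build_dataset <- function(recordings, config = dataset_config()) {
  if (length(recordings) == 0L) stop("no recordings supplied")
  samples <- list()
  rows <- list()
  for (rec in recordings) {
    if (is.na(rec$label))
      stop("recording ", rec$subject_id, "/", rec$trial_id,
           " has no attention label")
    if (!is.null(config$resample_hz))
      rec <- resample_recording(rec, config$resample_hz)
    rec <- normalize_recording(rec)
    segs <- window_segments(rec, config$window_s, config$overlap)
    for (seg in segs) {
      g <- build_graph(seg, config$montage, config$threshold, config$mode)
      n_nodes <- length(g$node_labels)
      skip <- g$empty || n_nodes < config$min_nodes
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, trial_id = rec$trial_id,
        start_sample = seg$source$start_sample, window_s = seg$window_s,
        label = seg$label, n_nodes = n_nodes, n_edges = nrow(g$edges),
        skipped = skip,
        reason = if (skip) "empty or too small graph after pruning" else "",
        stringsAsFactors = FALSE)
      if (skip) {
        warning("skipping empty/too-small graph: ", rec$subject_id, "/",
                rec$trial_id, " @", seg$source$start_sample, call. = FALSE)
        next
      }
      ord <- match(g$node_labels, seg$channel_names)
      samples[[length(samples) + 1L]] <- structure(
        list(x = seg$data[ord, , drop = FALSE],
             graph = g,
             label = if (seg$label == "left") 1L else 0L,
             n_montage = length(config$montage$labels),
             montage_index = match(g$node_labels, config$montage$labels),
             source = seg$source),
        class = "graph_sample")
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$sample_id <- cumsum(!manifest$skipped) * (!manifest$skipped)
  if (length(samples) == 0L)
    stop("every segment was skipped at threshold ", config$threshold,
         "; no usable samples")
  structure(list(samples = samples, manifest = manifest,
                 montage = config$montage, config = config),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  lab <- vapply(x$samples, function(s) s$label, 0L)
  cat(sprintf("<graph_dataset> %d samples (%d left / %d right), %d skipped\n",
              length(x$samples), sum(lab == 1L), sum(lab == 0L),
              sum(x$manifest$skipped)))
  invisible(x)
}

#' Write a graph dataset to a directory
#'
#' One TSV per sample for the node features, one JSON per sample for the
#' topology and provenance, plus `manifest.csv`.
#'
#' @param dataset a [build_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    base <- file.path(dir, sprintf("sample%05d", i))
    utils::write.table(s$x, paste0(base, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
      list(node_labels = s$graph$node_labels,
           edges = s$graph$edges, label = s$label,
           subject_id = s$source$subject_id, trial_id = s$source$trial_id,
           start_sample = s$source$start_sample),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
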