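# Independent brute-force oracles and tiny fixture builders.  The
# oracles deliberately use naive scalar loops / dense arithmetic so they
# share no code path with the package implementation they check.

# Pearson correlation, raw sum form evaluated with a scalar loop
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- 0; sx <- 0; sy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + x[i] * y[i]
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2
  }
  (n * sxy - sx * sy) / (sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2))
}

oracle_pcc_matrix <- function(x) {
  n <- nrow(x)
  r <- diag(n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      r[i, j] <- r[j, i] <- oracle_pearson(x[i, ], x[j, ])
  r
}

# neighbor lists from an undirected edge matrix
oracle_neighbors <- function(edges, n) {
  nb <- vector("list", n)
  if (nrow(edges))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  nb
}

# GraphSAGE mean aggregation, per-node loop
oracle_sage <- function(x, edges, W1, W2, b = NULL) {
  n <- nrow(x)
  nb <- oracle_neighbors(edges, n)
  out <- matrix(0, n, ncol(W1))
  for (i in seq_len(n)) {
    mn <- if (length(nb[[i]]))
      colMeans(x[nb[[i]], , drop = FALSE]) else numeric(ncol(x))
    out[i, ] <- drop(x[i, ] %*% W1) + drop(mn %*% W2)
    if (!is.null(b)) out[i, ] <- out[i, ] + b
  }
  out
}

# GCN propagation via explicit dense matrices
oracle_gcn <- function(H, A, W, slope = 0.01, activation = TRUE) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- diag(1 / sqrt(rowSums(At)))
  pre <- D %*% At %*% D %*% H %*% W
  if (!activation) return(pre)
  ifelse(pre >= 0, pre, slope * pre)
}

# GAT coefficients and single-head update with explicit exp/sum scalars
oracle_gat_alpha <- function(x, edges, a, W, slope = 0.01) {
  n <- nrow(x)
  dh <- ncol(W)
  nb <- oracle_neighbors(edges, n)
  lr <- function(v) if (v >= 0) v else slope * v
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- sort(unique(c(i, nb[[i]])))   # self-loop convention
    sc <- vapply(js, function(j) {
      exp(lr(sum(a * c(drop(x[i, ] %*% W), drop(x[j, ] %*% W)))))
    }, 0)
    alpha[i, js] <- sc / sum(sc)
  }
  alpha
}

oracle_gat_single_head <- function(x, edges, a, W, slope = 0.01) {
  alpha <- oracle_gat_alpha(x, edges, a, W, slope)
  n <- nrow(x)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (alpha[i, j] > 0)
        out[i, ] <- out[i, ] + alpha[i, j] * drop(x[j, ] %*% W)
  out
}

# scaled dot-product attention via per-row scalar softmax
oracle_attention <- function(Q, K, V) {
  dk <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  w <- matrix(0, nrow(Q), nrow(K))
  for (i in seq_len(nrow(Q))) {
    sc <- vapply(seq_len(nrow(K)),
                 function(j) sum(Q[i, ] * K[j, ]) / sqrt(dk), 0)
    e <- exp(sc)
    w[i, ] <- e / sum(e)
    out[i, ] <- colSums(w[i, ] * V)
  }
  list(output = out, weights = w)
}

# ---- fixtures -------------------------------------------------------------

# channels with EXACT pairwise sample correlations: linear combinations of
# an orthonormal, mean-zero basis
exact_corr_channels <- function(coefs, n = 32, seed = 1) {
  set.seed(seed)
  k <- ncol(coefs)
  m <- cbind(1, matrix(rnorm(n * k), n, k))
  q <- qr.Q(qr(m))[, -1, drop = FALSE]     # orthonormal, orthogonal to 1
  t(q %*% t(coefs))                        # rows = channels
}

make_recording <- function(n_ch = 3, n_s = 64, fs = 16, label = "left",
                           channels = c("Cz", "Pz", "Oz"), seed = 1,
                           subject = "S1", trial = "T1") {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n_s), n_ch), channels[seq_len(n_ch)],
                fs, label, subject, trial)
}

make_segment <- function(data, channels = paste0("ch", seq_len(nrow(data))),
                         fs = 16) {
  eeg_segment(data, channels, ncol(data) / fs, fs, "left",
              list(subject_id = "S1", trial_id = "T1", start_sample = 1L))
}

# hand-built graph sample (bypasses build_dataset) for model unit tests
make_toy_sample <- function(n_nodes = 4, T_ = 8,
                            n_montage = max(6L, n_nodes), seed = 1,
                            label = 1L, edges = NULL) {
  set.seed(seed)
  if (is.null(edges)) {
    edges <- t(combn(n_nodes, 2))
    edges <- edges[runif(nrow(edges)) < 0.6, , drop = FALSE]
    # ensure no isolated node: chain fallback
    deg <- tabulate(c(edges), n_nodes)
    for (i in which(deg == 0))
      edges <- rbind(edges, sort(c(i, if (i == 1) 2 else i - 1)))
    edges <- unique(edges)             # edges are a set
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"
  structure(list(
    x = matrix(rnorm(n_nodes * T_), n_nodes, T_),
    graph = list(edges = edges, empty = FALSE),
    label = label, n_montage = n_montage,
    montage_index = sort(sample.int(n_montage, n_nodes)),
    source = list(subject_id = "S1", trial_id = "T1", start_sample = 1L)),
    class = "graph_sample")
}

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 6, window_samples = 8, d_model = 4,
         n_heads_temporal = 2, n_transformer_layers = 2, d_ff = 6,
         d_node = 4, n_sage_layers = 2, sage_hidden = 4,
         gcn_hidden = 4, n_gat_layers = 2, gat_heads = 2,
         gat_head_dim = 3, dropout = 0),
    list(...))
  do.call(model_config, args)
}

# central finite-difference gradient of the per-sample loss
numeric_grad <- function(prep, params, cfg, name, idx, h = 1e-5) {
  lossf <- function(p) {
    fwd <- aadgraph:::.model_fwd(prep, p, cfg)
    lg <- fwd$logits
    m <- max(lg)
    pr <- exp(lg - m) / sum(exp(lg - m))
    -log(pr[prep$y + 1L])
  }
  pp <- params; pp[[name]][idx] <- pp[[name]][idx] + h
  pm <- params; pm[[name]][idx] <- pm[[name]][idx] - h
  (lossf(pp) - lossf(pm)) / (2 * h)
}
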