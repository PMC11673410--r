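#' Model configuration
#'
#' Hyperparameters of the hybrid temporal/spatial classifier: a stack of
#' transformer encoder layers over the time axis (channels as the token
#' feature dimension), followed by GraphSAGE, graph-convolution and
#' multi-head graph-attention layers over the pruned electrode graph,
#' global mean pooling and a linear two-class head.
#'
#' Layer counts follow the published architecture (two transformer
#' layers, two GraphSAGE layers, one GCN layer, graph-attention on top);
#' widths are engineering choices and fully overridable.
#'
#' @param n_channels size of the montage (node-identity projection rows).
#' @param window_samples segment length in samples (token count); may be
#'   left `NULL` and filled in from data by [run_cv()].
#' @param d_model transformer token width (divisible by
#'   `n_heads_temporal`).
#' @param n_heads_temporal temporal attention heads.
#' @param n_transformer_layers encoder layers (default 2).
#' @param d_ff feed-forward sublayer width.
#' @param temporal_mode `"encoder_only"` (default) or
#'   `"encoder_decoder"` (adds one decoder layer whose single learned
#'   query cross-attends to the encoder states; the resulting context is
#'   broadcast back onto the states).
#' @param use_posenc add sinusoidal positional encoding on the time
#'   axis (switchable off, e.g. for equivariance checks).
#' @param d_node width of each electrode's node feature after the
#'   temporal module.
#' @param n_sage_layers GraphSAGE layers (default 2).
#' @param sage_hidden,gcn_hidden spatial hidden widths.
#' @param n_gat_layers graph-attention layers (default 2; hidden layers
#'   concatenate heads, the final layer averages them).
#' @param gat_heads attention heads per GAT layer.
#' @param gat_head_dim per-head output width.
#' @param negative_slope LeakyReLU slope used throughout.
#' @param dropout dropout rate on the pooled representation
#'   (training only; default 0.2).
#' @param n_classes number of classes (2).
#' @return a `model_config` list.
#' @export
model_config <- function(n_channels, window_samples = NULL,
                         d_model = 64, n_heads_temporal = 4,
                         n_transformer_layers = 2, d_ff = 2 * d_model,
                         temporal_mode = c("encoder_only",
                                           "encoder_decoder"),
                         use_posenc = TRUE, d_node = 64,
                         n_sage_layers = 2, sage_hidden = 64,
                         gcn_hidden = 64, n_gat_layers = 2, gat_heads = 4,
                         gat_head_dim = 16, negative_slope = 0.01,
                         dropout = 0.2, n_classes = 2) {
  temporal_mode <- match.arg(temporal_mode)
  if (d_model %% n_heads_temporal != 0)
    stop("d_model must be divisible by n_heads_temporal")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (min(n_transformer_layers, n_sage_layers, n_gat_layers) < 1)
    stop("all layer counts must be >= 1")
  structure(list(
    n_channels = as.integer(n_channels),
    window_samples = if (is.null(window_samples)) NULL
                     else as.integer(window_samples),
    d_model = as.integer(d_model),
    n_heads_temporal = as.integer(n_heads_temporal),
    n_transformer_layers = as.integer(n_transformer_layers),
    d_ff = as.integer(d_ff), temporal_mode = temporal_mode,
    use_posenc = use_posenc, d_node = as.integer(d_node),
    n_sage_layers = as.integer(n_sage_layers),
    sage_hidden = as.integer(sage_hidden),
    gcn_hidden = as.integer(gcn_hidden),
    n_gat_layers = as.integer(n_gat_layers),
    gat_heads = as.integer(gat_heads),
    gat_head_dim = as.integer(gat_head_dim),
    negative_slope = negative_slope, dropout = dropout,
    n_classes = as.integer(n_classes)), class = "model_config")
}

# sinusoidal positional encoding, T x d
.posenc <- function(T_, d) {
  pos <- matrix(0, T_, d)
  t <- seq_len(T_) - 1
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2 * i - 1] <- sin(t * freq)
    if (2 * i <= d) pos[, 2 * i] <- cos(t * freq)
  }
  pos
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# widths of the GAT stack: inputs and output mode per layer
.gat_plan <- function(cfg) {
  l <- cfg$n_gat_layers
  ins <- numeric(l)
  ins[1] <- cfg$gcn_hidden
  if (l > 1)
    for (i in 2:l) ins[i] <- cfg$gat_heads * cfg$gat_head_dim
  list(ins = as.integer(ins),
       final = l)   # last layer averages heads, others concatenate
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization of every weight tensor, seeded for
#' reproducibility.  The returned flat named list is the single source
#' of truth consumed by [model_forward()], the trainer and the
#' checkpoint writer.
#'
#' @param config a [model_config()] with `window_samples` set.
#' @param seed integer RNG seed.
#' @return named list of parameter matrices/vectors.
#' @export
init_params <- function(config, seed = 1L) {
  if (is.null(config$window_samples))
    stop("config$window_samples must be set before init_params()")
  set.seed(seed)
  d <- config$d_model
  p <- list()
  p$win <- .glorot(config$n_channels, d)
  for (l in seq_len(config$n_transformer_layers)) {
    pre <- paste0("enc", l, "_")
    for (nm in c("wq", "wk", "wv", "wo")) p[[paste0(pre, nm)]] <- .glorot(d, d)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- numeric(d)
    p[[paste0(pre, "fw1")]] <- .glorot(d, config$d_ff)
    p[[paste0(pre, "fb1")]] <- numeric(config$d_ff)
    p[[paste0(pre, "fw2")]] <- .glorot(config$d_ff, d)
    p[[paste0(pre, "fb2")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- numeric(d)
  }
  if (config$temporal_mode == "encoder_decoder") {
    p$dec_query <- .glorot(1, d)
    for (nm in c("dec_wq", "dec_wk", "dec_wv", "dec_wo"))
      p[[nm]] <- .glorot(d, d)
    p$dec_bo <- numeric(d)
    p$dec_ln1_g <- rep(1, d); p$dec_ln1_b <- numeric(d)
    p$dec_fw1 <- .glorot(d, config$d_ff); p$dec_fb1 <- numeric(config$d_ff)
    p$dec_fw2 <- .glorot(config$d_ff, d); p$dec_fb2 <- numeric(d)
    p$dec_ln2_g <- rep(1, d); p$dec_ln2_b <- numeric(d)
  }
  p$wout <- .glorot(d, config$n_channels)
  p$wnode <- .glorot(config$window_samples, config$d_node)
  p$bnode <- numeric(config$d_node)
  din <- config$d_node
  for (l in seq_len(config$n_sage_layers)) {
    pre <- paste0("sage", l, "_")
    p[[paste0(pre, "w1")]] <- .glorot(din, config$sage_hidden)
    p[[paste0(pre, "w2")]] <- .glorot(din, config$sage_hidden)
    p[[paste0(pre, "b")]] <- numeric(config$sage_hidden)
    din <- config$sage_hidden
  }
  p$gcn_w <- .glorot(din, config$gcn_hidden)
  p$gcn_b <- numeric(config$gcn_hidden)
  plan <- .gat_plan(config)
  for (l in seq_len(config$n_gat_layers)) {
    for (k in seq_len(config$gat_heads)) {
      pre <- paste0("gat", l, "_h", k, "_")
      p[[paste0(pre, "w")]] <- .glorot(plan$ins[l], config$gat_head_dim)
      p[[paste0(pre, "a")]] <-
        stats::runif(2 * config$gat_head_dim, -0.1, 0.1)
    }
  }
  p$cls_w <- .glorot(config$gat_head_dim, config$n_classes)
  p$cls_b <- numeric(config$n_classes)
  p
}

# ---- internal forward passes (with caches for backprop) -------------------

.layernorm_fwd <- function(r, g, b, eps = 1e-5) {
  mu <- rowMeans(r)
  rc <- r - mu
  v <- rowMeans(rc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- rc * inv
  y <- xhat * matrix(g, nrow(r), length(g), byrow = TRUE) +
    matrix(b, nrow(r), length(b), byrow = TRUE)
  list(y = y, xhat = xhat, inv = inv)
}

.mha_fwd <- function(x, p, pre, n_heads) {
  d <- ncol(x)
  dk <- d %/% n_heads
  add_b <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)
  q <- add_b(x %*% p[[paste0(pre, "wq")]], p[[paste0(pre, "bq")]])
  k <- add_b(x %*% p[[paste0(pre, "wk")]], p[[paste0(pre, "bk")]])
  v <- add_b(x %*% p[[paste0(pre, "wv")]], p[[paste0(pre, "bv")]])
  o <- matrix(0, nrow(x), d)
  aw <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    hh <- ((h - 1) * dk + 1):(h * dk)
    aw[[h]] <- .softmax_rows(tcrossprod(q[, hh, drop = FALSE],
                                        k[, hh, drop = FALSE]) / sqrt(dk))
    o[, hh] <- aw[[h]] %*% v[, hh, drop = FALSE]
  }
  m <- add_b(o %*% p[[paste0(pre, "wo")]], p[[paste0(pre, "bo")]])
  list(m = m, q = q, k = k, v = v, o = o, aw = aw, x = x)
}

.encoder_layer_fwd <- function(x, p, pre, cfg) {
  mha <- .mha_fwd(x, p, pre, cfg$n_heads_temporal)
  r1 <- x + mha$m
  ln1 <- .layernorm_fwd(r1, p[[paste0(pre, "ln1_g")]],
                        p[[paste0(pre, "ln1_b")]])
  pre1 <- ln1$y %*% p[[paste0(pre, "fw1")]] +
    matrix(p[[paste0(pre, "fb1")]], nrow(x), cfg$d_ff, byrow = TRUE)
  f1 <- .lrelu(pre1, cfg$negative_slope)
  f2 <- f1 %*% p[[paste0(pre, "fw2")]] +
    matrix(p[[paste0(pre, "fb2")]], nrow(x), cfg$d_model, byrow = TRUE)
  r2 <- ln1$y + f2
  ln2 <- .layernorm_fwd(r2, p[[paste0(pre, "ln2_g")]],
                        p[[paste0(pre, "ln2_b")]])
  list(y = ln2$y, mha = mha, ln1 = ln1, pre1 = pre1, f1 = f1, ln2 = ln2)
}

# one decoder layer: a single learned query cross-attends to the encoder
# states z; the resulting context row is broadcast-added to every state.
.decoder_fwd <- function(z, p, cfg) {
  nh <- cfg$n_heads_temporal
  d <- cfg$d_model
  dk <- d %/% nh
  q0 <- p$dec_query
  q <- q0 %*% p$dec_wq
  kz <- z %*% p$dec_wk
  vz <- z %*% p$dec_wv
  o <- matrix(0, 1, d)
  aw <- vector("list", nh)
  for (h in seq_len(nh)) {
    hh <- ((h - 1) * dk + 1):(h * dk)
    aw[[h]] <- .softmax_rows(q[, hh, drop = FALSE] %*%
                               t(kz[, hh, drop = FALSE]) / sqrt(dk))
    o[, hh] <- aw[[h]] %*% vz[, hh, drop = FALSE]
  }
  c0 <- o %*% p$dec_wo + matrix(p$dec_bo, 1, d)
  r1 <- q0 + c0
  ln1 <- .layernorm_fwd(r1, p$dec_ln1_g, p$dec_ln1_b)
  pre1 <- ln1$y %*% p$dec_fw1 + matrix(p$dec_fb1, 1, cfg$d_ff)
  f1 <- .lrelu(pre1, cfg$negative_slope)
  f2 <- f1 %*% p$dec_fw2 + matrix(p$dec_fb2, 1, d)
  ln2 <- .layernorm_fwd(ln1$y + f2, p$dec_ln2_g, p$dec_ln2_b)
  zo <- z + matrix(ln2$y, nrow(z), d, byrow = TRUE)
  list(z = zo, q = q, kz = kz, vz = vz, o = o, aw = aw, c0 = c0,
       ln1 = ln1, pre1 = pre1, f1 = f1, ln2 = ln2)
}

# temporal module: time x channels in, per-electrode features out
.temporal_fwd <- function(xin, midx, p, cfg) {
  x0 <- xin %*% p$win[midx, , drop = FALSE]
  if (cfg$use_posenc) x0 <- x0 + .posenc(nrow(xin), cfg$d_model)
  layers <- vector("list", cfg$n_transformer_layers)
  x <- x0
  for (l in seq_len(cfg$n_transformer_layers)) {
    layers[[l]] <- .encoder_layer_fwd(x, p, paste0("enc", l, "_"), cfg)
    x <- layers[[l]]$y
  }
  dec <- NULL
  if (cfg$temporal_mode == "encoder_decoder") {
    dec <- .decoder_fwd(x, p, cfg)
    x <- dec$z
  }
  y <- x %*% p$wout[, midx, drop = FALSE]   # back to T x n
  series <- t(y)                            # each electrode's series
  h0 <- series %*% p$wnode +
    matrix(p$bnode, nrow(series), cfg$d_node, byrow = TRUE)
  list(h0 = h0, series = series, y = y, z = x, layers = layers, dec = dec,
       x0 = x0, xin = xin, midx = midx)
}

# one GAT head with cache
.gat_head_fwd <- function(h, mask, w, a, slope) {
  dh <- ncol(w)
  xw <- h %*% w
  sd <- drop(xw %*% a[seq_len(dh)])
  ss <- drop(xw %*% a[dh + seq_len(dh)])
  n <- nrow(h)
  e_raw <- outer(sd, rep(1, n)) + outer(rep(1, n), ss)
  e <- .lrelu(e_raw, slope)
  e[!mask] <- -Inf
  alpha <- .softmax_rows(e)
  list(out = alpha %*% xw, xw = xw, e_raw = e_raw, alpha = alpha)
}

# spatial module: node features + graph structure -> pooled vector
.spatial_fwd <- function(h0, madj, sadj, mask, p, cfg) {
  slope <- cfg$negative_slope
  h <- h0
  sage <- vector("list", cfg$n_sage_layers)
  for (l in seq_len(cfg$n_sage_layers)) {
    pre <- paste0("sage", l, "_")
    agg <- madj %*% h
    lin <- h %*% p[[paste0(pre, "w1")]] + agg %*% p[[paste0(pre, "w2")]] +
      matrix(p[[paste0(pre, "b")]], nrow(h), cfg$sage_hidden, byrow = TRUE)
    sage[[l]] <- list(h_in = h, agg = agg, lin = lin)
    h <- .lrelu(lin, slope)
  }
  gcn_in <- h
  u <- sadj %*% h
  gcn_lin <- u %*% p$gcn_w +
    matrix(p$gcn_b, nrow(h), cfg$gcn_hidden, byrow = TRUE)
  h <- .lrelu(gcn_lin, slope)
  gat <- vector("list", cfg$n_gat_layers)
  for (l in seq_len(cfg$n_gat_layers)) {
    final <- l == cfg$n_gat_layers
    heads <- vector("list", cfg$gat_heads)
    for (k in seq_len(cfg$gat_heads)) {
      pre <- paste0("gat", l, "_h", k, "_")
      heads[[k]] <- .gat_head_fwd(h, mask, p[[paste0(pre, "w")]],
                                  p[[paste0(pre, "a")]], slope)
    }
    if (final) {
      summed <- Reduce(`+`, lapply(heads, `[[`, "out")) / cfg$gat_heads
      out <- .lrelu(summed, slope)
    } else {
      summed <- do.call(cbind, lapply(heads, `[[`, "out"))
      out <- .lrelu(summed, slope)
    }
    gat[[l]] <- list(h_in = h, heads = heads, summed = summed, final = final)
    h <- out
  }
  pooled <- colMeans(h)
  list(pooled = pooled, h_final = h, gat = gat, gcn_in = gcn_in, u = u,
       gcn_lin = gcn_lin, sage = sage)
}

# assemble the static per-sample tensors the forward pass needs
.prep_sample <- function(sample) {
  n <- nrow(sample$x)
  a <- .edges_to_adjacency(sample$graph$edges, n)
  list(xin = t(sample$x), midx = sample$montage_index,
       a = a, madj = .mean_adjacency(a), sadj = .norm_adjacency(a),
       mask = (a + diag(n)) > 0, y = sample$label)
}

.model_fwd <- function(prep, p, cfg, dropmask = NULL) {
  tf <- .temporal_fwd(prep$xin, prep$midx, p, cfg)
  sp <- .spatial_fwd(tf$h0, prep$madj, prep$sadj, prep$mask, p, cfg)
  pooled <- sp$pooled
  if (!is.null(dropmask)) pooled <- pooled * dropmask
  logits <- drop(pooled %*% p$cls_w) + p$cls_b
  list(logits = logits, tf = tf, sp = sp, pooled_dropped = pooled)
}

#' Temporal transformer module
#'
#' Runs the encoder stack (and, in `encoder_decoder` mode, the
#' single-query decoder layer) over one segment's time series and
#' returns each electrode's contextualized representation.
#'
#' @param segment_features time x channels matrix (one segment,
#'   channels restricted to the graph's surviving electrodes).
#' @param params parameter list from [init_params()].
#' @param config the [model_config()].
#' @param channels integer montage indices of the columns of
#'   `segment_features` (selects the matching rows/columns of the
#'   node-identity projections).
#' @return list with `node_features` (channels x `d_node`) and `series`
#'   (channels x time, the contextualized per-electrode series before
#'   the node projection).
#' @export
temporal_forward <- function(segment_features, params, config,
                             channels = seq_len(ncol(segment_features))) {
  if (anyNA(segment_features))
    stop("NaN/NA in temporal input")
  if (max(channels) > config$n_channels ||
      length(channels) != ncol(segment_features))
    stop("channel index set does not match the input width ",
         "(graph survivors / montage wiring)")
  tf <- .temporal_fwd(segment_features, channels, params, config)
  list(node_features = tf$h0, series = tf$series)
}

#' Full model forward pass
#'
#' Temporal transformer -> per-electrode node features -> GraphSAGE
#' stack -> GCN -> graph-attention stack -> global mean pooling ->
#' (dropout in training) -> linear classifier.
#'
#' @param sample a `graph_sample` from [build_dataset()].
#' @param params parameter list from [init_params()].
#' @param config the [model_config()].
#' @param training if `TRUE`, applies dropout on the pooled vector using
#'   the current RNG stream; default `FALSE` (deterministic evaluation).
#' @return numeric class logits of length `config$n_classes`
#'   (attend-right, attend-left).
#' @export
model_forward <- function(sample, params, config, training = FALSE) {
  if (nrow(sample$x) < 1L || sample$graph$empty)
    stop("empty graph samples are unsupported; filter them upstream")
  prep <- .prep_sample(sample)
  dropmask <- NULL
  if (training && config$dropout > 0) {
    keep <- stats::runif(config$gat_head_dim) >= config$dropout
    dropmask <- keep / (1 - config$dropout)
  }
  fwd <- .model_fwd(prep, params, config, dropmask)
  if (anyNA(fwd$logits) || any(!is.finite(fwd$logits)))
    stop("non-finite logits")
  fwd$logits
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a parameter checkpoint
#'
#' A single portable JSON file holding the model configuration and every
#' parameter tensor.  Loading against an `expected_config` whose
#' architecture fields disagree is an error, never a silent reshape.
#'
#' @param params parameter list.
#' @param config the [model_config()] the parameters belong to.
#' @param path file path.
#' @return `path` invisibly (save); list with `params` and `config`
#'   (load).
#' @export
save_checkpoint <- function(params, config, path) {
  ser <- lapply(params, function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
    else list(dim = length(m), data = as.numeric(m))
  })
  jsonlite::write_json(list(config = unclass(config), params = ser), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config optional [model_config()] to validate against.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$temporal_mode <- as.character(cfg$temporal_mode)
  cfg <- structure(cfg, class = "model_config")
  if (!is.null(expected_config)) {
    arch <- c("n_channels", "window_samples", "d_model", "n_heads_temporal",
              "n_transformer_layers", "d_ff", "temporal_mode", "d_node",
              "n_sage_layers", "sage_hidden", "gcn_hidden", "n_gat_layers",
              "gat_heads", "gat_head_dim", "n_classes")
    for (f in arch) {
      if (!identical(as.vector(unlist(cfg[[f]])),
                     as.vector(unlist(expected_config[[f]]))))
        stop("checkpoint config mismatch on '", f, "': ",
             cfg[[f]], " vs ", expected_config[[f]])
    }
  }
  params <- lapply(obj$params, function(e) {
    if (length(e$dim) == 2) matrix(e$data, e$dim[1], e$dim[2])
    else as.numeric(e$data)
  })
  list(params = params, config = cfg)
}
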