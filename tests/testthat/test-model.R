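test_that("scaled dot-product attention matches hand-derived cases", {
  # single query/key: softmax of a scalar is 1
  r <- scaled_dot_attention(matrix(1, 1, 2), matrix(1, 1, 2),
                            matrix(7, 1, 1))
  expect_equal(r$weights, matrix(1, 1, 1))
  expect_equal(r$output, matrix(7, 1, 1))

  # identical key rows: uniform weights, output = column mean of V
  K <- matrix(1, 3, 2)
  V <- matrix(c(1, 2, 6, 0, 3, 3), 3)
  r <- scaled_dot_attention(matrix(rnorm(2), 1), K, V)
  expect_equal(r$weights, matrix(1 / 3, 1, 3))
  expect_equal(r$output, matrix(colMeans(V), 1))

  # hand-evaluated softmax(1/sqrt(2), 0)
  r <- scaled_dot_attention(matrix(c(1, 0), 1), diag(2),
                            matrix(c(1, 0), 2))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(r$weights, matrix(c(w1, 1 - w1), 1), tolerance = 1e-12)
  expect_equal(r$weights[1, 1], 0.6698, tolerance = 1e-4)
  expect_equal(r$output[1, 1], w1, tolerance = 1e-12)

  expect_error(scaled_dot_attention(matrix(NA_real_, 1, 1), diag(1),
                                    diag(1)), "NaN")
})

test_that("attention matches the scalar-loop oracle on random sequences", {
  set.seed(21)
  for (i in 1:20) {
    L <- sample(2:8, 1); dk <- sample(1:4, 1); dv <- sample(1:3, 1)
    Q <- matrix(rnorm(L * dk), L); K <- matrix(rnorm(L * dk), L)
    V <- matrix(rnorm(L * dv), L)
    r <- scaled_dot_attention(Q, K, V)
    o <- oracle_attention(Q, K, V)
    expect_lt(max(abs(r$output - o$output)), 1e-10)
    expect_lt(max(abs(r$weights - o$weights)), 1e-10)
    expect_equal(rowSums(r$weights), rep(1, L), tolerance = 1e-6)
  }
})

test_that("GraphSAGE layer: identity-weight star graph and isolated node", {
  # star: center 1, leaves 2..4; identity weights
  x <- rbind(rep(1, 3), matrix(0, 3, 3))
  edges <- cbind(1L, 2:4)
  out <- sage_forward(x, edges, diag(3), diag(3))
  expect_equal(out[1, ], rep(1, 3))          # own + mean(leaves)=0
  expect_equal(out[2, ], rep(1, 3))          # 0 + mean({center}) = 1
  # isolated node: empty-neighborhood mean is the zero vector
  out2 <- sage_forward(matrix(c(2, 5), 2, 1), matrix(0L, 0, 2),
                       diag(1), diag(1))
  expect_equal(out2, matrix(c(2, 5), 2, 1))
})

test_that("GraphSAGE matches the per-node loop oracle", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(2:8, 1); din <- sample(1:4, 1); dout <- sample(1:4, 1)
    s <- make_toy_sample(n, T_ = 8)
    x <- matrix(rnorm(n * din), n)
    W1 <- matrix(rnorm(din * dout), din); W2 <- matrix(rnorm(din * dout), din)
    b <- rnorm(dout)
    expect_lt(max(abs(sage_forward(x, s$graph$edges, W1, W2, b) -
                        oracle_sage(x, s$graph$edges, W1, W2, b))), 1e-10)
  }
})

test_that("GCN propagation collapses correctly on degenerate graphs", {
  # single node: A~ = D~ = 1, so H' = sigma(H W)
  H <- matrix(c(-2, 3), 1)
  W <- matrix(rnorm(4), 2)
  expect_equal(gcn_forward(H, matrix(0, 1, 1), W),
               leaky_relu(H %*% W, 0.01))
  # two connected nodes with identical features, W = I: output = features
  h <- c(0.4, -0.2)
  H2 <- rbind(h, h)
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(gcn_forward(H2, A2, diag(2), activation = "identity"),
               H2, ignore_attr = TRUE)
})

test_that("GCN matches the dense oracle on random graphs", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(2:8, 1); din <- sample(1:4, 1); dout <- sample(1:4, 1)
    s <- make_toy_sample(n)
    A <- aadgraph:::.edges_to_adjacency(s$graph$edges, n)
    H <- matrix(rnorm(n * din), n)
    W <- matrix(rnorm(din * dout), din)
    expect_lt(max(abs(gcn_forward(H, A, W) -
                        oracle_gcn(H, A, W))), 1e-10)
  }
  expect_error(gcn_forward(matrix(0, 2, 1), diag(2), matrix(1)),
               "zero diagonal")
})

test_that("GAT coefficients are a probability simplex and match the scalar oracle", {
  # exactly one neighbor + self: two identical feature rows give 0.5 each
  x <- rbind(c(1, 2), c(1, 2))
  edges <- matrix(c(1L, 2L), 1)
  a <- rnorm(4); W <- matrix(rnorm(4), 2)
  al <- gat_coefficients(x, edges, a, W)
  expect_equal(al, matrix(0.25 + 0.25, 2, 2), tolerance = 1e-12)

  set.seed(24)
  for (i in 1:25) {
    n <- sample(2:8, 1); din <- sample(1:3, 1); dh <- sample(1:3, 1)
    s <- make_toy_sample(n)
    x <- matrix(rnorm(n * din), n)
    a <- rnorm(2 * dh); W <- matrix(rnorm(din * dh), din)
    al <- gat_coefficients(x, s$graph$edges, a, W)
    expect_lt(max(abs(al - oracle_gat_alpha(x, s$graph$edges, a, W))), 1e-10)
    expect_equal(rowSums(al), rep(1, n), tolerance = 1e-6)
    expect_true(all(al >= 0))
  }
})

test_that("multi-head GAT with K=1 reduces to the single-head update", {
  set.seed(25)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    s <- make_toy_sample(n)
    x <- matrix(rnorm(n * 3), n)
    p <- list(list(W = matrix(rnorm(6), 3), a = rnorm(4)))
    got <- gat_forward(x, s$graph$edges, p, K = 1, mode = "concat",
                       activation = "identity")
    want <- oracle_gat_single_head(x, s$graph$edges, p[[1]]$a, p[[1]]$W)
    expect_lt(max(abs(got - want)), 1e-12)
    # average mode with one head is the same computation
    expect_equal(gat_forward(x, s$graph$edges, p, K = 1, mode = "average",
                             activation = "identity"), got)
  }
})

test_that("concatenated heads are independent and symmetric inputs stay symmetric", {
  set.seed(26)
  n <- 5
  s <- make_toy_sample(n)
  x <- matrix(rnorm(n * 3), n)
  p2 <- list(list(W = matrix(rnorm(6), 3), a = rnorm(4)),
             list(W = matrix(rnorm(6), 3), a = rnorm(4)))
  both <- gat_forward(x, s$graph$edges, p2, K = 2, mode = "concat")
  expect_equal(ncol(both), 4)              # 2 x head_dim
  solo1 <- gat_forward(x, s$graph$edges, p2[1], K = 1, mode = "concat")
  expect_equal(both[, 1:2], solo1)
  # identical node features: attention cannot break symmetry
  xs <- matrix(rep(c(1, -1, 0.5), each = n), n)
  outs <- gat_forward(xs, s$graph$edges, p2, K = 2)
  expect_equal(outs, outs[rep(1, n), ], ignore_attr = TRUE)
})

test_that("leaky_relu follows the piecewise definition with x=0 in the upper branch", {
  expect_equal(leaky_relu(3, 0.01), 3)
  expect_equal(leaky_relu(-2, 0.01), -0.02)
  expect_identical(leaky_relu(0, 0.01), 0)
  m <- matrix(c(-1, 1, -0.5, 0), 2)
  expect_equal(leaky_relu(m, 0.1), matrix(c(-0.1, 1, -0.05, 0), 2))
})

test_that("temporal module is time-permutation equivariant without positional encoding", {
  cfg <- tiny_model_config(use_posenc = FALSE)
  p <- init_params(cfg, seed = 2)
  X <- matrix(rnorm(8 * 3), 8, 3)
  ch <- c(1L, 3L, 5L)
  perm <- sample(8)
  a <- temporal_forward(X, p, cfg, ch)
  b <- temporal_forward(X[perm, ], p, cfg, ch)
  # tokens permute with the input; time-pooled features are invariant
  expect_equal(rowMeans(a$series), rowMeans(b$series), tolerance = 1e-10)
  expect_equal(a$series[, perm], b$series, tolerance = 1e-10)
})

test_that("zero input with zeroed feed-forward stays finite and deterministic", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, seed = 3)
  for (nm in grep("fw|fb", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * 0
  X <- matrix(0, 8, 2)
  out <- temporal_forward(X, p, cfg, c(1L, 2L))
  expect_true(all(is.finite(out$node_features)))
  expect_equal(out$node_features,
               temporal_forward(X, p, cfg, c(1L, 2L))$node_features)
})

test_that("model_forward yields finite 2-class logits and rejects empty graphs", {
  cfg <- tiny_model_config()
  s <- make_toy_sample(4, T_ = 8, n_montage = 6)
  p <- init_params(cfg, seed = 4)
  lg <- model_forward(s, p, cfg)
  expect_length(lg, 2)
  expect_true(all(is.finite(lg)))
  s_empty <- s
  s_empty$graph$empty <- TRUE
  expect_error(model_forward(s_empty, p, cfg), "empty graph")
})

test_that("pooled logits are invariant to node relabeling", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, seed = 5)
  for (i in 1:5) {
    s <- make_toy_sample(5, T_ = 8, n_montage = 6, seed = 30 + i)
    perm <- sample(5)
    s2 <- s
    s2$x <- s$x[perm, ]
    s2$montage_index <- s$montage_index[perm]
    inv <- order(perm)
    remap <- matrix(inv[s$graph$edges], ncol = 2)
    remap <- t(apply(remap, 1, sort))
    s2$graph$edges <- remap[order(remap[, 1], remap[, 2]), , drop = FALSE]
    storage.mode(s2$graph$edges) <- "integer"
    expect_equal(model_forward(s2, p, cfg), model_forward(s, p, cfg),
                 tolerance = 1e-5)
  }
})

test_that("evaluation-mode forward is bitwise deterministic", {
  cfg <- tiny_model_config()
  s <- make_toy_sample(4)
  p <- init_params(cfg, seed = 6)
  set.seed(1); a <- model_forward(s, p, cfg)
  set.seed(999); b <- model_forward(s, p, cfg)
  expect_identical(a, b)
})

test_that("encoder-decoder mode runs and differs from encoder-only", {
  cfg_e <- tiny_model_config()
  cfg_d <- tiny_model_config(temporal_mode = "encoder_decoder")
  s <- make_toy_sample(4)
  pe <- init_params(cfg_e, seed = 7)
  pd <- init_params(cfg_d, seed = 7)
  le <- model_forward(s, pe, cfg_e)
  ld <- model_forward(s, pd, cfg_d)
  expect_true(all(is.finite(ld)))
  expect_false(isTRUE(all.equal(le, ld)))
})

test_that("temporal attention rows are probability vectors across random configs", {
  set.seed(27)
  for (i in 1:5) {
    cfg <- model_config(n_channels = 6, window_samples = 10,
                        d_model = sample(c(4, 8), 1),
                        n_heads_temporal = 2,
                        n_transformer_layers = sample(1:2, 1), d_ff = 6,
                        d_node = 4, sage_hidden = 4, gcn_hidden = 4,
                        gat_heads = 2, gat_head_dim = 3, dropout = 0)
    p <- init_params(cfg, seed = i)
    X <- matrix(rnorm(10 * 3), 10, 3)
    tf <- aadgraph:::.temporal_fwd(X, c(1L, 2L, 4L), p, cfg)
    for (lc in tf$layers)
      for (aw in lc$mha$aw) {
        expect_equal(rowSums(aw), rep(1, 10), tolerance = 1e-6)
        expect_true(all(aw >= 0))
      }
  }
})

test_that("checkpoints round-trip and reject architecture mismatches", {
  d <- withr::local_tempdir()
  path <- file.path(d, "ckpt.json")
  cfg <- tiny_model_config()
  p <- init_params(cfg, seed = 8)
  save_checkpoint(p, cfg, path)
  back <- load_checkpoint(path, expected_config = cfg)
  expect_equal(back$params, p, tolerance = 1e-15)
  s <- make_toy_sample(4)
  expect_equal(model_forward(s, back$params, cfg),
               model_forward(s, p, cfg))
  cfg2 <- tiny_model_config()
  cfg2$d_model <- 8L
  expect_error(load_checkpoint(path, expected_config = cfg2), "mismatch")
})
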