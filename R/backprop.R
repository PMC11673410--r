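# Analytic reverse-mode gradients for the full model.  Each section
# mirrors the corresponding forward cache in model.R; correctness is
# guarded by the finite-difference gradient check in the test suite.
# crossprod/tcrossprod are used instead of explicit transposes in the
# hot path.

.layernorm_bwd <- function(dy, ln, g) {
  dg <- colSums(dy * ln$xhat)
  db <- colSums(dy)
  dxhat <- dy * matrix(g, nrow(dy), length(g), byrow = TRUE)
  rm1 <- rowMeans(dxhat)
  rm2 <- rowMeans(dxhat * ln$xhat)
  dr <- (dxhat - rm1 - ln$xhat * rm2) * ln$inv
  list(dr = dr, dg = dg, db = db)
}

.mha_bwd <- function(dm, mha, p, pre, n_heads, acc) {
  d <- ncol(mha$x)
  dk <- d %/% n_heads
  acc(paste0(pre, "wo"), crossprod(mha$o, dm))
  acc(paste0(pre, "bo"), colSums(dm))
  do_ <- tcrossprod(dm, p[[paste0(pre, "wo")]])
  dq <- matrix(0, nrow(mha$x), d)
  dk_ <- matrix(0, nrow(mha$x), d)
  dv <- matrix(0, nrow(mha$x), d)
  for (h in seq_len(n_heads)) {
    hh <- ((h - 1) * dk + 1):(h * dk)
    aw <- mha$aw[[h]]
    da <- tcrossprod(do_[, hh, drop = FALSE], mha$v[, hh, drop = FALSE])
    dv[, hh] <- crossprod(aw, do_[, hh, drop = FALSE])
    ds <- .softmax_rows_bwd(aw, da)
    dq[, hh] <- ds %*% mha$k[, hh, drop = FALSE] / sqrt(dk)
    dk_[, hh] <- crossprod(ds, mha$q[, hh, drop = FALSE]) / sqrt(dk)
  }
  acc(paste0(pre, "wq"), crossprod(mha$x, dq))
  acc(paste0(pre, "wk"), crossprod(mha$x, dk_))
  acc(paste0(pre, "wv"), crossprod(mha$x, dv))
  acc(paste0(pre, "bq"), colSums(dq))
  acc(paste0(pre, "bk"), colSums(dk_))
  acc(paste0(pre, "bv"), colSums(dv))
  tcrossprod(dq, p[[paste0(pre, "wq")]]) +
    tcrossprod(dk_, p[[paste0(pre, "wk")]]) +
    tcrossprod(dv, p[[paste0(pre, "wv")]])
}

.encoder_layer_bwd <- function(dy, lc, p, pre, cfg, acc) {
  l2 <- .layernorm_bwd(dy, lc$ln2, p[[paste0(pre, "ln2_g")]])
  acc(paste0(pre, "ln2_g"), l2$dg)
  acc(paste0(pre, "ln2_b"), l2$db)
  dr2 <- l2$dr
  df2 <- dr2
  acc(paste0(pre, "fw2"), crossprod(lc$f1, df2))
  acc(paste0(pre, "fb2"), colSums(df2))
  df1 <- tcrossprod(df2, p[[paste0(pre, "fw2")]])
  dpre1 <- df1 * .lrelu_grad(lc$pre1, cfg$negative_slope)
  acc(paste0(pre, "fw1"), crossprod(lc$ln1$y, dpre1))
  acc(paste0(pre, "fb1"), colSums(dpre1))
  dln1y <- dr2 + tcrossprod(dpre1, p[[paste0(pre, "fw1")]])
  l1 <- .layernorm_bwd(dln1y, lc$ln1, p[[paste0(pre, "ln1_g")]])
  acc(paste0(pre, "ln1_g"), l1$dg)
  acc(paste0(pre, "ln1_b"), l1$db)
  dr1 <- l1$dr
  dr1 + .mha_bwd(dr1, lc$mha, p, pre, cfg$n_heads_temporal, acc)
}

.decoder_bwd <- function(dzo, dec, z_enc, p, cfg, acc) {
  nh <- cfg$n_heads_temporal
  d <- cfg$d_model
  dk <- d %/% nh
  dz <- dzo                                 # residual path into encoder z
  dc2 <- matrix(colSums(dzo), 1, d)         # broadcast row
  l2 <- .layernorm_bwd(dc2, dec$ln2, p$dec_ln2_g)
  acc("dec_ln2_g", l2$dg); acc("dec_ln2_b", l2$db)
  dr2 <- l2$dr
  acc("dec_fw2", crossprod(dec$f1, dr2))
  acc("dec_fb2", colSums(dr2))
  df1 <- tcrossprod(dr2, p$dec_fw2)
  dpre1 <- df1 * .lrelu_grad(dec$pre1, cfg$negative_slope)
  acc("dec_fw1", crossprod(dec$ln1$y, dpre1))
  acc("dec_fb1", colSums(dpre1))
  dln1y <- dr2 + tcrossprod(dpre1, p$dec_fw1)
  l1 <- .layernorm_bwd(dln1y, dec$ln1, p$dec_ln1_g)
  acc("dec_ln1_g", l1$dg); acc("dec_ln1_b", l1$db)
  dr1 <- l1$dr
  dq0 <- dr1
  dc0 <- dr1
  acc("dec_wo", crossprod(dec$o, dc0))
  acc("dec_bo", colSums(dc0))
  do_ <- tcrossprod(dc0, p$dec_wo)
  dq <- matrix(0, 1, d)
  dkz <- matrix(0, nrow(z_enc), d)
  dvz <- matrix(0, nrow(z_enc), d)
  for (h in seq_len(nh)) {
    hh <- ((h - 1) * dk + 1):(h * dk)
    aw <- dec$aw[[h]]
    da <- tcrossprod(do_[, hh, drop = FALSE], dec$vz[, hh, drop = FALSE])
    dvz[, hh] <- crossprod(aw, do_[, hh, drop = FALSE])
    ds <- .softmax_rows_bwd(aw, da)
    dq[, hh] <- ds %*% dec$kz[, hh, drop = FALSE] / sqrt(dk)
    dkz[, hh] <- crossprod(ds, dec$q[, hh, drop = FALSE]) / sqrt(dk)
  }
  acc("dec_wq", crossprod(p$dec_query, dq))
  acc("dec_wk", crossprod(z_enc, dkz))
  acc("dec_wv", crossprod(z_enc, dvz))
  dq0 <- dq0 + tcrossprod(dq, p$dec_wq)
  acc("dec_query", dq0)
  dz + tcrossprod(dkz, p$dec_wk) + tcrossprod(dvz, p$dec_wv)
}

.gat_head_bwd <- function(dout, hc, h_in, w, a, slope, acc, wname, aname) {
  dh <- ncol(w)
  dalpha <- tcrossprod(dout, hc$xw)
  dxw <- crossprod(hc$alpha, dout)
  de <- .softmax_rows_bwd(hc$alpha, dalpha)
  de <- de * .lrelu_grad(hc$e_raw, slope)
  ds <- rowSums(de)
  dt_ <- colSums(de)
  a1 <- a[seq_len(dh)]
  a2 <- a[dh + seq_len(dh)]
  dxw <- dxw + outer(ds, a1) + outer(dt_, a2)
  acc(aname, c(drop(crossprod(hc$xw, ds)), drop(crossprod(hc$xw, dt_))))
  acc(wname, crossprod(h_in, dxw))
  tcrossprod(dxw, w)
}

.spatial_bwd <- function(dpooled, sp, prep, p, cfg, acc) {
  slope <- cfg$negative_slope
  n <- nrow(sp$h_final)
  dh <- outer(rep(1 / n, n), dpooled)       # mean-pool backward
  for (l in rev(seq_len(cfg$n_gat_layers))) {
    lc <- sp$gat[[l]]
    dsummed <- dh * .lrelu_grad(lc$summed, slope)
    dh_in <- matrix(0, n, ncol(lc$h_in))
    for (k in seq_len(cfg$gat_heads)) {
      pre <- paste0("gat", l, "_h", k, "_")
      dout_k <- if (lc$final) dsummed / cfg$gat_heads
                else dsummed[, ((k - 1) * cfg$gat_head_dim + 1):
                                 (k * cfg$gat_head_dim), drop = FALSE]
      dh_in <- dh_in + .gat_head_bwd(dout_k, lc$heads[[k]], lc$h_in,
                                     p[[paste0(pre, "w")]],
                                     p[[paste0(pre, "a")]], slope, acc,
                                     paste0(pre, "w"), paste0(pre, "a"))
    }
    dh <- dh_in
  }
  dlin <- dh * .lrelu_grad(sp$gcn_lin, slope)
  acc("gcn_w", crossprod(sp$u, dlin))
  acc("gcn_b", colSums(dlin))
  dh <- crossprod(prep$sadj, tcrossprod(dlin, p$gcn_w))
  for (l in rev(seq_len(cfg$n_sage_layers))) {
    lc <- sp$sage[[l]]
    pre <- paste0("sage", l, "_")
    dlin <- dh * .lrelu_grad(lc$lin, slope)
    acc(paste0(pre, "w1"), crossprod(lc$h_in, dlin))
    acc(paste0(pre, "w2"), crossprod(lc$agg, dlin))
    acc(paste0(pre, "b"), colSums(dlin))
    dh <- tcrossprod(dlin, p[[paste0(pre, "w1")]]) +
      crossprod(prep$madj, tcrossprod(dlin, p[[paste0(pre, "w2")]]))
  }
  dh  # gradient at the node features h0
}

.temporal_bwd <- function(dh0, tf, p, cfg, acc) {
  acc("wnode", crossprod(tf$series, dh0))
  acc("bnode", colSums(dh0))
  dy <- t(tcrossprod(dh0, p$wnode))
  midx <- tf$midx
  dwout <- matrix(0, cfg$d_model, cfg$n_channels)
  dwout[, midx] <- crossprod(tf$z, dy)
  acc("wout", dwout)
  dz <- tcrossprod(dy, p$wout[, midx, drop = FALSE])
  if (!is.null(tf$dec)) {
    z_enc <- tf$layers[[cfg$n_transformer_layers]]$y
    dz <- .decoder_bwd(dz, tf$dec, z_enc, p, cfg, acc)
  }
  for (l in rev(seq_len(cfg$n_transformer_layers)))
    dz <- .encoder_layer_bwd(dz, tf$layers[[l]], p, paste0("enc", l, "_"),
                             cfg, acc)
  dwin <- matrix(0, cfg$n_channels, cfg$d_model)
  dwin[midx, ] <- crossprod(tf$xin, dz)
  acc("win", dwin)
  invisible(NULL)
}

# forward + backward for one sample; returns loss, prediction and grads
.loss_grad_sample <- function(prep, p, cfg, dropmask = NULL) {
  fwd <- .model_fwd(prep, p, cfg, dropmask)
  logits <- fwd$logits
  m <- max(logits)
  probs <- exp(logits - m) / sum(exp(logits - m))
  y1 <- prep$y + 1L
  loss <- -log(max(probs[y1], 1e-12))
  dlogits <- probs
  dlogits[y1] <- dlogits[y1] - 1
  grads <- new.env(parent = emptyenv())
  acc <- function(nm, v) {
    cur <- grads[[nm]]
    grads[[nm]] <- if (is.null(cur)) v else cur + v
  }
  acc("cls_w", outer(fwd$pooled_dropped, dlogits))
  acc("cls_b", dlogits)
  dpooled <- drop(p$cls_w %*% dlogits)
  if (!is.null(dropmask)) dpooled <- dpooled * dropmask
  dh0 <- .spatial_bwd(dpooled, fwd$sp, prep, p, cfg, acc)
  .temporal_bwd(dh0, fwd$tf, p, cfg, acc)
  list(loss = loss, pred = which.max(logits) - 1L,
       grads = as.list(grads))
}

# elementwise sum of two gradient lists
.add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]]
                                  else a[[nm]] + b[[nm]]
  a
}
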