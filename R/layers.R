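# Core numeric helpers shared by the exported layer ops and the trainer.

.softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

.softmax_rows_bwd <- function(a, da) {
  a * (da - rowSums(da * a))
}

.lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

.lrelu_grad <- function(x, slope) {
  1 + (slope - 1) * (x < 0)
}

# row-normalized adjacency for neighbor-mean aggregation (zero row for
# isolated nodes: the empty-neighborhood mean is the zero vector)
.mean_adjacency <- function(a) {
  deg <- rowSums(a)
  a / ifelse(deg == 0, 1, deg)
}

# symmetric renormalization D^-1/2 (A + I) D^-1/2 with self-loops
.norm_adjacency <- function(a) {
  at <- a + diag(nrow(a))
  d <- rowSums(at)
  stopifnot(all(d > 0))  # impossible to violate after self-loops
  dm <- 1 / sqrt(d)
  at * outer(dm, dm)
}

.edges_to_adjacency <- function(edges, n) {
  a <- matrix(0, n, n)
  if (nrow(edges)) {
    a[edges] <- 1
    a[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  a
}

#' Leaky rectified linear unit
#'
#' Elementwise piecewise-linear activation: `x` for `x >= 0` (the
#' boundary `x = 0` belongs to the non-negative branch),
#' `negative_slope * x` otherwise.
#'
#' @param x numeric vector, matrix or array.
#' @param negative_slope slope of the negative branch (default 0.01).
#' @return object of the same shape as `x`.
#' @examples
#' leaky_relu(c(3, -2, 0), 0.01)  # 3, -0.02, 0
#' @export
leaky_relu <- function(x, negative_slope = 0.01) {
  .lrelu(x, negative_slope)
}

#' Scaled dot-product attention
#'
#' `output = softmax(Q K' / sqrt(d_k)) V`, the similarity-weighted sum at
#' the heart of every self-attention layer.  The row-stochastic weight
#' matrix is returned alongside the output so tests can assert the
#' probability-simplex property directly.
#'
#' @param Q,K,V numeric matrices; `Q` is queries x `d_k`, `K` is keys x
#'   `d_k`, `V` is keys x `d_v`.
#' @return list with `output` (queries x `d_v`) and `weights` (queries x
#'   keys, rows sum to 1).
#' @examples
#' q <- matrix(c(1, 0), 1); k <- diag(2); v <- matrix(c(1, 0), 2)
#' scaled_dot_attention(q, k, v)$weights  # ~ (0.6698, 0.3302)
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (anyNA(Q) || anyNA(K) || anyNA(V))
    stop("NaN/NA in attention inputs (scaled_dot_attention)")
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  d_k <- ncol(Q)
  w <- .softmax_rows(Q %*% t(K) / sqrt(d_k))
  list(output = w %*% V, weights = w)
}

#' GraphSAGE mean-aggregation layer
#'
#' Per node `i`: `x_i' = x_i W1 + mean_{j in N(i)} x_j W2` (row-vector
#' convention; `W1`, `W2` are input-dim x output-dim).  An empty
#' neighborhood contributes the zero vector.  This is the bare
#' aggregation rule; the model applies its activation separately.
#'
#' @param x node-feature matrix (nodes x features).
#' @param edges m x 2 integer matrix of undirected edges (`i < j`
#'   convention accepted; both directions are aggregated).  Edges form
#'   a set: duplicate rows are collapsed by the adjacency construction.
#' @param W1,W2 weight matrices (features x output).
#' @param b optional bias vector (length output).
#' @return updated node-feature matrix.
#' @export
sage_forward <- function(x, edges, W1, W2, b = NULL) {
  n <- nrow(x)
  if (nrow(edges) && max(edges) > n) stop("edge references unknown node")
  m <- .mean_adjacency(.edges_to_adjacency(edges, n))
  out <- x %*% W1 + (m %*% x) %*% W2
  if (!is.null(b)) out <- out + matrix(b, n, length(b), byrow = TRUE)
  out
}

#' Graph-convolution layer with renormalized adjacency
#'
#' `H' = sigma(D^-1/2 (A + I) D^-1/2 H W)`: self-loops are added to the
#' binary adjacency, the symmetric degree renormalization is applied,
#' features are linearly transformed and passed through the activation
#' (LeakyReLU by default).
#'
#' @param H node-feature matrix (nodes x features).
#' @param A binary symmetric zero-diagonal adjacency matrix.
#' @param W weight matrix (features x output).
#' @param negative_slope LeakyReLU slope.
#' @param activation `"leaky_relu"` (default) or `"identity"` to expose
#'   the pre-activation value.
#' @return updated node-feature matrix.
#' @export
gcn_forward <- function(H, A, W, negative_slope = 0.01,
                        activation = c("leaky_relu", "identity")) {
  activation <- match.arg(activation)
  stopifnot(nrow(A) == ncol(A), nrow(A) == nrow(H))
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (any(A != t(A))) stop("adjacency must be symmetric")
  s <- .norm_adjacency(A)
  out <- (s %*% H) %*% W
  if (activation == "leaky_relu") out <- .lrelu(out, negative_slope)
  out
}

#' Graph-attention coefficients
#'
#' Softmax-normalized attention weights over each node's neighborhood,
#' `alpha_ij = softmax_j(LeakyReLU(a' [W x_i || W x_j]))` with the
#' neighborhood taken as `N(i)` plus a self-loop (so every node keeps a
#' share of its own features and degree-1 graphs stay well-posed).  The
#' softmax is max-stabilized, which leaves the mathematical value
#' unchanged.
#'
#' @param x node-feature matrix (nodes x features).
#' @param edges m x 2 integer edge matrix (undirected).
#' @param a attention weight vector of length `2 * ncol(W)`; the first
#'   half scores the destination (`W x_i`), the second half the source
#'   (`W x_j`).
#' @param W linear transform (features x output).
#' @param negative_slope LeakyReLU slope used inside the score.
#' @return dense nodes x nodes matrix of coefficients; row `i` is zero
#'   outside `N(i) + self` and sums to 1.
#' @export
gat_coefficients <- function(x, edges, a, W, negative_slope = 0.01) {
  n <- nrow(x)
  dh <- ncol(W)
  if (length(a) != 2 * dh)
    stop("a must have length 2 * ncol(W) = ", 2 * dh)
  mask <- .edges_to_adjacency(edges, n) + diag(n) > 0
  xw <- x %*% W
  sc_dst <- drop(xw %*% a[seq_len(dh)])
  sc_src <- drop(xw %*% a[dh + seq_len(dh)])
  e <- .lrelu(outer(sc_dst, rep(1, n)) + outer(rep(1, n), sc_src),
              negative_slope)
  e[!mask] <- -Inf
  .softmax_rows(e)
}

#' Multi-head graph-attention layer
#'
#' Per head `k`: the attention-weighted neighbor sum
#' `sum_j alpha^k_ij W^k x_j` (neighborhood including a self-loop, as in
#' [gat_coefficients()]).  Hidden layers concatenate the `K` head
#' outputs; a final layer averages them.  With `K = 1` and identity
#' activation this is exactly the single-head attention update.
#'
#' @param x node-feature matrix (nodes x features).
#' @param edges m x 2 integer edge matrix.
#' @param params list of `K` head parameter lists, each with elements `W`
#'   (features x head width) and `a` (length `2 * head width`).
#' @param K number of heads (must equal `length(params)`).
#' @param mode `"concat"` (hidden layer) or `"average"` (final layer).
#' @param negative_slope LeakyReLU slope (scores and activation).
#' @param activation `"leaky_relu"` applies the activation per head
#'   before concatenation (or after averaging); `"identity"` returns the
#'   bare weighted sums.
#' @return node-feature matrix: nodes x `K * head width` for concat,
#'   nodes x head width for average.
#' @export
gat_forward <- function(x, edges, params, K = length(params),
                        mode = c("concat", "average"),
                        negative_slope = 0.01,
                        activation = c("leaky_relu", "identity")) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  if (K != length(params)) stop("K must match length(params)")
  heads <- lapply(params, function(p) {
    alpha <- gat_coefficients(x, edges, p$a, p$W, negative_slope)
    alpha %*% (x %*% p$W)
  })
  if (mode == "concat") {
    if (activation == "leaky_relu")
      heads <- lapply(heads, .lrelu, slope = negative_slope)
    do.call(cbind, heads)
  } else {
    out <- Reduce(`+`, heads) / K
    if (activation == "leaky_relu") out <- .lrelu(out, negative_slope)
    out
  }
}
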