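# Graph-convolution primitives: the symmetrically normalized adjacency
# operator, the ARMA recursion, the edge-conditioned message-passing layer,
# and global add pooling. Each trainable layer has a deliberately naive
# per-node loop twin (`*_reference`) kept free of vectorized shortcuts so the
# fast path can be checked against it.

#' Symmetrically normalized adjacency of a graph
#'
#' Computes `L = D^{-1/2} A D^{-1/2}` from the directed edge list (each
#' undirected bond contributing both directions) and its complement
#' `Ltilde = I - L`, the operator driving the ARMA recursion. Degree-zero
#' nodes get all-zero rows of `L` (the `0^{-1/2}` factor is taken as 0). No
#' self-loops are added; the recursion's skip term plays that role.
#'
#' @param edge_index m x 2 integer matrix of directed `(source, target)`
#'   pairs, 1-based.
#' @param n Number of nodes.
#' @return List of class `norm_adj` with dense matrices `L` and `Ltilde`.
#' @export
normalized_adjacency <- function(edge_index, n) {
  edge_index <- matrix(as.integer(edge_index), ncol = 2L)
  if (nrow(edge_index) && max(edge_index) > n) stopf("edge index exceeds n = %d", n)
  A <- matrix(0, n, n)
  if (nrow(edge_index)) {
    A[edge_index] <- 1
    A[edge_index[, c(2, 1), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- A * (dinv %o% dinv)
  structure(list(L = L, Ltilde = diag(n) - L), class = "norm_adj")
}

# Sparse Ltilde used by the model's hot path; identical values to
# normalized_adjacency()$Ltilde.
norm_adj_sparse <- function(edge_index, n) {
  edge_index <- matrix(as.integer(edge_index), ncol = 2L)
  if (!nrow(edge_index)) return(Matrix::Diagonal(n))
  und <- unique(rbind(edge_index, edge_index[, c(2, 1), drop = FALSE]))
  A <- Matrix::sparseMatrix(i = und[, 1], j = und[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Matrix::Diagonal(n) - Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

#' ARMA layer configuration
#'
#' @param K Number of parallel stacks (>= 1).
#' @param T Number of recursion steps per stack (>= 1).
#' @param d_in,d_out Input and output feature dimensions.
#' @param activation `"relu"` (default) or `"identity"`, applied at every
#'   recursion step; the final average over stacks is linear.
#' @return List of class `arma_config`.
#' @export
arma_config <- function(K = 3L, T = 5L, d_in, d_out = d_in,
                        activation = c("relu", "identity")) {
  if (!is_count(K, 1L) || !is_count(T, 1L)) stopf("K and T must be integers >= 1")
  structure(list(K = as.integer(K), T = as.integer(T), d_in = as.integer(d_in),
                 d_out = as.integer(d_out), activation = match.arg(activation)),
            class = "arma_config")
}

activation_fun <- function(label) {
  switch(label, relu = relu, identity = identity,
         stopf("unknown activation '%s'", label))
}

check_arma_shapes <- function(X, w, cfg) {
  if (ncol(X) != cfg$d_in) stopf("X has %d columns, config expects d_in = %d",
                                 ncol(X), cfg$d_in)
  if (length(w$W) != cfg$K || length(w$V) != cfg$K)
    stopf("weights must hold K = %d stacks", cfg$K)
  for (k in seq_len(cfg$K)) {
    if (length(w$W[[k]]) != cfg$T || length(w$V[[k]]) != cfg$T)
      stopf("stack %d must hold T = %d step matrices", k, cfg$T)
  }
}

#' ARMA graph-convolution forward pass
#'
#' Runs, in each of `K` parallel stacks, the recursion
#' `Xbar_{t+1} = sigma(Ltilde %*% Xbar_t %*% W[[k]][[t]] + X %*% V[[k]][[t]])`
#' for `t = 1..T`, starting from `Xbar_0 = X`, then averages the `K` final
#' states (the average itself is linear). Parameters are per-stack and
#' per-step (no weight sharing across steps).
#'
#' @param X n x d_in input feature matrix.
#' @param adj A `norm_adj` from [normalized_adjacency()] (or any list with an
#'   `Ltilde` matrix).
#' @param weights List with `W[[k]][[t]]` (d x d_out) and `V[[k]][[t]]`
#'   (d_in x d_out) matrices.
#' @param cfg An [arma_config()].
#' @return n x d_out output matrix.
#' @export
arma_forward <- function(X, adj, weights, cfg) {
  check_arma_shapes(X, weights, cfg)
  sigma <- activation_fun(cfg$activation)
  Lt <- adj$Ltilde
  acc <- NULL
  for (k in seq_len(cfg$K)) {
    Xbar <- X
    for (t in seq_len(cfg$T)) {
      Z <- as.matrix(Lt %*% Xbar %*% weights$W[[k]][[t]]) + X %*% weights$V[[k]][[t]]
      Xbar <- sigma(Z)
    }
    acc <- if (is.null(acc)) Xbar else acc + Xbar
  }
  acc / cfg$K
}

#' Per-node loop reference for [arma_forward()]
#'
#' Same recursion computed entry by entry with explicit loops and no
#' vectorized shortcuts; used only as a test oracle.
#'
#' @inheritParams arma_forward
#' @return n x d_out output matrix.
#' @export
arma_reference <- function(X, adj, weights, cfg) {
  check_arma_shapes(X, weights, cfg)
  sigma <- activation_fun(cfg$activation)
  Lt <- as.matrix(adj$Ltilde)
  n <- nrow(X)
  acc <- matrix(0, n, cfg$d_out)
  for (k in seq_len(cfg$K)) {
    Xbar <- X
    for (t in seq_len(cfg$T)) {
      W <- weights$W[[k]][[t]]; V <- weights$V[[k]][[t]]
      Znew <- matrix(0, n, cfg$d_out)
      for (i in seq_len(n)) {
        for (c in seq_len(cfg$d_out)) {
          s <- 0
          for (j in seq_len(n)) {
            if (Lt[i, j] != 0) {
              for (a in seq_len(ncol(Xbar))) s <- s + Lt[i, j] * Xbar[j, a] * W[a, c]
            }
          }
          for (a in seq_len(ncol(X))) s <- s + X[i, a] * V[a, c]
          Znew[i, c] <- s
        }
      }
      Xbar <- sigma(Znew)
    }
    acc <- acc + Xbar
  }
  acc / cfg$K
}

#' Create an edge network
#'
#' The small dense map from a 6-dimensional bond feature vector to a `d x d`
#' matrix that conditions the message-passing layer: one hidden layer of
#' width `hidden` with ReLU, then a linear map to `d * d` values reshaped
#' column-major into the mixing matrix.
#'
#' @param d Node feature dimension the produced matrices act on.
#' @param hidden Hidden width (default 32).
#' @param seed Optional seed for Glorot-uniform initialization.
#' @return List of class `edge_network` with `W1` (6 x hidden), `b1`, `W2`
#'   (hidden x d^2), `b2` and `d`.
#' @export
edge_network <- function(d, hidden = 32L, seed = NULL) {
  init <- function() {
    list(W1 = glorot_matrix(6L, hidden), b1 = numeric(hidden),
         W2 = glorot_matrix(hidden, d * d), b2 = numeric(d * d), d = as.integer(d))
  }
  net <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(net, class = "edge_network")
}

# All per-edge d x d matrices, flattened column-major into an m x d^2 matrix.
edge_network_matrices <- function(net, E) {
  H <- relu(E %*% net$W1 + rep(net$b1, each = nrow(E)))
  list(Theta = H %*% net$W2 + rep(net$b2, each = nrow(E)), hidden = H)
}

#' Edge-conditioned message-passing forward pass
#'
#' For every node `i`, `x_i' = x_i + sum over incoming edges (j -> i) of
#' `Theta(e_ij) %*% x_j`, where `Theta(e_ij)` is the `d x d` matrix produced
#' by the edge network from the bond features. The self term passes through
#' untransformed; a node with no neighbours is returned unchanged.
#'
#' @param X n x d node feature matrix.
#' @param edge_index m x 2 integer matrix of directed `(source, target)`
#'   pairs.
#' @param E m x 6 edge feature matrix (one row per directed edge).
#' @param net An [edge_network()] with matching `d`.
#' @return n x d output matrix.
#' @export
edge_conv_forward <- function(X, edge_index, E, net) {
  d <- ncol(X)
  edge_index <- matrix(as.integer(edge_index), ncol = 2L)
  if (nrow(E) != nrow(edge_index)) stopf("edge feature rows (%d) != edge count (%d)",
                                         nrow(E), nrow(edge_index))
  if (net$d != d) stopf("edge network built for d = %d, node features have d = %d",
                        net$d, d)
  if (!nrow(edge_index)) return(X)
  Theta <- edge_network_matrices(net, E)$Theta
  src <- edge_index[, 1]; tgt <- edge_index[, 2]
  Xs <- X[src, , drop = FALSE]
  msg <- matrix(0, nrow(edge_index), d)
  for (b in seq_len(d)) {
    cols <- ((b - 1L) * d + 1L):(b * d)
    msg <- msg + Theta[, cols, drop = FALSE] * Xs[, b]
  }
  out <- X
  agg <- rowsum(msg, group = tgt)
  out[as.integer(rownames(agg)), ] <- out[as.integer(rownames(agg)), , drop = FALSE] + agg
  out
}

#' Per-node loop reference for [edge_conv_forward()]
#'
#' @inheritParams edge_conv_forward
#' @return n x d output matrix.
#' @export
edge_conv_reference <- function(X, edge_index, E, net) {
  d <- ncol(X)
  edge_index <- matrix(as.integer(edge_index), ncol = 2L)
  if (nrow(E) != nrow(edge_index)) stopf("edge feature rows (%d) != edge count (%d)",
                                         nrow(E), nrow(edge_index))
  out <- X
  for (i in seq_len(nrow(X))) {
    incoming <- which(edge_index[, 2] == i)
    for (e in incoming) {
      j <- edge_index[e, 1]
      # edge MLP, computed scalar by scalar
      h <- numeric(length(net$b1))
      for (q in seq_along(h)) {
        s <- net$b1[q]
        for (p in 1:6) s <- s + E[e, p] * net$W1[p, q]
        h[q] <- max(s, 0)
      }
      Theta <- matrix(0, d, d)
      for (col in seq_len(d * d)) {
        s <- net$b2[col]
        for (q in seq_along(h)) s <- s + h[q] * net$W2[q, col]
        Theta[col] <- s   # column-major fill matches the flattening convention
      }
      for (a in seq_len(d)) {
        s <- 0
        for (b in seq_len(d)) s <- s + Theta[a, b] * X[j, b]
        out[i, a] <- out[i, a] + s
      }
    }
  }
  out
}

#' Global add pooling
#'
#' Sums node feature rows per graph, producing one permutation-invariant
#' vector per graph in the batch.
#'
#' @param X n x d node feature matrix.
#' @param graph_id Integer vector (length n) assigning each node to a graph;
#'   ids must be contiguous (all nodes of a graph adjacent).
#' @return g x d matrix, one row per graph in order of first appearance.
#' @export
global_add_pool <- function(X, graph_id = rep(1L, nrow(X))) {
  if (length(graph_id) != nrow(X)) stopf("graph_id length must equal node count")
  out <- rowsum(X, group = graph_id, reorder = FALSE)
  dimnames(out) <- NULL
  out
}
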