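# The cascade network: linear embedding -> ARMA stacks -> edge-conditioned
# message passing -> global add pool -> dense head -> scalar pKa. Forward and
# analytic backward passes are implemented directly on base matrices (plus a
# sparse block-diagonal normalized adjacency), so the model runs and trains
# on a plain CPU with no deep-learning runtime.

#' Network configuration
#'
#' @param input_dim Raw atom feature width (75).
#' @param embed_dim Width `m1` of the linear embedding and of every hidden
#'   node representation (default 128).
#' @param arma_layers Recursion depth `T` of each ARMA stack (default 5).
#' @param arma_stacks Number `K` of parallel ARMA stacks (default 3). The
#'   stack count is a free hyperparameter of this architecture.
#' @param mpnn_layers Number of stacked edge-conditioned layers (default 1;
#'   0 skips the stage). Layers beyond the first repeat the same
#'   architecture with fresh parameters and a ReLU in between.
#' @param edge_hidden Hidden width of the edge network (default 32).
#' @param head_dims Widths of the dense head's hidden layers; default
#'   `embed_dim / 2`. The final linear map to a scalar is implicit.
#' @param activation Nonlinearity for the ARMA recursion and head
#'   (`"relu"`).
#' @param variant `"full"`, `"arma_only"` (message passing dropped) or
#'   `"mpnn_only"` (ARMA stage dropped) - the ablation switches.
#' @return List of class `apmnet_config`.
#' @export
apmnet_config <- function(input_dim = 75L, embed_dim = 128L, arma_layers = 5L,
                          arma_stacks = 3L, mpnn_layers = 1L, edge_hidden = 32L,
                          head_dims = NULL,
                          activation = c("relu", "identity"),
                          variant = c("full", "arma_only", "mpnn_only")) {
  variant <- match.arg(variant)
  activation <- match.arg(activation)
  if (!is_count(embed_dim, 1L)) stopf("embed_dim must be a positive integer")
  if (!is_count(arma_layers, 1L) || !is_count(arma_stacks, 1L))
    stopf("arma_layers and arma_stacks must be >= 1")
  if (!is_count(mpnn_layers, 0L)) stopf("mpnn_layers must be >= 0")
  if (is.null(head_dims)) head_dims <- max(as.integer(embed_dim / 2L), 1L)
  structure(list(input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 arma_layers = as.integer(arma_layers),
                 arma_stacks = as.integer(arma_stacks),
                 mpnn_layers = as.integer(mpnn_layers),
                 edge_hidden = as.integer(edge_hidden),
                 head_dims = as.integer(head_dims),
                 activation = activation, variant = variant),
            class = "apmnet_config")
}

use_arma <- function(cfg) cfg$variant != "mpnn_only"
use_mpnn <- function(cfg) cfg$variant != "arma_only" && cfg$mpnn_layers > 0L

# Glorot (Xavier) uniform draw: U(-a, a), a = sqrt(6 / (fan_in + fan_out)).
glorot_matrix <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

#' Initialize network parameters
#'
#' All weight matrices are Glorot-uniform, biases zero; the same seed always
#' reproduces the same parameter set. Stages excluded by the config variant
#' draw no parameters, so e.g. the `arma_only` variant and a `full` model
#' with `mpnn_layers = 0` get identical parameters from the same seed.
#'
#' @param cfg An [apmnet_config()].
#' @param seed Integer seed.
#' @return Nested list of class `apmnet_params`.
#' @export
init_params <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "apmnet_config"))
  m1 <- cfg$embed_dim
  with_seed(seed, {
    params <- list(embed = list(W = glorot_matrix(cfg$input_dim, m1),
                                b = numeric(m1)))
    if (use_arma(cfg)) {
      W <- V <- vector("list", cfg$arma_stacks)
      for (k in seq_len(cfg$arma_stacks)) {
        W[[k]] <- lapply(seq_len(cfg$arma_layers), function(t) glorot_matrix(m1, m1))
        V[[k]] <- lapply(seq_len(cfg$arma_layers), function(t) glorot_matrix(m1, m1))
      }
      params$arma <- list(W = W, V = V)
    }
    if (use_mpnn(cfg)) {
      params$mpnn <- lapply(seq_len(cfg$mpnn_layers), function(l) {
        list(W1 = glorot_matrix(6L, cfg$edge_hidden), b1 = numeric(cfg$edge_hidden),
             W2 = glorot_matrix(cfg$edge_hidden, m1 * m1), b2 = numeric(m1 * m1))
      })
    }
    dims <- c(m1, cfg$head_dims, 1L)
    params$head <- lapply(seq_len(length(dims) - 1L), function(j) {
      list(W = glorot_matrix(dims[j], dims[j + 1L]), b = numeric(dims[j + 1L]))
    })
    structure(params, class = "apmnet_params")
  })
}

# ---- batch assembly ----

as_molgraph <- function(x) {
  if (inherits(x, "complex_graph")) x$graph
  else if (inherits(x, "molgraph")) x
  else stopf("expected a complex_graph or molgraph")
}

# Precompute the per-graph pieces reused every epoch.
prep_graph <- function(x) {
  g <- as_molgraph(x)
  list(X = g$X, ei = g$edge_index, E = g$E, n = g$n,
       Lt = norm_adj_sparse(g$edge_index, g$n),
       label = if (inherits(x, "complex_graph")) x$label else NA_real_,
       id = if (inherits(x, "complex_graph")) x$id else "graph")
}

# Concatenate prepped graphs into one block-diagonal batch.
collate_batch <- function(preps) {
  ns <- vapply(preps, `[[`, 0L, "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  ei <- do.call(rbind, lapply(seq_along(preps), function(i) {
    e <- preps[[i]]$ei
    if (nrow(e)) e + offs[i] else e
  }))
  list(X = do.call(rbind, lapply(preps, `[[`, "X")),
       ei = ei,
       E = do.call(rbind, lapply(preps, `[[`, "E")),
       Lt = if (length(preps) == 1L) preps[[1L]]$Lt
            else Matrix::bdiag(lapply(preps, `[[`, "Lt")),
       graph_id = rep(seq_along(preps), ns),
       y = vapply(preps, `[[`, 0, "label"),
       n_graphs = length(preps))
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# ---- forward ----

# Core forward over a collated batch; keep = TRUE retains every intermediate
# needed by the backward pass.
forward_core <- function(params, cfg, batch, keep = FALSE) {
  if (ncol(batch$X) != cfg$input_dim)
    stopf("node features have %d columns, config expects %d",
          ncol(batch$X), cfg$input_dim)
  sigma <- activation_fun(cfg$activation)
  cache <- list(batch = batch)
  H0 <- add_bias(batch$X %*% params$embed$W, params$embed$b)
  cache$H0 <- H0

  if (use_arma(cfg)) {
    K <- cfg$arma_stacks; T <- cfg$arma_layers
    Lt <- batch$Lt
    stacks <- vector("list", K)
    acc <- NULL
    for (k in seq_len(K)) {
      Xbars <- vector("list", T + 1L)
      LtXs <- vector("list", T)
      Xbars[[1L]] <- H0
      for (t in seq_len(T)) {
        LtX <- as.matrix(Lt %*% Xbars[[t]])
        Z <- LtX %*% params$arma$W[[k]][[t]] + H0 %*% params$arma$V[[k]][[t]]
        Xbars[[t + 1L]] <- sigma(Z)
        LtXs[[t]] <- LtX
      }
      acc <- if (is.null(acc)) Xbars[[T + 1L]] else acc + Xbars[[T + 1L]]
      if (keep) stacks[[k]] <- list(Xbars = Xbars, LtXs = LtXs)
    }
    H <- acc / K
    if (keep) cache$arma <- stacks
  } else {
    H <- H0
  }
  cache$H1 <- H

  if (use_mpnn(cfg)) {
    m1 <- cfg$embed_dim
    src <- batch$ei[, 1]; tgt <- batch$ei[, 2]
    has_edges <- nrow(batch$ei) > 0L
    mp <- vector("list", cfg$mpnn_layers)
    for (l in seq_len(cfg$mpnn_layers)) {
      net <- params$mpnn[[l]]
      Hin <- H
      if (has_edges) {
        Eh <- relu(add_bias(batch$E %*% net$W1, net$b1))
        Theta <- add_bias(Eh %*% net$W2, net$b2)
        Xs <- Hin[src, , drop = FALSE]
        msg <- matrix(0, nrow(batch$ei), m1)
        for (b in seq_len(m1)) {
          cols <- ((b - 1L) * m1 + 1L):(b * m1)
          msg <- msg + Theta[, cols, drop = FALSE] * Xs[, b]
        }
        Hpre <- Hin
        agg <- rowsum(msg, group = tgt)
        ridx <- as.integer(rownames(agg))
        Hpre[ridx, ] <- Hpre[ridx, , drop = FALSE] + agg
      } else {
        Eh <- Theta <- NULL
        Hpre <- Hin
      }
      H <- if (l < cfg$mpnn_layers) sigma(Hpre) else Hpre
      if (keep) mp[[l]] <- list(Hin = Hin, Eh = Eh, Theta = Theta, Hpre = Hpre,
                                activated = l < cfg$mpnn_layers)
    }
    if (keep) cache$mpnn <- mp
  }

  G <- global_add_pool(H, batch$graph_id)
  cache$G <- G

  A <- G
  J <- length(params$head)
  if (keep) cache$head <- vector("list", J)
  for (j in seq_len(J)) {
    if (keep) cache$head[[j]]$A_in <- A
    Z <- add_bias(A %*% params$head[[j]]$W, params$head[[j]]$b)
    A <- if (j < J) sigma(Z) else Z
    if (keep) cache$head[[j]]$A_out <- A
  }
  pred <- as.vector(A)
  if (keep) list(pred = pred, cache = cache) else pred
}

#' Forward pass of the cascade network
#'
#' Scores a batch of complexes (or bare molecular graphs). Deterministic
#' given parameters; invariant to node permutations within each graph.
#'
#' @param graphs A single `complex_graph`/`molgraph` or a list of them.
#' @param params An `apmnet_params` set from [init_params()].
#' @param cfg The matching [apmnet_config()].
#' @param pooled If `TRUE`, also return the pooled graph-level
#'   representations (one row per graph) fed to the dense head.
#' @return Numeric vector of predicted pKa values, one per graph; with
#'   `pooled = TRUE`, a list with elements `pred` and `pooled`.
#' @export
apmnet_forward <- function(graphs, params, cfg, pooled = FALSE) {
  if (inherits(graphs, c("complex_graph", "molgraph"))) graphs <- list(graphs)
  batch <- collate_batch(lapply(graphs, prep_graph))
  if (!pooled) return(forward_core(params, cfg, batch))
  out <- forward_core(params, cfg, batch, keep = TRUE)
  list(pred = out$pred, pooled = out$cache$G)
}

# ---- backward ----

# Analytic gradients of a scalar loss with d loss / d pred = dpred.
# Returns a list shaped exactly like `params`.
backward_core <- function(params, cfg, out, dpred) {
  cache <- out$cache
  batch <- cache$batch
  grads <- list(embed = list(W = NULL, b = NULL))
  relu_mask <- function(act) act > 0

  # head
  dA <- matrix(dpred, ncol = 1L)
  J <- length(params$head)
  grads$head <- vector("list", J)
  for (j in rev(seq_len(J))) {
    A_in <- cache$head[[j]]$A_in
    dZ <- if (j < J) dA else dA
    if (j < J) dZ <- dA * relu_mask(cache$head[[j]]$A_out)
    grads$head[[j]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- dZ %*% t(params$head[[j]]$W)
  }
  dG <- dA

  # un-pool: every node of graph g receives that graph's pooled gradient row
  dH <- dG[batch$graph_id, , drop = FALSE]

  # message-passing stage
  if (use_mpnn(cfg)) {
    m1 <- cfg$embed_dim
    src <- batch$ei[, 1]; tgt <- batch$ei[, 2]
    has_edges <- nrow(batch$ei) > 0L
    grads$mpnn <- vector("list", cfg$mpnn_layers)
    for (l in rev(seq_len(cfg$mpnn_layers))) {
      st <- cache$mpnn[[l]]
      net <- params$mpnn[[l]]
      dHpre <- if (st$activated) dH * relu_mask(st$Hpre) else dH
      if (has_edges) {
        dmsg <- dHpre[tgt, , drop = FALSE]
        Xs <- st$Hin[src, , drop = FALSE]
        dTheta <- matrix(0, nrow(batch$ei), m1 * m1)
        dXs <- matrix(0, nrow(batch$ei), m1)
        for (b in seq_len(m1)) {
          cols <- ((b - 1L) * m1 + 1L):(b * m1)
          dTheta[, cols] <- dmsg * Xs[, b]
          dXs[, b] <- rowSums(st$Theta[, cols, drop = FALSE] * dmsg)
        }
        dW2 <- crossprod(st$Eh, dTheta); db2 <- colSums(dTheta)
        dEh <- dTheta %*% t(net$W2)
        dZh <- dEh * relu_mask(st$Eh)
        dW1 <- crossprod(batch$E, dZh); db1 <- colSums(dZh)
        dHin <- dHpre
        aggs <- rowsum(dXs, group = src)
        ridx <- as.integer(rownames(aggs))
        dHin[ridx, ] <- dHin[ridx, , drop = FALSE] + aggs
        grads$mpnn[[l]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
        dH <- dHin
      } else {
        grads$mpnn[[l]] <- list(W1 = matrix(0, 6L, cfg$edge_hidden),
                                b1 = numeric(cfg$edge_hidden),
                                W2 = matrix(0, cfg$edge_hidden, m1 * m1),
                                b2 = numeric(m1 * m1))
      }
    }
  }
  dH1 <- dH

  # ARMA stage
  H0 <- cache$H0
  if (use_arma(cfg)) {
    K <- cfg$arma_stacks; T <- cfg$arma_layers
    Lt <- batch$Lt
    dH0 <- matrix(0, nrow(H0), ncol(H0))
    gW <- gV <- vector("list", K)
    for (k in seq_len(K)) {
      st <- cache$arma[[k]]
      gW[[k]] <- vector("list", T); gV[[k]] <- vector("list", T)
      dXbar <- dH1 / K
      for (t in rev(seq_len(T))) {
        dZ <- dXbar * relu_mask_act(st$Xbars[[t + 1L]], cfg$activation)
        gW[[k]][[t]] <- crossprod(st$LtXs[[t]], dZ)
        gV[[k]][[t]] <- crossprod(H0, dZ)
        dH0 <- dH0 + dZ %*% t(params$arma$V[[k]][[t]])
        dXbar <- as.matrix(Matrix::t(Lt) %*% (dZ %*% t(params$arma$W[[k]][[t]])))
      }
      dH0 <- dH0 + dXbar   # Xbar_0 = H0
    }
    grads$arma <- list(W = gW, V = gV)
  } else {
    dH0 <- dH1
  }

  grads$embed <- list(W = crossprod(batch$X, dH0), b = colSums(dH0))
  # keep field order identical to params for leaf-wise arithmetic
  grads[names(params)]
}

relu_mask_act <- function(act, activation) {
  if (activation == "relu") act > 0 else array(TRUE, dim(act))
}

# Loss + gradients for one collated batch (training hot path).
loss_and_grads <- function(params, cfg, batch) {
  out <- forward_core(params, cfg, batch, keep = TRUE)
  r <- out$pred - batch$y
  loss <- smooth_l1(out$pred, batch$y)
  dpred <- ifelse(abs(r) < 1, r, sign(r)) / length(r)
  list(pred = out$pred, loss = loss,
       grads = backward_core(params, cfg, out, dpred))
}
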