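# Graph-convolution primitives against hand algebra and loop oracles.

test_that("normalized adjacency matches hand computations", {
  # two nodes, one bond: degrees 1,1 so L is the plain adjacency
  adj <- normalized_adjacency(rbind(c(1L, 2L), c(2L, 1L)), 2L)
  expect_equal(adj$L, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(adj$Ltilde, diag(2) - adj$L)
  # edgeless graph: L = 0, Ltilde = I
  e <- normalized_adjacency(matrix(integer(0), ncol = 2), 3L)
  expect_equal(e$L, matrix(0, 3, 3))
  expect_equal(e$Ltilde, diag(3))
  # path on 3 nodes: D = diag(1,2,1), L[1,2] = 1/sqrt(2)
  p <- normalized_adjacency(rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L)), 3L)
  expect_equal(p$L[1, 2], 1 / sqrt(2))
  expect_equal(p$L, t(p$L))
  # zero-degree node gets an all-zero row
  z <- normalized_adjacency(rbind(c(1L, 2L), c(2L, 1L)), 3L)
  expect_equal(z$L[3, ], numeric(3))
})

test_that("row sums of L are 1 for k-regular graphs and eigenvalues lie in [-1, 1]", {
  ring6 <- cbind(1:6, c(2:6, 1))
  ei <- rbind(ring6, ring6[, c(2, 1)])
  adj <- normalized_adjacency(ei, 6L)
  expect_equal(rowSums(adj$L), rep(1, 6), tolerance = 1e-12)
  for (s in 1:5) {
    g <- random_graph(8, 3, seed = 500 + s)
    if (!nrow(g$ei)) next
    ev <- eigen(normalized_adjacency(g$ei, g$n)$L, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
  # sparse and dense constructions agree
  g <- random_graph(9, 2, seed = 77)
  expect_equal(as.matrix(apmnet:::norm_adj_sparse(g$ei, g$n)),
               normalized_adjacency(g$ei, g$n)$Ltilde,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ARMA closed-form identities hold", {
  X <- matrix(rnorm(12), 4, 3)
  adj <- normalized_adjacency(matrix(integer(0), ncol = 2), 4L)
  cfg <- arma_config(K = 1, T = 1, d_in = 3, activation = "identity")
  wz <- list(W = list(list(matrix(0, 3, 3))), V = list(list(diag(3))))
  # edgeless graph, W = 0, V = I: the recursion is the identity
  expect_equal(arma_forward(X, adj, wz, cfg), X)
  # with the graph-term weight zeroed, the layer is the dense map sigma(X V)
  V <- matrix(rnorm(9), 3, 3)
  wv <- list(W = list(list(matrix(0, 3, 3))), V = list(list(V)))
  cfg_relu <- arma_config(K = 1, T = 1, d_in = 3, activation = "relu")
  expect_equal(arma_forward(X, adj, wv, cfg_relu), pmax(X %*% V, 0))
  # K = 2 with identical stacks equals K = 1
  w1 <- random_arma_weights(1, 3, 3, 3, seed = 9)
  w2 <- list(W = list(w1$W[[1]], w1$W[[1]]), V = list(w1$V[[1]], w1$V[[1]]))
  g <- random_graph(5, 3, seed = 10)
  adj5 <- normalized_adjacency(g$ei, 5L)
  expect_equal(
    arma_forward(g$X, adj5, w2, arma_config(K = 2, T = 3, d_in = 3)),
    arma_forward(g$X, adj5, w1, arma_config(K = 1, T = 3, d_in = 3)))
  # 3-node path, T = 1, identity activation: hand-expandable single step
  path_ei <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L))
  adj3 <- normalized_adjacency(path_ei, 3L)
  Xp <- matrix(rnorm(6), 3, 2)
  W <- matrix(rnorm(4), 2, 2); V2 <- matrix(rnorm(4), 2, 2)
  wp <- list(W = list(list(W)), V = list(list(V2)))
  expect_equal(
    arma_forward(Xp, adj3, wp, arma_config(K = 1, T = 1, d_in = 2, activation = "identity")),
    adj3$Ltilde %*% Xp %*% W + Xp %*% V2)
})

test_that("vectorized ARMA matches the per-node loop reference on random graphs", {
  for (s in 1:20) {
    n <- sample(3:12, 1)
    d <- sample(2:8, 1)
    g <- random_graph(n, d, seed = 1000 + s)
    K <- sample(1:3, 1); T <- sample(1:3, 1)
    w <- random_arma_weights(K, T, d, d, seed = 2000 + s)
    cfg <- arma_config(K = K, T = T, d_in = d)
    adj <- normalized_adjacency(g$ei, n)
    expect_lt(max_abs_diff(arma_forward(g$X, adj, w, cfg),
                           arma_reference(g$X, adj, w, cfg)), 1e-6)
  }
})

test_that("edge-conditioned convolution identities hold", {
  # isolated node: empty neighbour sum leaves the input untouched
  X <- matrix(rnorm(4), 1, 4)
  net <- edge_network(4, hidden = 3, seed = 1)
  expect_equal(edge_conv_forward(X, matrix(integer(0), ncol = 2),
                                 matrix(0, 0, 6), net), X)
  # two nodes, identity edge matrix: x1' = x1 + x2
  X2 <- matrix(rnorm(8), 2, 4)
  ei <- rbind(c(1L, 2L), c(2L, 1L))
  E <- matrix(c(1, 0, 0, 0, 0, 0), 2, 6, byrow = TRUE)
  id_net <- constant_edge_network(diag(4))
  out <- edge_conv_forward(X2, ei, E, id_net)
  expect_equal(out[1, ], X2[1, ] + X2[2, ])
  expect_equal(out[2, ], X2[2, ] + X2[1, ])
  # zero edge matrix: layer is the identity
  zero_net <- constant_edge_network(matrix(0, 4, 4))
  expect_equal(edge_conv_forward(X2, ei, E, zero_net), X2)
  # star graph with identity matrices: centre collects the leaf sum
  Xs <- matrix(rnorm(20), 5, 4)
  star <- cbind(2:5, 1L)
  ei_s <- rbind(star, star[, c(2, 1)])
  Es <- matrix(rbinom(nrow(ei_s) * 6, 1, 0.5), nrow(ei_s), 6)
  outs <- edge_conv_forward(Xs, ei_s, Es, id_net)
  expect_equal(outs[1, ], Xs[1, ] + colSums(Xs[2:5, , drop = FALSE]))
})

test_that("vectorized edge convolution matches the loop reference on random graphs", {
  for (s in 1:20) {
    n <- sample(2:12, 1)
    d <- sample(2:6, 1)
    g <- random_graph(n, d, seed = 3000 + s)
    net <- edge_network(d, hidden = 4, seed = 4000 + s)
    expect_lt(max_abs_diff(edge_conv_forward(g$X, g$ei, g$E, net),
                           edge_conv_reference(g$X, g$ei, g$E, net)), 1e-6)
  }
  # mismatched edge features are rejected
  g <- random_graph(5, 3, seed = 1)
  net <- edge_network(3, seed = 2)
  expect_error(edge_conv_forward(g$X, g$ei, g$E[-1, , drop = FALSE], net), "edge")
})

test_that("both layers are permutation equivariant and pooling is invariant", {
  for (s in 1:6) {
    n <- 8; d <- 4
    g <- random_graph(n, d, seed = 5000 + s)
    perm <- sample(n)
    inv <- integer(n); inv[perm] <- seq_len(n)
    ei_p <- if (nrow(g$ei)) matrix(inv[g$ei], ncol = 2) else g$ei
    X_p <- g$X[perm, , drop = FALSE]

    w <- random_arma_weights(2, 2, d, d, seed = 6000 + s)
    cfg <- arma_config(K = 2, T = 2, d_in = d)
    out <- arma_forward(g$X, normalized_adjacency(g$ei, n), w, cfg)
    out_p <- arma_forward(X_p, normalized_adjacency(ei_p, n), w, cfg)
    expect_lt(max_abs_diff(out[perm, , drop = FALSE], out_p), 1e-6)

    net <- edge_network(d, hidden = 4, seed = 7000 + s)
    ec <- edge_conv_forward(g$X, g$ei, g$E, net)
    ec_p <- edge_conv_forward(X_p, ei_p, g$E, net)
    expect_lt(max_abs_diff(ec[perm, , drop = FALSE], ec_p), 1e-6)

    expect_lt(max_abs_diff(global_add_pool(ec), global_add_pool(ec_p)), 1e-6)
  }
})

test_that("global add pool sums rows per contiguous graph id", {
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(global_add_pool(X), matrix(c(4, 6), 1, 2))
  # batch of 3 graphs vs per-graph brute force
  set.seed(8)
  X3 <- matrix(rnorm(18), 9, 2)
  gid <- rep(1:3, times = c(2, 4, 3))
  pooled <- global_add_pool(X3, gid)
  for (g in 1:3)
    expect_equal(pooled[g, ], colSums(X3[gid == g, , drop = FALSE]))
  expect_error(global_add_pool(X3, 1:4), "length")
})
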