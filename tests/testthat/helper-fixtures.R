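# Shared in-code fixtures: tiny hand-built molecules and random graphs.

# A random undirected graph as a directed edge list (both directions),
# with random node features; n <= a dozen keeps reference oracles instant.
random_graph <- function(n, d, seed, p_edge = 0.35) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  ei <- rbind(keep, keep[, c(2, 1), drop = FALSE])
  if (!nrow(ei)) ei <- matrix(integer(0), ncol = 2)
  list(X = matrix(stats::rnorm(n * d), n, d),
       ei = matrix(as.integer(ei), ncol = 2),
       n = n, d = d,
       E = matrix(stats::rbinom(nrow(ei) * 6, 1, 0.4), nrow(ei), 6))
}

# Nested ARMA weight lists W[[k]][[t]], V[[k]][[t]].
random_arma_weights <- function(K, T, d_in, d_out, seed) {
  set.seed(seed)
  W <- V <- vector("list", K)
  for (k in seq_len(K)) {
    W[[k]] <- lapply(seq_len(T), function(t)
      matrix(stats::rnorm(d_out * d_out, sd = 0.5), d_out, d_out))
    V[[k]] <- lapply(seq_len(T), function(t)
      matrix(stats::rnorm(d_in * d_out, sd = 0.5), d_in, d_out))
  }
  # first recursion step multiplies Xbar_0 = X (d_in wide)
  for (k in seq_len(K))
    W[[k]][[1]] <- matrix(stats::rnorm(d_in * d_out, sd = 0.5), d_in, d_out)
  list(W = W, V = V)
}

# Constant edge network: every edge maps to the same d x d matrix M
# (hidden layer zeroed out, bias carries M).
constant_edge_network <- function(M, hidden = 4L) {
  d <- nrow(M)
  structure(list(W1 = matrix(0, 6, hidden), b1 = numeric(hidden),
                 W2 = matrix(0, hidden, d * d), b2 = as.vector(M),
                 d = d), class = "edge_network")
}

# Benzene: 6 aromatic SP2 carbons in a ring, all bonds aromatic + conjugated.
benzene <- function() {
  atoms <- lapply(1:6, function(i)
    atom_record("C", degree = 2L, explicit_valence = 4L, hybridization = "SP2",
                is_aromatic = TRUE, total_hydrogens = 1L))
  bonds <- lapply(1:6, function(i)
    bond_record(i, if (i < 6) i + 1L else 1L, order = "aromatic",
                is_conjugated = TRUE, is_in_ring = TRUE))
  molecule(atoms, bonds, id = "benzene")
}

# Linear chain of n SP3 carbons, single bonds.
carbon_chain <- function(n, id = "chain") {
  atoms <- lapply(seq_len(n), function(i) {
    deg <- if (n == 1) 0L else if (i == 1 || i == n) 1L else 2L
    atom_record("C", degree = deg, explicit_valence = 4L,
                total_hydrogens = 4L - deg)
  })
  bonds <- if (n > 1) lapply(seq_len(n - 1), function(i) bond_record(i, i + 1L))
           else list()
  molecule(atoms, bonds, id = id)
}

# Apply a node permutation to a molgraph: row i of the result is old node
# perm[i]; edges relabelled accordingly.
permute_molgraph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  ei <- g$edge_index
  if (nrow(ei)) ei <- matrix(inv[ei], ncol = 2)
  molgraph(g$X[perm, , drop = FALSE], ei, g$E)
}

tiny_model_cfg <- function(...) {
  args <- utils::modifyList(
    list(embed_dim = 6L, arma_layers = 2L, arma_stacks = 2L, mpnn_layers = 1L,
         edge_hidden = 5L, head_dims = 4L),
    list(...))
  do.call(apmnet_config, args)
}

tiny_complexes <- function(n, seed = 5, noise_sd = 0) {
  spec <- synthetic_spec(n_complexes = n, pocket_size_range = c(8L, 14L),
                         ligand_size_range = c(4L, 8L), noise_sd = noise_sd,
                         seed = seed)
  synthetic_dataset(spec)
}

max_abs_diff <- function(a, b) max(abs(a - b))
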