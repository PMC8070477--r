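# Molecular graphs: featurized node/edge matrices, the joint pocket-ligand
# complex graph, and a plain-JSON on-disk container for caching.

#' Convert a molecule to a featurized graph
#'
#' Stacks [featurize_atom()] rows into the node matrix `X` (n x 75) and emits
#' each undirected bond as two directed edges, `(i -> j)` and `(j -> i)`, that
#' share one [featurize_bond()] feature row. Storing both directions makes
#' the neighbour sums of the message-passing layer a single pass over
#' incoming edges.
#'
#' @param mol A [molecule()].
#' @return An object of class `molgraph`: list with `X` (n x 75 matrix),
#'   `edge_index` (m x 2 integer matrix of 1-based `(source, target)` pairs,
#'   `m = 2 *` bond count), `E` (m x 6 bond feature matrix) and `n`.
#' @export
mol_to_graph <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$atoms)
  if (n == 0L) stopf("molecule '%s' has no atoms; structure unusable", mol$id)
  X <- t(vapply(mol$atoms, featurize_atom, numeric(75L)))
  nb <- length(mol$bonds)
  ei <- matrix(0L, nrow = 2L * nb, ncol = 2L)
  E <- matrix(0, nrow = 2L * nb, ncol = 6L)
  for (k in seq_len(nb)) {
    b <- mol$bonds[[k]]
    f <- featurize_bond(b)
    ei[2L * k - 1L, ] <- c(b$i, b$j)
    ei[2L * k, ] <- c(b$j, b$i)
    E[2L * k - 1L, ] <- f
    E[2L * k, ] <- f
  }
  molgraph(X, ei, E)
}

#' Construct a molgraph from raw matrices
#'
#' Low-level constructor validating the graph container invariants; most code
#' should go through [mol_to_graph()].
#'
#' @param X Node feature matrix, one row per atom.
#' @param edge_index m x 2 integer matrix of directed `(source, target)`
#'   pairs, 1-based.
#' @param E m x 6 edge feature matrix.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(X, edge_index, E) {
  X <- as.matrix(X)
  edge_index <- matrix(as.integer(edge_index), ncol = 2L)
  E <- matrix(as.numeric(E), ncol = if (nrow(edge_index)) 6L else 6L,
              nrow = nrow(edge_index))
  if (ncol(X) != 75L) stopf("node feature matrix must have 75 columns, got %d", ncol(X))
  if (nrow(E) != nrow(edge_index)) stopf("edge feature rows must match edge count")
  if (nrow(edge_index) && (min(edge_index) < 1L || max(edge_index) > nrow(X)))
    stopf("edge indices out of range 1..%d", nrow(X))
  structure(list(X = X, edge_index = edge_index, E = E, n = nrow(X)),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d nodes, %d directed edges>\n", x$n, nrow(x$edge_index)))
  invisible(x)
}

#' Join a pocket graph and a ligand graph into a complex graph
#'
#' Row-concatenates the node matrices (pocket first), offsets the ligand edge
#' indices by the pocket size and concatenates the edge features. No edges
#' are added between the two molecules: non-covalent pocket-ligand contacts
#' are deliberately not part of the input, so a complex can be scored without
#' a bound 3D pose.
#'
#' @param pocket,ligand `molgraph` objects (both non-empty).
#' @param label Optional pKa label (unitless, -log10 of the molar affinity).
#' @param id Optional complex identifier.
#' @return An object of class `complex_graph`: list with `graph` (the joint
#'   `molgraph`), `n_pocket`, `n_ligand`, `label`, `id`.
#' @export
build_complex <- function(pocket, ligand, label = NULL, id = "complex") {
  stopifnot(inherits(pocket, "molgraph"), inherits(ligand, "molgraph"))
  if (pocket$n == 0L || ligand$n == 0L) stopf("pocket and ligand must be non-empty")
  X <- rbind(pocket$X, ligand$X)
  ei <- rbind(pocket$edge_index, ligand$edge_index + pocket$n)
  E <- rbind(pocket$E, ligand$E)
  structure(list(graph = molgraph(X, ei, E), n_pocket = pocket$n,
                 n_ligand = ligand$n,
                 label = if (is.null(label)) NA_real_ else as.numeric(label),
                 id = id),
            class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf("<complex_graph '%s': %d pocket + %d ligand atoms, label %s>\n",
              x$id, x$n_pocket, x$n_ligand,
              if (is.na(x$label)) "NA" else sprintf("%.3f", x$label)))
  invisible(x)
}

#' Convert an affinity measurement to pKa
#'
#' `pKa = -log10(K)` with `K` in molar units; applies to Kd, Ki or IC50
#' alike. 1 nM gives 9, 1 M gives 0.
#'
#' @param value Positive affinity value(s).
#' @param unit Unit of `value`: `"M"`, `"mM"`, `"uM"`, `"nM"` or `"pM"`.
#' @return Numeric pKa value(s).
#' @export
affinity_to_pka <- function(value, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value)) || any(value <= 0))
    stopf("affinity values must be positive and finite")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  -log10(value * scale)
}

#' Write a complex graph to a plain-JSON cache file
#'
#' The container stores the node matrix, directed edge list, edge feature
#' matrix, block sizes and label; [read_complex_graph()] restores it exactly.
#'
#' @param cg A `complex_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex_graph <- function(cg, path) {
  stopifnot(inherits(cg, "complex_graph"))
  obj <- list(id = cg$id, n_pocket = cg$n_pocket, n_ligand = cg$n_ligand,
              label = cg$label, X = cg$graph$X, edge_index = cg$graph$edge_index,
              E = cg$graph$E)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a complex graph written by [write_complex_graph()]
#'
#' @param path File path.
#' @return A `complex_graph`.
#' @export
read_complex_graph <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  ei <- obj$edge_index
  if (is.null(ei) || length(ei) == 0L) ei <- matrix(integer(0), ncol = 2L)
  g <- molgraph(obj$X, ei, matrix(unlist(obj$E), ncol = 6L, nrow = nrow(ei)))
  structure(list(graph = g, n_pocket = as.integer(obj$n_pocket),
                 n_ligand = as.integer(obj$n_ligand),
                 label = obj$label %||% NA_real_, id = obj$id),
            class = "complex_graph")
}
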