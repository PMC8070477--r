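# Synthetic study generator: random but chemically plausible molecules,
# pocket-ligand complexes with a planted affinity function, and a miniature
# PDBbind-layout fixture directory. This is what the test-bench trains on in
# place of the real database, so every piece of the pipeline is exercised
# without downloads.

MAX_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L,
                 I = 1L, P = 3L, B = 3L, Si = 4L)

#' Specification of a synthetic complex dataset
#'
#' The defaults define the package's reference synthetic study: pockets of
#' 16-30 heavy atoms, ligands of 6-14, a five-element alphabet, and additive
#' Gaussian label noise of 0.25 pKa (the order of experimental affinity
#' uncertainty). Pockets are far smaller than real binding pockets; the size
#' is a desk-scale choice, not a chemical claim.
#'
#' @param n_complexes Number of complexes.
#' @param pocket_size_range,ligand_size_range Inclusive atom-count ranges.
#' @param element_alphabet Subset of [atom_type_vocabulary()] to draw from.
#' @param noise_sd Gaussian noise on the planted label, in pKa units.
#' @param seed Base seed; every complex derives its own sub-seed from it.
#' @param planted `"composition"` (label linear in element counts) or
#'   `"topology"` (adds a ring-bond term so that only a bond-aware model can
#'   fit perfectly).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_complexes = 250L, pocket_size_range = c(16L, 30L),
                           ligand_size_range = c(6L, 14L),
                           element_alphabet = c("C", "N", "O", "S", "Cl"),
                           noise_sd = 0.25, seed = 42L,
                           planted = c("composition", "topology")) {
  if (any(pocket_size_range < 2L) || any(ligand_size_range < 2L))
    stopf("pocket and ligand sizes must be >= 2")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!all(element_alphabet %in% names(MAX_VALENCE)))
    stopf("element_alphabet limited to {%s}", paste(names(MAX_VALENCE), collapse = ","))
  structure(list(n_complexes = as.integer(n_complexes),
                 pocket_size_range = as.integer(pocket_size_range),
                 ligand_size_range = as.integer(ligand_size_range),
                 element_alphabet = element_alphabet, noise_sd = noise_sd,
                 seed = as.integer(seed), planted = match.arg(planted)),
            class = "synthetic_spec")
}

#' Planted affinity function parameters
#'
#' The ground-truth label of a synthetic complex is
#' `b + sum over atoms of w[element]` (plus `ring_coef` per ring bond for the
#' topology variant), clipped to the 0-14 pKa range. The constants are fixed
#' and published here so an independent re-count of a complex's composition
#' reproduces its noise-free label exactly.
#'
#' @return List with `w` (named per-element weights), `b` (intercept) and
#'   `ring_coef`.
#' @export
planted_affinity_params <- function() {
  list(w = c(C = 0.06, N = 0.16, O = 0.13, S = 0.32, Cl = 0.22,
             F = 0.18, Br = 0.20, I = 0.20, P = 0.25, B = 0.15, Si = 0.10),
       b = 1.5, ring_coef = 0.25)
}

planted_label <- function(pocket_mol, ligand_mol, planted = "composition") {
  pp <- planted_affinity_params()
  els <- c(vapply(pocket_mol$atoms, `[[`, "", "element"),
           vapply(ligand_mol$atoms, `[[`, "", "element"))
  lab <- pp$b + sum(pp$w[els])
  if (planted == "topology") {
    nring <- sum(vapply(c(pocket_mol$bonds, ligand_mol$bonds),
                        `[[`, FALSE, "is_in_ring"))
    lab <- lab + pp$ring_coef * nring
  }
  lab
}

#' Generate a random, chemically plausible molecule
#'
#' Builds a connected graph (a random spanning tree plus a few extra edges,
#' all degrees capped at 4), then assigns each atom an element from the
#' alphabet whose maximum valence accommodates its degree. All bonds are
#' single; hydrogens fill the remaining valence, so every generated atom
#' featurizes inside the one-hot bins without clamping.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param alphabet Candidate element symbols.
#' @param seed Optional seed; the caller's RNG stream is left untouched when
#'   given.
#' @return A [molecule()].
#' @export
make_random_molecule <- function(n_atoms, alphabet = c("C", "N", "O", "S", "Cl"),
                                 seed = NULL) {
  if (!is_count(n_atoms, 1L)) stopf("n_atoms must be >= 1")
  gen <- function() {
    deg <- integer(n_atoms)
    pairs <- list()
    adjacent <- function(i, j) {
      any(vapply(pairs, function(p) all(p == c(min(i, j), max(i, j))), FALSE))
    }
    for (i in seq_len(n_atoms)[-1]) {
      open <- which(deg[seq_len(i - 1L)] < 4L)
      parent <- if (length(open) == 1L) open else sample(open, 1L)
      pairs[[length(pairs) + 1L]] <- c(min(parent, i), max(parent, i))
      deg[c(parent, i)] <- deg[c(parent, i)] + 1L
    }
    n_extra <- if (n_atoms >= 6L) stats::rbinom(1L, n_atoms %/% 5L, 0.7) else 0L
    for (e in seq_len(n_extra)) {
      open <- which(deg < 4L)
      if (length(open) < 2L) break
      ij <- sample(open, 2L)
      if (!adjacent(ij[1], ij[2])) {
        pairs[[length(pairs) + 1L]] <- sort(ij)
        deg[ij] <- deg[ij] + 1L
      }
    }
    elements <- character(n_atoms)
    for (a in seq_len(n_atoms)) {
      ok <- alphabet[MAX_VALENCE[alphabet] >= max(deg[a], 1L)]
      elements[a] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    btab <- if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      data.frame(i = pm[, 1], j = pm[, 2], order = "single", stringsAsFactors = FALSE)
    } else empty_bonds()
    in_ring <- ring_bond_flags(n_atoms, btab)
    atoms <- lapply(seq_len(n_atoms), function(a) {
      mv <- MAX_VALENCE[[elements[a]]]
      atom_record(elements[a], degree = deg[a], explicit_valence = mv,
                  formal_charge = 0L, num_radical_electrons = 0L,
                  hybridization = "SP3", is_aromatic = FALSE,
                  total_hydrogens = mv - deg[a])
    })
    bonds <- lapply(seq_len(nrow(btab)), function(k)
      bond_record(btab$i[k], btab$j[k], order = "single",
                  is_conjugated = FALSE, is_in_ring = in_ring[k]))
    molecule(atoms, bonds, id = sprintf("rand%d", n_atoms))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

complex_seed <- function(spec, index) {
  (abs(spec$seed) %% 1000003L) * 2001L + 17L * index
}

make_synthetic_pair <- function(spec, index) {
  with_seed(complex_seed(spec, index), {
    np <- sample(seq(spec$pocket_size_range[1], spec$pocket_size_range[2]), 1L)
    nl <- sample(seq(spec$ligand_size_range[1], spec$ligand_size_range[2]), 1L)
    pocket <- make_random_molecule(np, spec$element_alphabet)
    ligand <- make_random_molecule(nl, spec$element_alphabet)
    id <- sprintf("syn%04d", index)
    pocket$id <- paste0(id, "_pocket"); ligand$id <- paste0(id, "_ligand")
    lab <- planted_label(pocket, ligand, spec$planted)
    if (spec$noise_sd > 0) lab <- lab + stats::rnorm(1L, 0, spec$noise_sd)
    list(pocket = pocket, ligand = ligand, id = id,
         label = min(max(lab, 0), 14))
  })
}

#' Generate one synthetic pocket-ligand complex
#'
#' @param spec A [synthetic_spec()].
#' @param index 1-based complex index; together with the spec seed it fully
#'   determines the complex.
#' @return A labelled `complex_graph`.
#' @export
make_synthetic_complex <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- make_synthetic_pair(spec, index)
  build_complex(mol_to_graph(p$pocket), mol_to_graph(p$ligand),
                label = p$label, id = p$id)
}

#' Generate a full synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List of `spec$n_complexes` labelled `complex_graph` objects.
#' @export
synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lapply(seq_len(spec$n_complexes), function(i) make_synthetic_complex(spec, i))
}

#' Write a miniature PDBbind-layout fixture directory
#'
#' Creates one subdirectory per complex holding `<id>_pocket.pdb` (with
#' CONECT records) and `<id>_ligand.sdf` (or `.mol2`), plus a PDBbind-style
#' index file `INDEX_synthetic.data` whose affinity strings (`Kd=...`)
#' round-trip to each complex's planted pKa label. Ids listed in
#' `corrupt_ids` get a deliberately unparseable ligand file so the
#' assembly-time discard rule can be exercised.
#'
#' @param dir Target directory (created if missing).
#' @param spec A [synthetic_spec()].
#' @param ligand_format `"sdf"` or `"mol2"`.
#' @param corrupt_ids Complex ids to corrupt.
#' @return The index file path, invisibly.
#' @export
write_mini_pdbbind <- function(dir, spec, ligand_format = c("sdf", "mol2"),
                               corrupt_ids = character(0)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ligand_format <- match.arg(ligand_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mult <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  rows <- character(spec$n_complexes)
  for (i in seq_len(spec$n_complexes)) {
    p <- make_synthetic_pair(spec, i)
    cdir <- file.path(dir, p$id)
    dir.create(cdir, showWarnings = FALSE)
    write_pdb_molecule(p$pocket, file.path(cdir, paste0(p$id, "_pocket.pdb")))
    lig_path <- file.path(cdir, paste0(p$id, "_ligand.", ligand_format))
    if (p$id %in% corrupt_ids) {
      writeLines(c("this is not a structure file", "@@corrupt@@"), lig_path)
    } else if (ligand_format == "sdf") {
      write_sdf_molecule(p$ligand, lig_path)
    } else {
      write_mol2_molecule(p$ligand, lig_path)
    }
    kd <- 10^(-p$label)
    unit <- names(mult)[max(which(kd / unlist(mult) >= 1), 1L)]
    if (kd / mult[[unit]] < 1 && unit == "M") unit <- "pM"
    rows[i] <- sprintf("%s  2.00  2020  %.6f  Kd=%.8g%s", p$id, p$label,
                       kd / mult[[unit]], unit)
  }
  index_path <- file.path(dir, "INDEX_synthetic.data")
  writeLines(c("# Synthetic PDBbind-style index", "# id resolution year -logKd/Ki Kd",
               rows), index_path)
  invisible(index_path)
}

#' Assemble a dataset from a PDBbind-layout directory
#'
#' Reads the index, parses each complex's pocket and ligand structure files,
#' and builds labelled complex graphs. Complexes whose structures fail to
#' parse are discarded (with a message), mirroring how unreadable entries
#' are dropped from the real database during preparation.
#'
#' @param dir Dataset directory (real or from [write_mini_pdbbind()]).
#' @param index_file Optional explicit index path; defaults to the first
#'   `INDEX*` file found in `dir`.
#' @return List with `complexes` (labelled `complex_graph` list),
#'   `discarded` (character ids) and `index` (the parsed index data.frame).
#' @export
assemble_dataset <- function(dir, index_file = NULL) {
  if (is.null(index_file)) {
    cand <- list.files(dir, pattern = "^INDEX", full.names = TRUE)
    if (!length(cand)) stopf("no INDEX* file found in '%s'", dir)
    index_file <- cand[1]
  }
  if (!file.exists(index_file)) stopf("index file '%s' does not exist", index_file)
  index <- read_pdbbind_index(index_file)
  complexes <- list()
  discarded <- character(0)
  for (r in seq_len(nrow(index))) {
    id <- index$id[r]
    cdir <- file.path(dir, id)
    res <- tryCatch({
      pocket <- read_structure(file.path(cdir, paste0(id, "_pocket.pdb")),
                               format = "pdb", id = id)
      lig_sdf <- file.path(cdir, paste0(id, "_ligand.sdf"))
      lig_mol2 <- file.path(cdir, paste0(id, "_ligand.mol2"))
      lig_path <- if (file.exists(lig_sdf)) lig_sdf else lig_mol2
      ligand <- read_structure(lig_path, format = "auto", id = id)
      build_complex(mol_to_graph(pocket), mol_to_graph(ligand),
                    label = index$pka[r], id = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("discarding complex '%s': %s", id, conditionMessage(res)))
      discarded <- c(discarded, id)
    } else {
      complexes[[length(complexes) + 1L]] <- res
    }
  }
  if (!length(complexes)) stopf("no parseable complexes in '%s'", dir)
  list(complexes = complexes, discarded = discarded, index = index)
}

#' Run the reference synthetic study end to end
#'
#' Generates the planted-affinity dataset (noise off by default, so the
#' ground truth is exactly graph-computable), trains the cascade network
#' with the package's desk-scale protocol, and evaluates scoring and
#' ranking power on the held-out complexes. The default protocol - 200
#' training and 50 test complexes, a 16-dimensional embedding with 2 ARMA
#' stacks of depth 2 and one message-passing layer, 300 epochs of Adam at
#' learning rate 3e-3 halved every 100 epochs - fits on a single CPU in a
#' few minutes; see the methods vignette for the reasoning behind these
#' sizes.
#'
#' @param seed Seed driving data generation, initialization and shuffling.
#' @param n_train,n_test Training and held-out complex counts.
#' @param noise_sd Label noise in pKa units (default 0).
#' @param config Optional [apmnet_config()] override.
#' @param control Optional [apmnet_control()] override.
#' @return List with the fitted model (`fit`), `train_report` and
#'   `test_report` ([evaluate_predictions()] objects), and `ranking_report`
#'   ([ranking_power()] over consecutive triples of test complexes).
#' @export
run_synthetic_study <- function(seed = 1L, n_train = 200L, n_test = 50L,
                                noise_sd = 0, config = NULL, control = NULL) {
  spec <- synthetic_spec(n_complexes = n_train + n_test, noise_sd = noise_sd,
                         seed = seed)
  dataset <- synthetic_dataset(spec)
  train <- dataset[seq_len(n_train)]
  test <- dataset[n_train + seq_len(n_test)]
  if (is.null(config))
    config <- apmnet_config(embed_dim = 16L, arma_layers = 2L, arma_stacks = 2L,
                            mpnn_layers = 1L, edge_hidden = 16L, head_dims = 8L)
  if (is.null(control))
    control <- apmnet_control(lr = 3e-3, lr_step = 100L, lr_gamma = 0.5,
                              epochs = 300L, batch_size = 32L, seed = seed)
  fit <- apmnet(train, config = config, control = control)
  pred <- predict(fit, test)
  y_test <- vapply(test, `[[`, 0, "label")
  triples <- split(seq_len(n_test), ceiling(seq_len(n_test) / 3L))
  triples <- Filter(function(ii) length(ii) == 3L && !anyDuplicated(y_test[ii]),
                    triples)
  clusters <- lapply(triples, function(ii)
    data.frame(y_true = y_test[ii], y_pred = pred[ii]))
  list(fit = fit,
       train_report = evaluate_predictions(fitted(fit), fit$y),
       test_report = evaluate_predictions(pred, y_test),
       ranking_report = ranking_power(clusters))
}
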