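# Atom/bond featurization and graph construction.

seg <- function(v, group) {
  widths <- c(44, 11, 7, 1, 1, 5, 1, 5)
  names(widths) <- c("atom_type", "degree", "valence", "charge", "radicals",
                     "hybridization", "aromatic", "hydrogens")
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  v[starts[[group]]:ends[[group]]]
}

test_that("methane carbon featurizes to a 75-vector with one hot per group", {
  a <- atom_record("C", degree = 4L, explicit_valence = 4L, formal_charge = 0L,
                   num_radical_electrons = 0L, hybridization = "SP3",
                   is_aromatic = FALSE, total_hydrogens = 4L)
  v <- featurize_atom(a)
  expect_length(v, 75)
  expect_equal(sum(seg(v, "atom_type")), 1)
  expect_equal(which(seg(v, "atom_type") == 1), 1)   # C is first in the vocabulary
  expect_equal(which(seg(v, "degree") == 1), 5)      # bin for degree 4
  expect_equal(which(seg(v, "valence") == 1), 5)
  expect_equal(seg(v, "charge"), 0)
  expect_equal(seg(v, "radicals"), 0)
  expect_equal(which(seg(v, "hybridization") == 1), 3)
  expect_equal(seg(v, "aromatic"), 0)
  expect_equal(which(seg(v, "hydrogens") == 1), 5)
  expect_equal(sum(v == 1), 5)  # 5 one-hot groups set; raw slots are zero here
})

test_that("out-of-vocabulary elements hit the unknown slot, raw slots pass through", {
  v <- featurize_atom(atom_record("Xx", degree = 1L, total_hydrogens = 0L))
  expect_equal(which(seg(v, "atom_type") == 1), 44)
  v2 <- featurize_atom(atom_record("O", degree = 1L, explicit_valence = 1L,
                                   formal_charge = -1L, total_hydrogens = 0L))
  expect_equal(seg(v2, "charge"), -1)
  expect_equal(unname(v2[56]), 0)  # valence one-hot region starts at index 56
  v3 <- featurize_atom(atom_record("N", num_radical_electrons = 2L))
  expect_equal(seg(v3, "radicals"), 2)
})

test_that("values above the one-hot ranges clamp to the top bin with a warning", {
  expect_warning(v <- featurize_atom(atom_record("C", degree = 12L)),
                 "degree")
  expect_equal(which(seg(v, "degree") == 1), 11)
  expect_warning(v <- featurize_atom(atom_record("C", total_hydrogens = 7L)),
                 "hydrogen")
  expect_equal(which(seg(v, "hydrogens") == 1), 5)
  expect_warning(v <- featurize_atom(atom_record("P", hybridization = "UNSPECIFIED")),
                 "SP3")
  expect_equal(which(seg(v, "hybridization") == 1), 3)
})

test_that("every one-hot group sums to one for randomly drawn atoms", {
  set.seed(71)
  vocab <- c(atom_type_vocabulary(), "Qq")
  for (i in 1:50) {
    a <- atom_record(sample(vocab, 1), degree = sample(0:10, 1),
                     explicit_valence = sample(0:6, 1),
                     formal_charge = sample(-2:2, 1),
                     num_radical_electrons = sample(0:2, 1),
                     hybridization = sample(c("SP", "SP2", "SP3", "SP3D", "SP3D2"), 1),
                     is_aromatic = sample(c(TRUE, FALSE), 1),
                     total_hydrogens = sample(0:4, 1))
    v <- featurize_atom(a)
    expect_length(v, 75)
    for (g in c("atom_type", "degree", "valence", "hybridization", "hydrogens"))
      expect_equal(sum(seg(v, g)), 1)
  }
})

test_that("bond featurization follows the single/double/triple/aromatic/conj/ring layout", {
  expect_equal(featurize_bond(bond_record(1, 2, "single")), c(1, 0, 0, 0, 0, 0))
  expect_equal(featurize_bond(bond_record(1, 2, "aromatic", is_conjugated = TRUE,
                                          is_in_ring = TRUE)),
               c(0, 0, 0, 1, 1, 1))
  expect_equal(featurize_bond(bond_record(1, 2, "triple", is_conjugated = TRUE)),
               c(0, 0, 1, 0, 1, 0))
  for (ord in c("single", "double", "triple", "aromatic")) {
    v <- featurize_bond(bond_record(3, 7, ord))
    expect_length(v, 6)
    expect_equal(sum(v[1:4]), 1)
  }
})

test_that("mol_to_graph mirrors every bond as two directed edges with one feature row", {
  two <- carbon_chain(2)
  g <- mol_to_graph(two)
  expect_equal(g$n, 2)
  expect_equal(nrow(g$edge_index), 2)
  expect_equal(dim(g$E), c(2, 6))
  expect_equal(g$E[1, ], g$E[2, ])

  gb <- mol_to_graph(benzene())
  expect_equal(nrow(gb$edge_index), 12)
  for (r in seq_len(12)) expect_equal(gb$E[r, ], c(0, 0, 0, 1, 1, 1))

  expect_error(mol_to_graph(molecule(list(), list(), id = "void")), "no atoms")
})

test_that("adjacency rebuilt from the edge list equals the brute-force bond adjacency", {
  for (s in 1:5) {
    mol <- make_random_molecule(10L, seed = 100 + s)
    g <- mol_to_graph(mol)
    A_edges <- matrix(0, g$n, g$n)
    A_edges[g$edge_index] <- 1
    A_bonds <- matrix(0, g$n, g$n)
    for (b in mol$bonds) {
      A_bonds[b$i, b$j] <- 1
      A_bonds[b$j, b$i] <- 1
    }
    expect_equal(A_edges, A_bonds)
    expect_equal(A_edges, t(A_edges))
    expect_equal(diag(A_edges), numeric(g$n))
  }
})

test_that("build_complex offsets ligand indices and adds no cross edges", {
  pocket <- molgraph(matrix(0, 5, 75), rbind(c(1L, 2L), c(2L, 1L)),
                     matrix(rep(c(1, 0, 0, 0, 0, 0), 2), 2, 6, byrow = TRUE))
  ligand <- molgraph(matrix(1, 3, 75), rbind(c(1L, 3L), c(3L, 1L)),
                     matrix(rep(c(1, 0, 0, 0, 0, 0), 2), 2, 6, byrow = TRUE))
  cg <- build_complex(pocket, ligand, label = 5.5)
  expect_equal(cg$graph$n, 8)
  expect_equal(cg$n_pocket + cg$n_ligand, cg$graph$n)
  got <- cg$graph$edge_index[order(cg$graph$edge_index[, 1]), ]
  expect_equal(got, rbind(c(1L, 2L), c(2L, 1L), c(6L, 8L), c(8L, 6L)))
  # zero edges crossing the pocket/ligand boundary, for arbitrary inputs
  for (s in 1:4) {
    p <- mol_to_graph(make_random_molecule(9L, seed = 300 + s))
    l <- mol_to_graph(make_random_molecule(6L, seed = 400 + s))
    cgx <- build_complex(p, l)
    ei <- cgx$graph$edge_index
    crosses <- xor(ei[, 1] <= p$n, ei[, 2] <= p$n)
    expect_equal(sum(crosses), 0)
    expect_equal(nrow(ei), nrow(p$edge_index) + nrow(l$edge_index))
  }
})

test_that("affinity converts to pKa on the -log10 molar scale", {
  expect_equal(affinity_to_pka(1, "nM"), 9)
  expect_equal(affinity_to_pka(1, "M"), 0)
  expect_equal(affinity_to_pka(50, "uM"), -log10(5e-5), tolerance = 1e-12)
  expect_equal(round(affinity_to_pka(50, "uM"), 3), 4.301)
  expect_error(affinity_to_pka(0, "nM"), "positive")
  expect_error(affinity_to_pka(-2, "mM"), "positive")
  for (x in 0:12) expect_equal(affinity_to_pka(10^(-x), "M"), x, tolerance = 1e-12)
})

test_that("complex graphs round-trip through the JSON cache container", {
  cg <- make_synthetic_complex(synthetic_spec(n_complexes = 1, seed = 12), 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_complex_graph(cg, path)
  back <- read_complex_graph(path)
  expect_equal(back$graph$X, cg$graph$X)
  expect_equal(back$graph$edge_index, cg$graph$edge_index)
  expect_equal(back$graph$E, cg$graph$E)
  expect_equal(back$label, cg$label)
  expect_equal(back$n_pocket, cg$n_pocket)
})
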