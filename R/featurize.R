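# Atom and bond featurization: the fixed 75-dimensional atom descriptor and
# 6-dimensional bond descriptor consumed by the network.

#' Element vocabulary of the atom-type one-hot block
#'
#' The 43 elements recognised by the atom featurizer, in the fixed order that
#' defines feature indices 1..43; any other element symbol maps to a 44th
#' "unknown" slot. The order is part of the model contract: saved parameters
#' are only meaningful against this exact layout.
#'
#' @return Character vector of length 43.
#' @export
atom_type_vocabulary <- function() {
  c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
    "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
    "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
    "Zr", "Cr", "Pt", "Hg", "Pb")
}

HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")

# Feature-group widths, in layout order. Total must be 75.
ATOM_FEATURE_GROUPS <- c(
  atom_type = 44L, degree = 11L, valence = 7L, formal_charge = 1L,
  radical_electrons = 1L, hybridization = 5L, aromaticity = 1L, hydrogens = 5L
)

#' Construct an atom record
#'
#' A plain, chemistry-level description of one atom: everything the atom
#' featurizer needs, independent of any file format or toolkit.
#'
#' @param element Element symbol (e.g. `"C"`); symbols outside
#'   [atom_type_vocabulary()] are legal and featurize as "unknown".
#' @param degree Number of directly bonded neighbours.
#' @param explicit_valence Explicit valence of the atom.
#' @param formal_charge Signed formal charge.
#' @param num_radical_electrons Number of unpaired electrons.
#' @param hybridization One of `"SP"`, `"SP2"`, `"SP3"`, `"SP3D"`, `"SP3D2"`,
#'   or any other label (clamped to SP3 at featurization time).
#' @param is_aromatic Logical aromaticity flag.
#' @param total_hydrogens Total hydrogen count (explicit + implicit).
#' @return An object of class `atom_record`.
#' @export
atom_record <- function(element, degree = 0L, explicit_valence = 0L,
                        formal_charge = 0L, num_radical_electrons = 0L,
                        hybridization = "SP3", is_aromatic = FALSE,
                        total_hydrogens = 0L) {
  if (!is.character(element) || length(element) != 1L || !nzchar(element))
    stopf("element must be a non-empty symbol string")
  if (!is_count(degree)) stopf("degree must be a non-negative integer")
  if (!is_count(total_hydrogens)) stopf("total_hydrogens must be >= 0")
  structure(
    list(element = element, degree = as.integer(degree),
         explicit_valence = as.integer(explicit_valence),
         formal_charge = as.integer(formal_charge),
         num_radical_electrons = as.integer(num_radical_electrons),
         hybridization = hybridization, is_aromatic = isTRUE(is_aromatic),
         total_hydrogens = as.integer(total_hydrogens)),
    class = "atom_record")
}

#' Construct a bond record
#'
#' @param i,j 1-based indices of the bonded atoms (`i != j`).
#' @param order Bond order label: `"single"`, `"double"`, `"triple"` or
#'   `"aromatic"`.
#' @param is_conjugated Logical: part of a conjugated system.
#' @param is_in_ring Logical: member of a ring.
#' @return An object of class `bond_record`.
#' @export
bond_record <- function(i, j, order = "single", is_conjugated = FALSE,
                        is_in_ring = FALSE) {
  if (!is_count(i, 1L) || !is_count(j, 1L)) stopf("bond indices must be positive integers")
  if (i == j) stopf("a bond cannot join an atom to itself (i == j == %d)", i)
  order <- match.arg(order, c("single", "double", "triple", "aromatic"))
  structure(
    list(i = as.integer(i), j = as.integer(j), order = order,
         is_conjugated = isTRUE(is_conjugated), is_in_ring = isTRUE(is_in_ring)),
    class = "bond_record")
}

#' Construct a molecule
#'
#' An ordered list of atoms plus an undirected bond list. Bond endpoints must
#' index into the atom list and no undirected bond may appear twice.
#'
#' @param atoms List of [atom_record()] objects.
#' @param bonds List of [bond_record()] objects.
#' @param id Identifier string (e.g. a PDB id), carried through to error
#'   messages and dataset assembly.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = list(), id = "mol") {
  n <- length(atoms)
  for (a in atoms) if (!inherits(a, "atom_record")) stopf("atoms must be atom_record objects")
  seen <- character(0)
  for (b in bonds) {
    if (!inherits(b, "bond_record")) stopf("bonds must be bond_record objects")
    if (b$i > n || b$j > n)
      stopf("bond (%d,%d) indexes outside the %d-atom molecule '%s'", b$i, b$j, n, id)
    key <- paste(min(b$i, b$j), max(b$i, b$j))
    if (key %in% seen) stopf("duplicate undirected bond (%d,%d) in '%s'", b$i, b$j, id)
    seen <- c(seen, key)
  }
  structure(list(atoms = atoms, bonds = bonds, id = id), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, %d bonds>\n",
              x$id, length(x$atoms), length(x$bonds)))
  invisible(x)
}

one_hot <- function(value, n_bins, what, clamp_to = n_bins - 1L) {
  v <- value
  if (v > n_bins - 1L) {
    warning(sprintf("%s %d above one-hot range 0..%d; clamped", what, v, n_bins - 1L),
            call. = FALSE)
    v <- clamp_to
  }
  out <- numeric(n_bins)
  out[v + 1L] <- 1
  out
}

#' Featurize one atom into the fixed 75-dimensional descriptor
#'
#' Concatenates, in order: element one-hot (44: the 43 vocabulary elements
#' then "unknown"), degree one-hot (bins 0..10), explicit-valence one-hot
#' (bins 0..6), formal charge as a raw signed value (1), radical-electron
#' count as a raw value (1), hybridization one-hot (SP, SP2, SP3, SP3D,
#' SP3D2), aromaticity flag (1), and total-hydrogen one-hot (bins 0..4).
#' Values above a one-hot range clamp to the top bin with a warning;
#' unrecognised hybridizations clamp to SP3 with a warning.
#'
#' @param atom An [atom_record()].
#' @return Numeric vector of length 75.
#' @export
featurize_atom <- function(atom) {
  stopifnot(inherits(atom, "atom_record"))
  vocab <- atom_type_vocabulary()
  el <- numeric(44L)
  idx <- match(atom$element, vocab)
  el[if (is.na(idx)) 44L else idx] <- 1

  hyb <- numeric(5L)
  hidx <- match(atom$hybridization, HYBRIDIZATIONS)
  if (is.na(hidx)) {
    warning(sprintf("hybridization '%s' outside {%s}; clamped to SP3",
                    atom$hybridization, paste(HYBRIDIZATIONS, collapse = ",")),
            call. = FALSE)
    hidx <- 3L
  }
  hyb[hidx] <- 1

  c(el,
    one_hot(atom$degree, 11L, "degree"),
    one_hot(max(atom$explicit_valence, 0L), 7L, "explicit valence"),
    as.numeric(atom$formal_charge),
    as.numeric(atom$num_radical_electrons),
    hyb,
    as.numeric(atom$is_aromatic),
    one_hot(atom$total_hydrogens, 5L, "hydrogen count"))
}

#' Featurize one bond into the 6-dimensional descriptor
#'
#' Layout: `[single, double, triple, aromatic, conjugated, in_ring]`. The
#' first four (order flags) are mutually exclusive; conjugation and ring
#' membership are independent flags.
#'
#' @param bond A [bond_record()].
#' @return Numeric 0/1 vector of length 6.
#' @export
featurize_bond <- function(bond) {
  stopifnot(inherits(bond, "bond_record"))
  ord <- as.numeric(bond$order == c("single", "double", "triple", "aromatic"))
  c(ord, as.numeric(bond$is_conjugated), as.numeric(bond$is_in_ring))
}
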