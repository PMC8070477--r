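# Structure file I/O: PDB / SDF / mol2 readers producing `molecule` objects,
# matching writers used by the synthetic fixture generator, and the
# PDBbind-style index file parser that supplies affinity labels.

BOND_ORDER_NUM <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# Build a molecule from parsed element symbols and a raw bond table
# (columns i, j, order label), perceiving the derived atom attributes the
# featurizer needs. Formal charges and radical counts default to whatever the
# file provided (zero when the format does not carry them). Conjugation and
# hybridization are perceived with standard topology-only heuristics: a bond
# is conjugated when aromatic or when it links two atoms that each carry a
# multiple-order bond; an atom is SP on a triple (or cumulated double) bond,
# SP2 when aromatic or doubly bonded, SP3 otherwise.
perceive_molecule <- function(elements, bonds, id, charges = NULL) {
  n <- length(elements)
  if (n == 0L) stopf("structure '%s' contains no atoms", id)
  if (is.null(charges)) charges <- integer(n)
  nb <- nrow(bonds)
  deg <- integer(n); n_double <- integer(n); n_triple <- integer(n)
  arom_atom <- logical(n); n_h <- integer(n); val <- numeric(n)
  multi_atom <- logical(n)   # atom carries a double/triple/aromatic bond
  if (nb) {
    for (k in seq_len(nb)) {
      i <- bonds$i[k]; j <- bonds$j[k]; ord <- bonds$order[k]
      if (i < 1L || j < 1L || i > n || j > n || i == j)
        stopf("structure '%s': bond (%d,%d) is inconsistent with %d atoms", id, i, j, n)
      deg[c(i, j)] <- deg[c(i, j)] + 1L
      val[c(i, j)] <- val[c(i, j)] + BOND_ORDER_NUM[[ord]]
      if (ord == "double") n_double[c(i, j)] <- n_double[c(i, j)] + 1L
      if (ord == "triple") n_triple[c(i, j)] <- n_triple[c(i, j)] + 1L
      if (ord == "aromatic") arom_atom[c(i, j)] <- TRUE
      if (ord %in% c("double", "triple", "aromatic")) multi_atom[c(i, j)] <- TRUE
      if (elements[j] == "H") n_h[i] <- n_h[i] + 1L
      if (elements[i] == "H") n_h[j] <- n_h[j] + 1L
    }
  }
  in_ring <- ring_bond_flags(n, bonds)
  atoms <- vector("list", n)
  for (a in seq_len(n)) {
    hyb <- if (n_triple[a] > 0L || n_double[a] >= 2L) "SP"
           else if (arom_atom[a] || n_double[a] == 1L) "SP2" else "SP3"
    atoms[[a]] <- atom_record(
      element = elements[a], degree = deg[a],
      explicit_valence = as.integer(round(val[a])),
      formal_charge = charges[a], num_radical_electrons = 0L,
      hybridization = hyb, is_aromatic = arom_atom[a], total_hydrogens = n_h[a])
  }
  brecs <- vector("list", nb)
  if (nb) {
    for (k in seq_len(nb)) {
      i <- bonds$i[k]; j <- bonds$j[k]; ord <- bonds$order[k]
      conj <- ord == "aromatic" || (multi_atom[i] && multi_atom[j])
      brecs[[k]] <- bond_record(i, j, order = ord, is_conjugated = conj,
                                is_in_ring = in_ring[k])
    }
  }
  molecule(atoms, brecs, id = id)
}

# A bond lies in a ring iff it is not a bridge of the molecular graph.
ring_bond_flags <- function(n, bonds) {
  nb <- nrow(bonds)
  if (!nb) return(logical(0))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nb)
  flags[as.integer(br)] <- FALSE
  flags
}

#' Read a molecular structure file
#'
#' Parses a PDB, SDF (V2000) or mol2 file into a [molecule()]. Hydrogens are
#' kept exactly as present in the file (none are added or removed); derived
#' atom attributes (degree, valence, hybridization, aromaticity, H counts)
#' are perceived from the connection table. Unparseable structures raise an
#' error carrying the complex id so that dataset assembly can discard them.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"`, `"mol2"` or `"sdf"`.
#' @param id Identifier attached to the molecule and to error messages;
#'   defaults to the file name without extension.
#' @return A [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mol2", "sdf"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("structure file '%s' does not exist", path)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- switch(ext, pdb = "pdb", mol2 = "mol2", sdf = "sdf", mol = "sdf",
                     stopf("cannot infer format from extension '.%s' (%s)", ext, path))
  }
  parsed <- tryCatch(
    switch(format,
           pdb = parse_pdb(path),
           mol2 = parse_mol2(path),
           sdf = parse_sdf(path)),
    error = function(e) stopf("failed to parse %s structure for '%s': %s",
                              format, id, conditionMessage(e)))
  perceive_molecule(parsed$elements, parsed$bonds, id = id,
                    charges = parsed$charges)
}

empty_bonds <- function() data.frame(i = integer(0), j = integer(0),
                                     order = character(0), stringsAsFactors = FALSE)

# Fixed-column PDB parser keeping ATOM/HETATM records and CONECT bonds.
# PDB carries no bond orders, so CONECT bonds are read as single bonds;
# bio3d::read.pdb is not used here because it drops the CONECT records the
# pocket fixtures rely on.
parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(at)) stop("no ATOM/HETATM records")
  serial <- as.integer(trimws(substr(at, 7, 11)))
  name <- trimws(substr(at, 13, 16))
  elem <- trimws(substr(at, 77, 78))
  fix <- !nzchar(elem) | is.na(elem)
  if (any(fix)) elem[fix] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", name[fix])
  if (any(!nzchar(elem)) || any(is.na(serial))) stop("malformed ATOM records")
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10)))
  index <- seq_along(serial); names(index) <- as.character(serial)
  con <- lines[startsWith(lines, "CONECT")]
  pairs <- list()
  for (ln in con) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    f <- f[!is.na(f)]
    if (length(f) < 2L) next
    centre <- index[[as.character(f[1])]]
    for (s in f[-1]) {
      nb <- index[as.character(s)]
      if (is.na(nb)) stop("CONECT references unknown atom serial ", s)
      pairs[[length(pairs) + 1L]] <- sort(c(centre, nb))
    }
  }
  bonds <- empty_bonds()
  if (length(pairs)) {
    pm <- unique(do.call(rbind, pairs))
    bonds <- data.frame(i = pm[, 1], j = pm[, 2], order = "single",
                        stringsAsFactors = FALSE)
  }
  list(elements = elem, bonds = bonds, charges = NULL)
}

# SDF (V2000) via ChemmineR; bond type 4 is aromatic.
parse_sdf <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) < 1L) stop("no molecule block found")
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || nrow(ab) == 0L) stop("empty atom block")
  elem <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- empty_bonds()
  if (!is.null(dim(bb)) && nrow(bb) > 0L) {
    ord_map <- c("1" = "single", "2" = "double", "3" = "triple", "4" = "aromatic")
    ord <- ord_map[as.character(as.integer(bb[, 3]))]
    if (any(is.na(ord))) stop("unsupported bond type in bond block")
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = unname(ord), stringsAsFactors = FALSE)
    if (any(bonds$i > length(elem)) || any(bonds$j > length(elem)))
      stop("bond block indexes outside atom block")
  }
  list(elements = elem, bonds = bonds, charges = NULL)
}

# Minimal Tripos mol2 parser (@<TRIPOS>ATOM / @<TRIPOS>BOND sections). The
# element is the SYBYL atom type up to the first '.'; 'ar' bonds are
# aromatic, 'am' amide bonds are read as single.
parse_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(tag) {
    start <- grep(paste0("^@<TRIPOS>", tag, "\\s*$"), lines)
    if (!length(start)) return(character(0))
    start <- start[1] + 1L
    ends <- grep("^@<TRIPOS>", lines)
    stop_at <- ends[ends >= start]
    end <- if (length(stop_at)) stop_at[1] - 1L else length(lines)
    out <- lines[seq(start, end)]
    out[nzchar(trimws(out))]
  }
  at <- sec("ATOM")
  if (!length(at)) stop("no @<TRIPOS>ATOM section")
  afields <- lapply(strsplit(trimws(at), "\\s+"), identity)
  if (any(vapply(afields, length, 1L) < 6L)) stop("malformed ATOM line")
  elem <- vapply(afields, function(f) sub("\\..*$", "", f[6]), "")
  bonds <- empty_bonds()
  bt <- sec("BOND")
  if (length(bt)) {
    bfields <- strsplit(trimws(bt), "\\s+")
    if (any(vapply(bfields, length, 1L) < 4L)) stop("malformed BOND line")
    ord_map <- c("1" = "single", "2" = "double", "3" = "triple",
                 ar = "aromatic", am = "single")
    ord <- ord_map[vapply(bfields, `[`, "", 4L)]
    if (any(is.na(ord))) stop("unsupported mol2 bond type")
    bonds <- data.frame(i = as.integer(vapply(bfields, `[`, "", 2L)),
                        j = as.integer(vapply(bfields, `[`, "", 3L)),
                        order = unname(ord), stringsAsFactors = FALSE)
  }
  list(elements = elem, bonds = bonds, charges = NULL)
}

#' Parse a PDBbind-style index file
#'
#' Whitespace-delimited records: complex id, resolution, year, -logKd/Ki and
#' an affinity string such as `"Kd=50uM"` or `"Ki~1.2nM"`; lines starting
#' with `#` are comments. The affinity string is decomposed and converted to
#' pKa (`-log10` molar).
#'
#' @param path Index file path.
#' @return A data.frame with columns `id`, `resolution`, `year`, `neg_log_k`,
#'   `measure`, `relation`, `value`, `unit`, `pka`.
#' @export
read_pdbbind_index <- function(path) {
  if (!file.exists(path)) stopf("index file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("index file '%s' has no data rows", path)
  mult <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 5L) stopf("malformed index row: '%s'", ln)
    m <- regmatches(f[5], regexec(
      "^(Kd|Ki|IC50)([=~<>]=?)([0-9.]+(?:[eE][+-]?[0-9]+)?)(fM|pM|nM|uM|mM|M)$", f[5]))[[1]]
    if (length(m) != 5L) stopf("cannot parse affinity string '%s' (id %s)", f[5], f[1])
    value <- as.numeric(m[4])
    data.frame(id = f[1], resolution = suppressWarnings(as.numeric(f[2])),
               year = suppressWarnings(as.integer(f[3])),
               neg_log_k = suppressWarnings(as.numeric(f[4])),
               measure = m[2], relation = m[3], value = value, unit = m[5],
               pka = -log10(value * mult[[m[5]]]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- writers (used by the synthetic fixture generator) ----

order_to_sdf <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

# Deterministic dummy coordinates: the model is topology-only, files just
# need syntactically valid geometry.
dummy_coords <- function(n) {
  cbind(1.5 * seq_len(n), rep(c(0, 0.7), length.out = n), 0)
}

#' Write a molecule as a PDB file with CONECT records
#'
#' Bond orders are not representable in PDB; connectivity is preserved via
#' CONECT records and all bonds read back as single bonds.
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_molecule <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  xyz <- dummy_coords(length(mol$atoms))
  lines <- character(0)
  for (a in seq_along(mol$atoms)) {
    el <- mol$atoms[[a]]$element
    nm <- sprintf("%s%d", toupper(el), a %% 100)
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a, substr(nm, 1, 4), "SYN", "A", 1L, xyz[a, 1], xyz[a, 2], xyz[a, 3],
      1, 0, toupper(el)))
  }
  nbrs <- lapply(seq_along(mol$atoms), function(i) integer(0))
  for (b in mol$bonds) {
    nbrs[[b$i]] <- c(nbrs[[b$i]], b$j)
    nbrs[[b$j]] <- c(nbrs[[b$j]], b$i)
  }
  for (a in seq_along(nbrs)) {
    if (length(nbrs[[a]]))
      lines <- c(lines, paste0("CONECT", sprintf("%5d", a),
                               paste(sprintf("%5d", sort(nbrs[[a]])), collapse = "")))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a molecule as an SDF (V2000) file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf_molecule <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$atoms); nb <- length(mol$bonds)
  xyz <- dummy_coords(n)
  lines <- c(mol$id, "  apmnet synthetic", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      xyz[a, 1], xyz[a, 2], xyz[a, 3], mol$atoms[[a]]$element))
  }
  for (b in mol$bonds) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j,
                              order_to_sdf[[b$order]]))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}

#' Write a molecule as a Tripos mol2 file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mol2_molecule <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$atoms); nb <- length(mol$bonds)
  xyz <- dummy_coords(n)
  lines <- c("@<TRIPOS>MOLECULE", mol$id,
             sprintf("%d %d 0 0 0", n, nb), "SMALL", "NO_CHARGES", "",
             "@<TRIPOS>ATOM")
  for (a in seq_len(n)) {
    el <- mol$atoms[[a]]$element
    lines <- c(lines, sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s 1 SYN 0.0000",
                              a, sprintf("%s%d", el, a), xyz[a, 1], xyz[a, 2],
                              xyz[a, 3], el))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  mol2_ord <- c(single = "1", double = "2", triple = "3", aromatic = "ar")
  for (k in seq_along(mol$bonds)) {
    b <- mol$bonds[[k]]
    lines <- c(lines, sprintf("%6d %5d %5d %s", k, b$i, b$j, mol2_ord[[b$order]]))
  }
  writeLines(lines, path)
  invisible(path)
}
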