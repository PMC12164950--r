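# Molecule-graph edits used by negative-product enumeration.
#
# Graphs are obtained from OpenBabel (SMILES -> SDF) and read with
# ChemmineR; edits (attach / delete an atom) are done on the atom and bond
# tables and serialized back through OpenBabel for canonical SMILES output.

# Parse a SMILES into a light graph: atom symbols, bond table, aromatic
# atom indices, plus the ChemmineR SDF object.
mol_graph <- function(smiles) {
  sdftxt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles),
    error = function(e) ""
  )
  if (!nzchar(sdftxt)) abort_invalid_molecule(smiles)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdftxt, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
  ring_info <- tryCatch(
    ChemmineR::rings(sdf, type = "all", arom = TRUE),
    error = function(e) list(RINGS = list(), AROMATIC = logical(0))
  )
  arom_atoms <- integer(0)
  if (length(ring_info$RINGS)) {
    arom_rings <- ring_info$RINGS[which(ring_info$AROMATIC)]
    arom_atoms <- unique(as.integer(sub("^.*_", "", unlist(arom_rings))))
  }
  list(
    atoms = atoms,
    coords = ab[, 1:3, drop = FALSE],
    bonds = bonds,
    aromatic = arom_atoms
  )
}

# Sum of bond orders incident to each atom (implicit hydrogens fill the
# remaining valence; an aromatic carbon with order sum 3 bears one H).
bond_order_sums <- function(graph) {
  s <- numeric(length(graph$atoms))
  for (i in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[i, ]
    s[b[1]] <- s[b[1]] + b[3]
    s[b[2]] <- s[b[2]] + b[3]
  }
  s
}

# Aromatic carbons carrying an implicit hydrogen: the candidate
# substitution sites for halogen repositioning.
aromatic_ch_sites <- function(graph) {
  s <- bond_order_sums(graph)
  which(graph$atoms == "C" & seq_along(graph$atoms) %in% graph$aromatic & s <= 3)
}

# Serialize a graph to an SDF molblock (V2000) string.
graph_to_molblock <- function(graph) {
  n <- length(graph$atoms)
  m <- nrow(graph$bonds)
  atom_lines <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            graph$coords[i, 1], graph$coords[i, 2], graph$coords[i, 3],
            graph$atoms[i])
  }, character(1))
  bond_lines <- vapply(seq_len(m), function(i) {
    sprintf("%3d%3d%3d  0  0  0  0",
            graph$bonds[i, 1], graph$bonds[i, 2], graph$bonds[i, 3])
  }, character(1))
  paste(c(
    "", " rxnrl", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    atom_lines, bond_lines,
    "M  END", "$$$$"
  ), collapse = "\n")
}

# Canonical SMILES of a graph, or NA if OpenBabel rejects it.
graph_to_smiles <- function(graph) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", graph_to_molblock(graph)),
    error = function(e) ""
  )
  out <- sub("[ \t\n]+.*$", "", out)
  if (!nzchar(out)) return(NA_character_)
  # round-trip through the string canonicalizer so cached forms agree
  canonicalize_or_na(out)
}

# Attach a single-bonded atom of `symbol` to atom `site`.
graph_attach <- function(graph, site, symbol) {
  n <- length(graph$atoms)
  graph$atoms <- c(graph$atoms, symbol)
  graph$coords <- rbind(graph$coords, graph$coords[site, ] + c(0.7, 0.7, 0))
  graph$bonds <- rbind(graph$bonds, c(site, n + 1L, 1L))
  graph
}

# Delete atom `idx` (and its bonds), renumbering the remainder.
graph_delete <- function(graph, idx) {
  keep <- setdiff(seq_along(graph$atoms), idx)
  remap <- integer(length(graph$atoms))
  remap[keep] <- seq_along(keep)
  bonds <- graph$bonds[graph$bonds[, 1] != idx & graph$bonds[, 2] != idx, ,
                       drop = FALSE]
  bonds[, 1] <- remap[bonds[, 1]]
  bonds[, 2] <- remap[bonds[, 2]]
  list(
    atoms = graph$atoms[keep],
    coords = graph$coords[keep, , drop = FALSE],
    bonds = bonds,
    aromatic = remap[intersect(graph$aromatic, keep)]
  )
}

# Molecular formula (hydrogens included) via atom symbols + implicit-H
# count from standard valences; used for the isomer invariant.
mol_formula <- function(smiles) {
  g <- mol_graph(canonicalize_smiles(smiles))
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
           B = 3, Si = 4)
  s <- bond_order_sums(g)
  h <- 0
  for (i in seq_along(g$atoms)) {
    v <- val[[g$atoms[i]]]
    if (!is.null(v)) h <- h + max(0, v - s[i])
  }
  counts <- sort(table(g$atoms))
  paste0(paste0(names(counts), as.integer(counts), collapse = ""), "H", h)
}
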