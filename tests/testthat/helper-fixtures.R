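# In-code builders for small molecular fixtures.

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal PDB ATOM/HETATM line
pdb_line <- function(serial, name, res, chain, seq, x, y, z, occ = 1,
                     element = substr(name, 1, 1), record = "ATOM") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, res, chain, seq, x, y, z, occ, 0, element)
}

pdb_line_alt <- function(serial, name, alt, res, chain, seq, x, y, z, occ) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, res, chain, seq, x, y, z, occ, 0,
          substr(name, 1, 1))
}

# minimal MOL2 text from atom/bond tables
mol2_text <- function(atoms, bonds = NULL) {
  nb <- if (is.null(bonds)) 0 else nrow(bonds)
  c("@<TRIPOS>MOLECULE", "test", sprintf(" %d %d 1", nrow(atoms), nb),
    "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %9.4f %9.4f %9.4f %-7s %2d %-8s %9.4f",
            seq_len(nrow(atoms)), atoms$name, atoms$x, atoms$y, atoms$z,
            atoms$type, 1L, "LIG1", atoms$charge %||% 0),
    if (nb) c("@<TRIPOS>BOND",
              sprintf("%6d %5d %5d %s", seq_len(nb), bonds$i, bonds$j,
                      bonds$order)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tetrahedral methane centered at the origin
methane_mol2 <- function() {
  s <- 1.09 / sqrt(3)
  atoms <- data.frame(
    name = c("C1", "H1", "H2", "H3", "H4"),
    type = c("C.3", "H", "H", "H", "H"),
    x = c(0, s, s, -s, -s), y = c(0, s, -s, s, -s),
    z = c(0, s, -s, -s, s))
  bonds <- data.frame(i = 1, j = 2:5, order = "1")
  write_lines_tmp(mol2_text(atoms, bonds), ".mol2")
}

# formate anion HCOO-
formate_mol2 <- function() {
  atoms <- data.frame(
    name = c("C1", "O1", "O2", "H1"),
    type = c("C.2", "O.co2", "O.co2", "H"),
    x = c(0, 1.13, -0.67, -0.55), y = c(0, 0.51, 1.02, -1.0),
    z = c(0, 0, 0, 0))
  bonds <- data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = c("ar", "ar", "1"))
  write_lines_tmp(mol2_text(atoms, bonds), ".mol2")
}

# flat aromatic hexagon with the given C-C bond length, normal = +z
benzene_ligand <- function(bond = 1.4, center = c(0, 0, 0)) {
  ang <- 2 * pi * (0:5) / 6
  r <- bond
  atoms <- data.frame(
    name = paste0("C", 1:6), type = "C.ar",
    x = center[1] + r * cos(ang), y = center[2] + r * sin(ang),
    z = center[3])
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = "ar")
  parse_ligand(write_lines_tmp(mol2_text(atoms, bonds), ".mol2"), "mol2")
}

# random rigid rotation matrix (uniform via QR of gaussians)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(x, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")]) %*% t(R)
  x$atoms$x <- xyz[, 1] + t[1]
  x$atoms$y <- xyz[, 2] + t[2]
  x$atoms$z <- xyz[, 3] + t[3]
  x
}

# random fixture spec with a seeded draw of planted counts
random_fixture_spec <- function(seed, max_count = 2) {
  set.seed(seed)
  kinds <- c("hydrogen_bond", "halogen_bond", "hydrophobic", "metal",
             "salt_bridge", "cation_pi", "pi_pi", "t_stack", "close_contact")
  counts <- sample(0:max_count, length(kinds), replace = TRUE)
  names(counts) <- kinds
  if (sum(counts) == 0) counts["hydrogen_bond"] <- 1
  fixture_spec(counts, seed = seed)
}

# build parsed + charged pocket/ligand pair from a fixture spec
parsed_complex <- function(spec) {
  cx <- make_complex(spec)
  d <- tempfile("cx")
  paths <- write_complex(cx, d)
  lig <- suppressWarnings(
    assign_partial_charges(parse_ligand(paths[["ligand"]], "mol2")))
  poc <- suppressWarnings(
    assign_partial_charges(parse_protein_pdb(paths[["protein"]])))
  unlink(d, recursive = TRUE)
  list(ligand = lig, pocket = poc, truth = cx$truth, counts = cx$counts)
}

# small learnable dataset shared across test files (built once per run)
model_test_env <- new.env()

small_dataset <- function() {
  if (is.null(model_test_env$ds)) {
    model_test_env$ds <- suppressWarnings(
      make_dataset(dataset_spec(n = 70, seed = 101, max_count = 2)))
  }
  model_test_env$ds
}

small_cfg <- function(...) {
  gnn_config(hidden_channels = 24, conv_layers = 2, epochs = 8,
             batch_size = 16, seed = 7, ...)
}

scaled_small <- function() {
  if (is.null(model_test_env$scaled)) {
    ds <- small_dataset()
    sc <- suppressWarnings(fit_scalers(ds$graphs))
    model_test_env$scaled <- lapply(ds$graphs, scale_graph, scaler = sc)
  }
  model_test_env$scaled
}

empty_pocket <- function() {
  structure(list(atoms = plaig:::empty_atoms(0), bonds = NULL),
            class = "plaig_pocket")
}

# node permutation of a built graph (for pooling-invariance checks)
permute_graph_nodes <- function(g, perm) {
  inv <- order(perm)
  g$node_matrix <- g$node_matrix[perm, , drop = FALSE]
  if (nrow(g$edge_list)) {
    g$edge_list[, 1] <- inv[g$edge_list[, 1]]
    g$edge_list[, 2] <- inv[g$edge_list[, 2]]
  }
  g
}
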