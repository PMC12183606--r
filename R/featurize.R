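# Node (40), edge (11), global-ligand (88) and global-pocket (74) features.
#
# Node layout: atomic number (1) | residue one-hot (22: 20 amino acids +
# OTHER + LIG) | hybridization one-hot (8) | degree (1) | aromaticity (1) |
# n_hydrogens (1) | mass (1, min-max scaled at training) | formal charge (1) |
# Gasteiger charge (1, z-scored) | xyz (3, raw Angstrom).
# Edge layout: electrostatic energy (z-scored) | 8 interaction flags
# (halogen, hydrogen, hydrophobic, metal, pi-pi, T-stack, salt bridge,
# cation-pi) | bond type (0 = protein-ligand contact, 1/2/3/4 = ligand
# single/double/triple/aromatic bond) | distance (min-max scaled).

.edge_flag_kinds <- c("halogen_bond", "hydrogen_bond", "hydrophobic", "metal",
                      "pi_pi", "t_stack", "salt_bridge", "cation_pi")

.lig_desc_names <- c(
  "n_atoms", "n_heavy_atoms", "n_hydrogen_atoms", "n_bonds", "n_single_bonds",
  "n_double_bonds", "n_triple_bonds", "n_aromatic_bonds", "n_carbon",
  "n_nitrogen", "n_oxygen", "n_sulfur", "n_phosphorus", "n_fluorine",
  "n_chlorine", "n_bromine", "n_iodine", "n_halogen", "n_heteroatoms",
  "molecular_weight", "mean_atomic_mass", "heavy_atom_fraction",
  "heteroatom_fraction", "aromatic_atom_fraction", "fraction_sp3",
  "n_sp_atoms", "n_sp2_atoms", "n_sp3_atoms", "n_aromatic_atoms",
  "n_rings", "n_aromatic_rings", "n_aromatic_ring_atoms",
  "n_hbond_donors", "n_hbond_acceptors", "tpsa_estimate", "logp_estimate",
  "n_rotatable_bonds", "mean_bond_length",
  "total_formal_charge", "n_positive_atoms", "n_negative_atoms",
  "mean_partial_charge", "sd_partial_charge", "min_partial_charge",
  "max_partial_charge", "sum_abs_partial_charge",
  "mean_degree", "max_degree", "n_degree_1", "n_degree_2", "n_degree_3",
  "n_degree_4plus", "zagreb_index", "chi0_connectivity", "chi1_connectivity",
  "radius_of_gyration", "max_interatomic_distance",
  "mean_interatomic_distance", "span_x", "span_y", "span_z", "asphericity",
  "acylindricity",
  "surface_area_estimate", "polar_surface_area_estimate",
  "apolar_surface_area_estimate", "polar_surface_fraction",
  "mean_vdw_radius", "vdw_volume_estimate",
  "fraction_carbon", "fraction_nitrogen", "fraction_oxygen",
  "fraction_sulfur",
  "n_fragments", "n_ring_bonds", "n_bridge_bonds", "graph_diameter",
  "mean_graph_distance",
  paste0("charge_bin_", sprintf("%02d", 1:10)))

.pocket_desc_names <- c(
  paste0("n_res_", .standard_residues), "n_res_other",
  "n_residues", "n_chains", "n_atoms", "n_heavy_atoms",
  "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur", "n_metal",
  "n_other_elements",
  "n_hydrophobic_residues", "n_polar_residues", "n_positive_residues",
  "n_negative_residues", "n_aromatic_residues", "mean_residue_size",
  "total_formal_charge", "mean_partial_charge", "sd_partial_charge",
  "min_partial_charge", "max_partial_charge", "sum_abs_partial_charge",
  "n_hbond_donors", "n_hbond_acceptors", "polar_atom_fraction",
  "n_aromatic_rings", "n_aromatic_atoms",
  "kd_hydrophobicity_mean", "kd_hydrophobicity_total",
  "radius_of_gyration", "span_x", "span_y", "span_z",
  "max_interatomic_distance", "mean_interatomic_distance", "asphericity",
  "acylindricity", "mean_vdw_radius", "vdw_volume_estimate",
  "surface_area_estimate", "polar_surface_area_estimate",
  "apolar_surface_area_estimate", "polar_surface_fraction",
  paste0("charge_bin_", sprintf("%02d", 1:10)))

.charge_bin_breaks <- c(-Inf, -0.5, -0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3, 0.5, Inf)

.kd_hydropathy <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
                    GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
                    LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
                    SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

.logp_atom <- c(C = 0.27, H = 0.12, N = -0.60, O = -0.55, S = 0.25, P = -0.50,
                F = 0.22, CL = 0.65, BR = 0.86, I = 1.12)

.tpsa_atom <- c(N = 15.79, O = 20.23, S = 25.30)

#' Feature schema
#'
#' The fixed layouts of the four feature vectors: 40 node features, 11 edge
#' features, 88 global ligand descriptors and 74 global pocket descriptors.
#' Vocabularies (22 residue classes, 8 hybridization states) and descriptor
#' orders are frozen for reproducibility; a human-readable JSON copy ships in
#' `inst/extdata/feature_schema.json`.
#'
#' @return named list with the vocabularies, slot names and scaling plan.
#' @export
feature_schema <- function() {
  residues <- c(.standard_residues, "OTHER", "LIG")
  node_names <- c("atomic_number", paste0("res_", residues),
                  paste0("hyb_", .hybridizations), "degree", "is_aromatic",
                  "n_hydrogens", "mass", "formal_charge", "gasteiger_charge",
                  "x", "y", "z")
  edge_names <- c("electrostatic_energy", paste0("flag_", .edge_flag_kinds),
                  "bond_type", "distance")
  stopifnot(length(node_names) == 40, length(edge_names) == 11,
            length(.lig_desc_names) == 88, length(.pocket_desc_names) == 74)
  list(version = "1",
       residues = residues,
       hybridizations = .hybridizations,
       node_names = node_names,
       edge_names = edge_names,
       ligand_descriptors = .lig_desc_names,
       pocket_descriptors = .pocket_desc_names,
       scaling = list(node_minmax = "mass", node_zscore = "gasteiger_charge",
                      edge_zscore = "electrostatic_energy",
                      edge_minmax = "distance", globals = "zscore"))
}

node_slot <- function(schema, name) match(name, schema$node_names)
edge_slot <- function(schema, name) match(name, schema$edge_names)

#' Node feature vectors
#'
#' @param atoms atom table (rows of a ligand or pocket container).
#' @param schema from \code{\link{feature_schema}}.
#' @param center_coords subtract the centroid from the coordinate block
#'   (default FALSE: absolute coordinates enter the graph raw).
#' @return numeric matrix nrow(atoms) x 40.
#' @export
node_features <- function(atoms, schema = feature_schema(),
                          center_coords = FALSE) {
  n <- nrow(atoms)
  res <- ifelse(atoms$residue_name == "LIG", "LIG",
                ifelse(atoms$residue_name %in% .standard_residues,
                       atoms$residue_name, "OTHER"))
  res_oh <- outer(res, schema$residues, "==") * 1
  hyb_oh <- outer(atoms$hybridization, schema$hybridizations, "==") * 1
  zn <- element_number(atoms$element)
  zn[is.na(zn)] <- 0
  mass <- atoms$mass; mass[is.na(mass)] <- 0
  xyz <- atom_xyz(atoms)
  if (center_coords && n) xyz <- sweep(xyz, 2, colMeans(xyz))
  out <- cbind(zn, res_oh, hyb_oh, atoms$degree, atoms$is_aromatic * 1,
               atoms$n_hydrogens, mass, atoms$formal_charge,
               atoms$partial_charge, xyz)
  colnames(out) <- schema$node_names
  out
}

#' Edge feature vector
#'
#' @param energy electrostatic energy of the pair (kcal/mol).
#' @param kinds character vector of interaction kinds present on this edge
#'   (close_contact sets no flag).
#' @param bond_order NULL/NA for a protein-ligand contact edge, else one of
#'   "1","2","3","ar" for a ligand covalent bond.
#' @param distance interatomic distance in Angstrom.
#' @param schema from \code{\link{feature_schema}}.
#' @return numeric vector of length 11.
#' @export
edge_features <- function(energy, kinds = character(), bond_order = NULL,
                          distance = 0, schema = feature_schema()) {
  flags <- as.numeric(.edge_flag_kinds %in% kinds)
  bt <- 0
  if (!is.null(bond_order) && !is.na(bond_order))
    bt <- switch(as.character(bond_order),
                 "1" = 1, "2" = 2, "3" = 3, "ar" = 4, 0)
  out <- c(energy, flags, bt, distance)
  names(out) <- schema$edge_names
  out
}

# ---------------------------------------------------------------------------
# Global descriptors.

.bridge_bonds <- function(bonds, n) {
  # Tarjan bridge finding; returns logical per bond row
  m <- nrow(bonds)
  if (!m) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bonds$i[k]]] <- rbind(adj[[bonds$i[k]]], c(bonds$j[k], k))
    adj[[bonds$j[k]]] <- rbind(adj[[bonds$j[k]]], c(bonds$i[k], k))
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  bridge <- logical(m)
  # iterative DFS to avoid recursion limits
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, ptr = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      nbrs <- adj[[fr$v]]
      if (is.null(nbrs) || fr$ptr > nrow(nbrs)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          par <- stack[[length(stack)]]
          low[par$v] <- min(low[par$v], low[fr$v])
          if (low[fr$v] > disc[par$v]) bridge[fr$pe] <- TRUE
        }
        next
      }
      to <- nbrs[fr$ptr, 1]; eid <- nbrs[fr$ptr, 2]
      stack[[length(stack)]]$ptr <- fr$ptr + 1L
      if (eid == fr$pe) next
      if (disc[to] != 0L) {
        low[fr$v] <- min(low[fr$v], disc[to])
      } else {
        timer <- timer + 1L; disc[to] <- low[to] <- timer
        stack[[length(stack) + 1]] <- list(v = to, pe = eid, ptr = 1L)
      }
    }
  }
  bridge
}

.graph_distances <- function(bonds, keep, n) {
  # BFS geodesics over the subgraph induced by `keep` (logical length n)
  idx <- which(keep)
  if (length(idx) < 2) return(c(diameter = 0, mean = 0))
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    if (keep[bonds$i[k]] && keep[bonds$j[k]]) {
      adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
      adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
    }
  }
  dmax <- 0; dsum <- 0; npair <- 0
  for (s in idx) {
    dist <- rep(-1L, n); dist[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] < 0) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    reach <- dist[idx] > 0
    dmax <- max(dmax, dist[idx][reach], 0)
    dsum <- dsum + sum(dist[idx][reach]); npair <- npair + sum(reach)
  }
  c(diameter = dmax, mean = if (npair) dsum / npair else 0)
}

.gyration_stats <- function(xyz) {
  if (nrow(xyz) < 2)
    return(c(rg = 0, asph = 0, acyl = 0))
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  gt <- crossprod(cen) / nrow(xyz)
  ev <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(rg = sqrt(sum(ev)), asph = ev[1] - 0.5 * (ev[2] + ev[3]),
    acyl = ev[2] - ev[3])
}

.charge_hist <- function(q) {
  q <- q[!is.na(q)]
  as.numeric(table(cut(q, .charge_bin_breaks, right = TRUE)))
}

.shared_shape_surface <- function(atoms) {
  el <- .norm_element(atoms$element)
  xyz <- atom_xyz(atoms)
  gy <- .gyration_stats(xyz)
  spans <- apply(xyz, 2, function(v) diff(range(v)))
  if (nrow(xyz) > 1) {
    d <- stats::dist(xyz)
    dmax <- max(d); dmean <- mean(d)
  } else { dmax <- 0; dmean <- 0 }
  rv <- vdw_radius(el)
  area <- 4 * pi * rv^2
  polar <- el %in% c("N", "O", "S", "P")
  c(rg = unname(gy["rg"]), span_x = spans[1], span_y = spans[2],
    span_z = spans[3], dmax = dmax, dmean = dmean,
    asph = unname(gy["asph"]), acyl = unname(gy["acyl"]),
    mean_rvdw = mean(rv), vol = sum(4 / 3 * pi * rv^3),
    area = sum(area), polar_area = sum(area[polar]),
    apolar_area = sum(area[!polar]),
    polar_frac = if (sum(area) > 0) sum(area[polar]) / sum(area) else 0)
}

#' Global ligand descriptors
#'
#' The fixed 88-descriptor physicochemical/topological summary of a ligand:
#' composition counts, mass and hybridization fractions, ring statistics,
#' hydrogen-bonding counts, additive logP/TPSA estimates, flexibility,
#' partial-charge statistics and histogram, connectivity indices, and
#' geometric shape/surface estimates. Values are raw here; they are z-scored
#' by the fitted \code{\link{fit_scalers}} at training time.
#'
#' @param ligand a `plaig_ligand` with charges assigned.
#' @param schema from \code{\link{feature_schema}}.
#' @return named numeric vector of length 88, all finite.
#' @export
global_ligand_features <- function(ligand, schema = feature_schema()) {
  atoms <- ligand$atoms; bonds <- ligand$bonds
  if (!nrow(atoms)) stop("empty molecule")
  el <- .norm_element(atoms$element)
  heavy <- el != "H"
  n <- nrow(atoms)
  q <- atoms$partial_charge; q[is.na(q)] <- 0
  cnt <- function(e) sum(el == e)
  ord <- bonds$order
  arom_rings <- find_aromatic_rings(ligand)
  # heavy-atom subgraph degrees for connectivity indices
  hdeg <- integer(n)
  hb <- bonds[heavy[bonds$i] & heavy[bonds$j], , drop = FALSE]
  if (nrow(hb)) {
    tab <- tabulate(c(hb$i, hb$j), nbins = n)
    hdeg <- tab
  }
  bridge <- .bridge_bonds(bonds, n)
  in_ring_bond <- !bridge
  comp <- .graph_distances(bonds, heavy, n)
  # rotatable: acyclic single bond between heavy atoms that both carry
  # another heavy neighbour
  rot <- if (nrow(bonds))
    sum(ord == "1" & bridge & heavy[bonds$i] & heavy[bonds$j] &
        hdeg[bonds$i] >= 2 & hdeg[bonds$j] >= 2) else 0
  n_frag <- {
    # connected components of the full graph
    seen <- logical(n); nfrag <- 0L
    adj <- neighbor_list(bonds, n)
    for (s in seq_len(n)) {
      if (seen[s]) next
      nfrag <- nfrag + 1L; queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    nfrag
  }
  blen <- if (nrow(bonds)) {
    xyz <- atom_xyz(atoms)
    mean(sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                       xyz[bonds$j, , drop = FALSE])^2)))
  } else 0
  shp <- .shared_shape_surface(atoms)
  hyb <- atoms$hybridization
  v <- c(
    n, sum(heavy), sum(!heavy), nrow(bonds), sum(ord == "1"),
    sum(ord == "2"), sum(ord == "3"), sum(ord == "ar"), cnt("C"), cnt("N"),
    cnt("O"), cnt("S"), cnt("P"), cnt("F"), cnt("CL"), cnt("BR"), cnt("I"),
    sum(is_halogen(el)), sum(heavy & !el %in% c("C")),
    sum(atoms$mass, na.rm = TRUE), mean(atoms$mass, na.rm = TRUE),
    sum(heavy) / n, sum(heavy & el != "C") / max(1, sum(heavy)),
    sum(atoms$is_aromatic) / n,
    sum(hyb == "SP3" & el == "C") / max(1, cnt("C")),
    sum(hyb == "SP"), sum(hyb == "SP2"), sum(hyb == "SP3"),
    sum(atoms$is_aromatic),
    nrow(bonds) - n + n_frag, length(arom_rings),
    length(unique(unlist(lapply(arom_rings, `[[`, "members")))),
    sum(el %in% c("N", "O", "S") & atoms$n_hydrogens > 0),
    sum(el %in% c("N", "O")),
    sum(.tpsa_atom[el], na.rm = TRUE),
    sum(.logp_atom[el], na.rm = TRUE),
    rot, blen,
    sum(atoms$formal_charge), sum(atoms$formal_charge > 0),
    sum(atoms$formal_charge < 0),
    mean(q), if (n > 1) sd(q) else 0, min(q), max(q), sum(abs(q)),
    mean(atoms$degree), max(atoms$degree, 0), sum(atoms$degree == 1),
    sum(atoms$degree == 2), sum(atoms$degree == 3), sum(atoms$degree >= 4),
    sum(atoms$degree^2),
    sum(1 / sqrt(hdeg[heavy & hdeg > 0])),
    if (nrow(hb)) sum(1 / sqrt(hdeg[hb$i] * hdeg[hb$j])) else 0,
    shp["rg"], shp["dmax"], shp["dmean"], shp["span_x"], shp["span_y"],
    shp["span_z"], shp["asph"], shp["acyl"],
    shp["area"], shp["polar_area"], shp["apolar_area"], shp["polar_frac"],
    shp["mean_rvdw"], shp["vol"],
    cnt("C") / n, cnt("N") / n, cnt("O") / n, cnt("S") / n,
    n_frag, sum(in_ring_bond), sum(bridge), comp["diameter"], comp["mean"],
    .charge_hist(q))
  v[!is.finite(v)] <- 0
  names(v) <- schema$ligand_descriptors
  v
}

#' Global pocket descriptors
#'
#' The fixed 74-descriptor summary of a binding pocket: residue composition
#' and class counts, element counts, charge statistics and histogram,
#' hydrogen-bonding capacity, aromatic content, Kyte-Doolittle
#' hydrophobicity, and geometric shape/surface estimates. Raw values;
#' z-scored at training time.
#'
#' @param pocket a `plaig_pocket` with charges assigned.
#' @param schema from \code{\link{feature_schema}}.
#' @return named numeric vector of length 74, all finite.
#' @export
global_pocket_features <- function(pocket, schema = feature_schema()) {
  atoms <- pocket$atoms
  if (!nrow(atoms)) stop("empty pocket")
  el <- .norm_element(atoms$element)
  q <- atoms$partial_charge; q[is.na(q)] <- 0
  key <- residue_key(atoms)
  resname <- tapply(atoms$residue_name, key, `[`, 1)
  res_counts <- vapply(.standard_residues, function(r) sum(resname == r),
                       numeric(1))
  n_res <- length(resname)
  hydrophobic_set <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
  polar_set <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "GLY")
  pos_set <- c("LYS", "ARG", "HIS"); neg_set <- c("ASP", "GLU")
  arom_set <- c("PHE", "TYR", "TRP", "HIS")
  kd <- .kd_hydropathy[resname]; kd[is.na(kd)] <- 0
  arom_rings <- find_aromatic_rings(pocket)
  shp <- .shared_shape_surface(atoms)
  heavy <- el != "H"
  v <- c(
    res_counts, sum(!resname %in% .standard_residues),
    n_res, length(unique(atoms$chain)), nrow(atoms), sum(heavy),
    sum(el == "C"), sum(el == "N"), sum(el == "O"), sum(el == "S"),
    sum(is_metal(el)),
    sum(!el %in% c("C", "N", "O", "S", "H") & !is_metal(el)),
    sum(resname %in% hydrophobic_set), sum(resname %in% polar_set),
    sum(resname %in% pos_set), sum(resname %in% neg_set),
    sum(resname %in% arom_set), nrow(atoms) / n_res,
    sum(atoms$formal_charge), mean(q),
    if (nrow(atoms) > 1) sd(q) else 0, min(q), max(q), sum(abs(q)),
    sum(el %in% c("N", "O", "S") & atoms$n_hydrogens > 0),
    sum(el %in% c("N", "O")),
    sum(el %in% c("N", "O", "S")) / nrow(atoms),
    length(arom_rings), sum(atoms$is_aromatic),
    mean(kd), sum(kd),
    shp["rg"], shp["span_x"], shp["span_y"], shp["span_z"], shp["dmax"],
    shp["dmean"], shp["asph"], shp["acyl"], shp["mean_rvdw"], shp["vol"],
    shp["area"], shp["polar_area"], shp["apolar_area"], shp["polar_frac"],
    .charge_hist(q))
  v[!is.finite(v)] <- 0
  names(v) <- schema$pocket_descriptors
  v
}

# ---------------------------------------------------------------------------
# Feature scaling.

#' Fit feature scalers on a training set of raw graphs
#'
#' Gathers the training-set statistics for the representation's scaling plan:
#' z-scores for Gasteiger charges, electrostatic energies and both global
#' descriptor blocks; min-max for atomic masses and edge distances. The
#' statistics are global (training-set-wide), so every graph shares one
#' range. Constant features fall back to passthrough with a warning.
#'
#' @param graphs list of raw (unscaled) `plaig_graph` objects, length >= 2.
#' @return a `plaig_scaler`.
#' @export
fit_scalers <- function(graphs) {
  if (length(graphs) < 2) stop("need at least 2 training complexes")
  if (any(vapply(graphs, function(g) isTRUE(g$scaled), logical(1))))
    stop("fit_scalers expects raw (unscaled) graphs")
  schema <- feature_schema()
  im <- node_slot(schema, "mass"); ig <- node_slot(schema, "gasteiger_charge")
  ie <- edge_slot(schema, "electrostatic_energy")
  id <- edge_slot(schema, "distance")
  masses <- unlist(lapply(graphs, function(g) g$node_matrix[, im]))
  gast <- unlist(lapply(graphs, function(g) g$node_matrix[, ig]))
  energies <- unlist(lapply(graphs, function(g)
    if (nrow(g$edge_matrix)) g$edge_matrix[, ie] else numeric(0)))
  dists <- unlist(lapply(graphs, function(g)
    if (nrow(g$edge_matrix)) g$edge_matrix[, id] else numeric(0)))
  lg <- do.call(rbind, lapply(graphs, `[[`, "ligand_global"))
  pg <- do.call(rbind, lapply(graphs, `[[`, "pocket_global"))
  zstat <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  mstat <- function(x) c(min = if (length(x)) min(x) else 0,
                         max = if (length(x)) max(x) else 0)
  sc <- structure(list(
    node_mass = mstat(masses), node_gasteiger = zstat(gast),
    edge_energy = zstat(energies), edge_distance = mstat(dists),
    lig_mean = colMeans(lg), lig_sd = apply(lg, 2, sd),
    pocket_mean = colMeans(pg), pocket_sd = apply(pg, 2, sd),
    schema_version = schema$version), class = "plaig_scaler")
  ncon <- sum(sc$lig_sd <= 0) + sum(sc$pocket_sd <= 0) +
    (sc$node_gasteiger["sd"] <= 0) + (sc$edge_energy["sd"] <= 0)
  if (ncon > 0)
    warning(ncon, " constant feature(s) left unscaled (passthrough)")
  sc
}

.apply_z <- function(x, stat) {
  if (is.na(stat["sd"]) || stat["sd"] <= 0) return(x)
  (x - stat["mean"]) / stat["sd"]
}

.apply_minmax <- function(x, stat) {
  rng <- stat["max"] - stat["min"]
  if (is.na(rng) || rng <= 0) return(x)
  pmin(1, pmax(0, (x - stat["min"]) / rng))
}

#' Apply fitted scalers to a raw graph
#'
#' Out-of-range min-max values are clamped to [0, 1]; a graph can only be
#' scaled once (guarded by the `scaled` flag).
#'
#' @param graph a raw `plaig_graph`.
#' @param scaler a fitted `plaig_scaler`.
#' @return the scaled graph.
#' @export
scale_graph <- function(graph, scaler) {
  stopifnot(inherits(scaler, "plaig_scaler"))
  if (isTRUE(graph$scaled)) stop("graph is already scaled")
  schema <- feature_schema()
  im <- node_slot(schema, "mass"); ig <- node_slot(schema, "gasteiger_charge")
  ie <- edge_slot(schema, "electrostatic_energy")
  id <- edge_slot(schema, "distance")
  graph$node_matrix[, im] <- .apply_minmax(graph$node_matrix[, im],
                                           scaler$node_mass)
  graph$node_matrix[, ig] <- .apply_z(graph$node_matrix[, ig],
                                      scaler$node_gasteiger)
  if (nrow(graph$edge_matrix)) {
    graph$edge_matrix[, ie] <- .apply_z(graph$edge_matrix[, ie],
                                        scaler$edge_energy)
    graph$edge_matrix[, id] <- .apply_minmax(graph$edge_matrix[, id],
                                             scaler$edge_distance)
  }
  zvec <- function(x, m, s) ifelse(s > 0, (x - m) / s, x)
  graph$ligand_global <- zvec(graph$ligand_global, scaler$lig_mean,
                              scaler$lig_sd)
  graph$pocket_global <- zvec(graph$pocket_global, scaler$pocket_mean,
                              scaler$pocket_sd)
  graph$scaled <- TRUE
  graph
}

# ---------------------------------------------------------------------------
# PCA elbow analysis (optional path; not part of the default pipeline).

#' PCA elbow analysis of a global-feature matrix
#'
#' Full principal-component decomposition of an (already z-scored) feature
#' matrix. The elbow is the smallest component count k such that the next
#' component's marginal explained-variance gain drops below `gain_threshold`
#' (default 1% of total variance); when every gain stays above the threshold
#' the elbow is capped at the matrix rank.
#'
#' @param mat numeric matrix, rows = complexes (>= 2), columns = features.
#' @param gain_threshold marginal explained-variance fraction (default 0.01).
#' @return list(n_components, explained_variance, cumulative_variance).
#' @export
pca_elbow <- function(mat, gain_threshold = 0.01) {
  stopifnot(is.matrix(mat) || is.data.frame(mat))
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows")
  keep <- apply(mat, 2, function(v) sd(v) > 0)
  pc <- prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  var_ <- pc$sdev^2
  rank_ <- sum(var_ > max(var_) * 1e-12)
  ratio <- var_ / sum(var_)
  cum <- cumsum(ratio)
  k <- rank_
  for (i in seq_len(rank_ - 1)) {
    if (ratio[i + 1] < gain_threshold) { k <- i; break }
  }
  list(n_components = k, explained_variance = ratio,
       cumulative_variance = cum)
}
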