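# Complex-graph assembly and serialization.
#
# Nodes: all ligand atoms (file order) followed by the pocket atoms that are
# either within the contact cutoff of any ligand atom or named by a contact
# (ring-mediated categories can reference a member atom slightly beyond the
# generic cutoff; including it keeps every edge endpoint a node). Pocket
# nodes are ordered by (chain, residue_seq, atom index). Edges: every ligand
# covalent bond, plus exactly one edge per (ligand atom, pocket atom) pair
# appearing in any contact -- all of a pair's interaction flags live on that
# single edge. There are no pocket-pocket edges, so the graph is sparse.

#' Build a protein-ligand complex graph
#'
#' @param pocket a `plaig_pocket` with charges assigned.
#' @param ligand a `plaig_ligand` with charges assigned.
#' @param interactions result of \code{\link{detect_interactions}}, computed
#'   with the same `cutoff`.
#' @param scaler optional fitted `plaig_scaler`; when supplied the graph is
#'   returned scaled.
#' @param schema from \code{\link{feature_schema}}.
#' @param cutoff node-inclusion cutoff in Angstrom (default 3.0).
#' @param id complex identifier string.
#' @param target experimental affinity in pKd/pKi units, or NA.
#' @param center_coords passed to \code{\link{node_features}}.
#' @return a `plaig_graph`: list(node_matrix n x 40, edge_list m x 2,
#'   edge_matrix m x 11, ligand_global, pocket_global, target, id,
#'   n_ligand_atoms, pocket_node_atoms, scaled).
#' @export
build_graph <- function(pocket, ligand, interactions, scaler = NULL,
                        schema = feature_schema(), cutoff = 3.0,
                        id = "complex", target = NA_real_,
                        center_coords = FALSE) {
  stopifnot(inherits(interactions, "plaig_interactions"))
  if (!isTRUE(all.equal(interactions$cutoff, cutoff)))
    stop(sprintf("interactions were detected with cutoff %.3f but graph cutoff is %.3f",
                 interactions$cutoff, cutoff))
  la <- ligand$atoms; pa <- pocket$atoms
  nl <- nrow(la)
  lxyz <- atom_xyz(la); pxyz <- atom_xyz(pa)
  # pocket atoms within cutoff of any ligand atom
  mind2 <- rep(Inf, nrow(pa))
  for (k in seq_len(nl)) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
      (pxyz[, 3] - lxyz[k, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  ct <- interactions$contacts
  pocket_sel <- sort(unique(c(which(sqrt(mind2) <= cutoff), ct$pocket_atom)))
  if (!length(pocket_sel))
    warning("no pocket atom within the cutoff; graph holds the ligand only")
  # canonical pocket-node order: chain, residue number, atom index
  if (length(pocket_sel)) {
    ordp <- pocket_sel[order(pa$chain[pocket_sel], pa$residue_seq[pocket_sel],
                             pocket_sel)]
  } else ordp <- integer(0)
  pocket_map <- integer(nrow(pa))
  pocket_map[ordp] <- nl + seq_along(ordp)
  atoms <- rbind(la, pa[ordp, , drop = FALSE])
  rownames(atoms) <- NULL
  node_matrix <- node_features(atoms, schema, center_coords = center_coords)
  xyz <- atom_xyz(atoms)

  edge_rows <- list()
  # ligand covalent bonds
  if (nrow(ligand$bonds)) {
    b <- ligand$bonds
    d <- sqrt(rowSums((lxyz[b$i, , drop = FALSE] -
                       lxyz[b$j, , drop = FALSE])^2))
    en <- electrostatic_energy(la$partial_charge[b$i], la$partial_charge[b$j],
                               d)
    for (k in seq_len(nrow(b))) {
      edge_rows[[length(edge_rows) + 1]] <- list(
        i = min(b$i[k], b$j[k]), j = max(b$i[k], b$j[k]),
        feat = edge_features(en[k], character(), b$order[k], d[k], schema))
    }
  }
  # one edge per contact pair, all flags merged
  if (nrow(ct)) {
    pair_id <- paste(ct$ligand_atom, ct$pocket_atom)
    for (pid in unique(pair_id)) {
      rows <- ct[pair_id == pid, , drop = FALSE]
      i <- rows$ligand_atom[1]; jp <- rows$pocket_atom[1]
      j <- pocket_map[jp]
      d <- sqrt(sum((lxyz[i, ] - pxyz[jp, ])^2))
      en <- electrostatic_energy(la$partial_charge[i],
                                 pa$partial_charge[jp], d)
      edge_rows[[length(edge_rows) + 1]] <- list(
        i = i, j = j,
        feat = edge_features(en, rows$kind, NULL, d, schema))
    }
  }
  if (length(edge_rows)) {
    el <- t(vapply(edge_rows, function(e) c(e$i, e$j), numeric(2)))
    em <- t(vapply(edge_rows, `[[`, numeric(11), "feat"))
    ord <- order(el[, 1], el[, 2])
    el <- el[ord, , drop = FALSE]; em <- em[ord, , drop = FALSE]
  } else {
    el <- matrix(numeric(0), 0, 2)
    em <- matrix(numeric(0), 0, 11,
                 dimnames = list(NULL, schema$edge_names))
  }
  colnames(em) <- schema$edge_names
  g <- structure(list(
    node_matrix = node_matrix, edge_list = el, edge_matrix = em,
    ligand_global = global_ligand_features(ligand, schema),
    pocket_global = global_pocket_features(pocket, schema),
    target = as.numeric(target), id = as.character(id),
    n_ligand_atoms = nl, pocket_node_atoms = ordp,
    cutoff = cutoff, scaled = FALSE,
    schema_version = schema$version), class = "plaig_graph")
  if (!is.null(scaler)) g <- scale_graph(g, scaler)
  g
}

#' @export
print.plaig_graph <- function(x, ...) {
  cat(sprintf("<plaig_graph> '%s': %d nodes (%d ligand), %d edges%s%s\n",
              x$id, nrow(x$node_matrix), x$n_ligand_atoms, nrow(x$edge_list),
              if (isTRUE(x$scaled)) ", scaled" else "",
              if (is.finite(x$target)) sprintf(", target %.2f", x$target)
              else ""))
  invisible(x)
}

# numbers serialized as %.17g strings: lossless double round trip
.num_out <- function(x) {
  out <- sprintf("%.17g", as.numeric(x))
  out[is.na(x)] <- "NA"
  out
}
.num_in <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out
}

#' Write a complex graph to a JSON container
#'
#' Matrices are stored as full-precision decimal strings, so
#' `read_graph(write_graph(g))` reproduces every matrix bit-exactly.
#'
#' @param graph a `plaig_graph`.
#' @param path output path.
#' @export
write_graph <- function(graph, path) {
  payload <- list(
    format = "plaig-graph", version = graph$schema_version,
    id = graph$id, target = .num_out(graph$target),
    cutoff = .num_out(graph$cutoff), scaled = isTRUE(graph$scaled),
    n_ligand_atoms = graph$n_ligand_atoms,
    pocket_node_atoms = graph$pocket_node_atoms,
    node_matrix = list(dim = dim(graph$node_matrix),
                       data = .num_out(graph$node_matrix)),
    edge_list = list(dim = dim(graph$edge_list),
                     data = as.integer(graph$edge_list)),
    edge_matrix = list(dim = dim(graph$edge_matrix),
                       data = .num_out(graph$edge_matrix)),
    ligand_global = .num_out(graph$ligand_global),
    pocket_global = .num_out(graph$pocket_global))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a complex graph written by \code{\link{write_graph}}
#' @param path path to the JSON container.
#' @return a `plaig_graph`.
#' @export
read_graph <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (!identical(p$format, "plaig-graph"))
    stop("not a plaig graph container: ", path)
  schema <- feature_schema()
  mkmat <- function(entry, conv = .num_in) {
    m <- matrix(conv(entry$data), entry$dim[1], entry$dim[2])
    m
  }
  nm <- mkmat(p$node_matrix); colnames(nm) <- schema$node_names
  em <- mkmat(p$edge_matrix); colnames(em) <- schema$edge_names
  structure(list(
    node_matrix = nm,
    edge_list = mkmat(p$edge_list, as.numeric),
    edge_matrix = em,
    ligand_global = setNames(.num_in(p$ligand_global),
                             schema$ligand_descriptors),
    pocket_global = setNames(.num_in(p$pocket_global),
                             schema$pocket_descriptors),
    target = .num_in(p$target), id = p$id,
    n_ligand_atoms = p$n_ligand_atoms,
    pocket_node_atoms = p$pocket_node_atoms,
    cutoff = .num_in(p$cutoff), scaled = isTRUE(p$scaled),
    schema_version = p$version), class = "plaig_graph")
}
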