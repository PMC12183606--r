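# Distance-based binding-pocket extraction.

#' Extract the binding pocket around a docked ligand
#'
#' Keeps every protein residue having at least one atom within `radius` of
#' any ligand atom. Retention is residue-level: a residue is kept whole or
#' not at all, and residue order is preserved. Metal ions and cofactor
#' HETATM groups inside the radius are retained like any other residue.
#'
#' @param protein a `plaig_pocket` holding the full protein (from
#'   \code{\link{parse_protein_pdb}}).
#' @param ligand a `plaig_ligand` in its docked pose.
#' @param radius cutoff in Angstrom (default 10).
#' @param heavy_only measure distances to heavy atoms only (default FALSE:
#'   hydrogens count when present).
#' @return a `plaig_pocket` restricted to the retained residues.
#' @export
extract_pocket <- function(protein, ligand, radius = 10.0, heavy_only = FALSE) {
  stopifnot(inherits(protein, "plaig_pocket"), inherits(ligand, "plaig_ligand"))
  if (!nrow(protein$atoms) || !nrow(ligand$atoms))
    stop("protein and ligand must both be non-empty")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  pa <- protein$atoms
  la <- ligand$atoms
  pi_keep <- seq_len(nrow(pa))
  li_keep <- seq_len(nrow(la))
  if (heavy_only) {
    pi_keep <- which(.norm_element(pa$element) != "H")
    li_keep <- which(.norm_element(la$element) != "H")
  }
  pxyz <- atom_xyz(pa)[pi_keep, , drop = FALSE]
  lxyz <- atom_xyz(la)[li_keep, , drop = FALSE]
  # per protein atom: squared distance to the nearest ligand atom
  mind2 <- rep(Inf, nrow(pa))
  for (k in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
      (pxyz[, 3] - lxyz[k, 3])^2
    mind2[pi_keep] <- pmin(mind2[pi_keep], d2)
  }
  key <- residue_key(pa)
  res_min <- tapply(mind2, key, min)
  hit <- names(res_min)[sqrt(res_min) <= radius]
  if (!length(hit))
    stop(sprintf(
      "no residue within %.3g Angstrom of the ligand (minimum observed distance %.3f)",
      radius, sqrt(min(mind2))))
  sel <- key %in% hit
  atoms <- pa[sel, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- NULL
  if (!is.null(protein$bonds) && nrow(protein$bonds)) {
    remap <- integer(nrow(pa)); remap[which(sel)] <- seq_len(sum(sel))
    b <- protein$bonds
    keep <- sel[b$i] & sel[b$j]
    bonds <- data.frame(i = remap[b$i[keep]], j = remap[b$j[keep]],
                        order = b$order[keep], stringsAsFactors = FALSE)
  }
  new_pocket(atoms, bonds)
}
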