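# Geometric detection of the nine protein-ligand interaction categories.
#
# Category rules (distances in Angstrom, angles in degrees). The generic
# contact cutoff bounds close-contact/edge creation and the hydrogen-bond
# donor-acceptor distance; the remaining categories carry their own caps:
#   hydrogen_bond  D...A <= cutoff (3.0), D-H...A angle >= 140, D in {N,O,S}
#                  with >= 1 explicit H, A in {N,O}
#   halogen_bond   ligand X in {F,Cl,Br,I} to pocket {O,N,S}, X...A <= cutoff,
#                  C-X...A angle >= 140
#   hydrophobic    C...C <= 4.0, both carbons bonded only to C/H/halogen
#   metal          ligand {N,O,S} to pocket metal ion <= 3.5
#   salt_bridge    formally positive group atom to formally negative group
#                  atom <= 5.5
#   cation_pi      cation to aromatic ring centroid <= 6.0
#   pi_pi          ring centroids <= 7.2, acute inter-normal angle <= 30
#   t_stack        ring centroids <= 5.0, inter-normal angle 60-120
#   close_contact  any ligand-pocket pair <= cutoff
# Every contact carries the Coulomb energy of its stored atom pair.

.contact_kinds <- c("hydrogen_bond", "halogen_bond", "hydrophobic", "metal",
                    "pi_pi", "t_stack", "salt_bridge", "cation_pi",
                    "close_contact")

#' Default interaction rule table
#'
#' Loads the packaged rule table (inst/extdata/interaction_rules.json).
#' Every threshold can be overridden by passing a modified copy to
#' \code{\link{detect_interactions}}.
#' @return named list of thresholds.
#' @export
interaction_rules <- function() {
  path <- system.file("extdata", "interaction_rules.json", package = "plaig")
  if (nzchar(path)) {
    jsonlite::fromJSON(path)
  } else {
    # fallback when running from a source checkout
    list(hbond_angle = 140, halogen_angle = 140, hydrophobic_dist = 4.0,
         metal_dist = 3.5, salt_bridge_dist = 5.5, cation_pi_dist = 6.0,
         pi_pi_dist = 7.2, pi_pi_angle = 30, t_stack_dist = 5.0,
         t_stack_angle_min = 60, t_stack_angle_max = 120)
  }
}

#' Coulomb electrostatic energy of an atom pair
#'
#' `332.06 * q1 * q2 / r` kcal/mol (dielectric constant 1; 332.06 converts
#' e^2/Angstrom to kcal/mol).
#'
#' @param q1,q2 partial charges in elementary-charge units.
#' @param r interatomic distance in Angstrom, must be positive.
#' @return energy in kcal/mol.
#' @export
electrostatic_energy <- function(q1, q2, r) {
  if (any(r <= 0)) stop("distance must be positive")
  332.06 * q1 * q2 / r
}

#' Find aromatic rings
#'
#' Returns all 5- and 6-membered cycles whose members are all flagged
#' aromatic. For ligands the cycles are found on the covalent bond graph; for
#' pockets the standard aromatic side-chain ring definitions (Phe/Tyr/His/Trp)
#' are used. The ring normal is the least-squares plane normal (unit length).
#'
#' @param x a `plaig_ligand` or `plaig_pocket`.
#' @return list of rings, each `list(members, centroid, normal)`.
#' @export
find_aromatic_rings <- function(x) {
  atoms <- x$atoms
  xyz <- atom_xyz(atoms)
  ring_geom <- function(members) {
    pts <- xyz[members, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    nrm <- sv$v[, 3]
    nrm <- nrm / sqrt(sum(nrm^2))
    list(members = members, centroid = ctr, normal = nrm)
  }
  out <- list()
  if (inherits(x, "plaig_ligand")) {
    cycles <- find_rings(x$bonds, nrow(atoms), sizes = c(5L, 6L))
    for (r in cycles) {
      if (all(atoms$is_aromatic[r])) out[[length(out) + 1]] <- ring_geom(sort(r))
    }
  } else {
    key <- residue_key(atoms)
    nm <- toupper(atoms$atom_name)
    for (res in unique(key)) {
      idx <- which(key == res)
      rname <- atoms$residue_name[idx[1]]
      defs <- .residue_rings[[rname]]
      if (is.null(defs)) next
      for (d in defs) {
        members <- idx[match(d, nm[idx])]
        if (any(is.na(members))) next
        if (!all(atoms$is_aromatic[members])) next
        out[[length(out) + 1]] <- ring_geom(sort(members))
      }
    }
  }
  out
}

.angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

.acute_normal_angle <- function(n1, n2) {
  cosv <- abs(sum(n1 * n2))
  acos(pmin(1, cosv)) * 180 / pi
}

neighbor_list <- function(bonds, n) {
  nb <- vector("list", n)
  if (!is.null(bonds) && nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
      nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
    }
  }
  nb
}

# carbon bonded only to C/H/halogen => eligible for hydrophobic contacts
hydrophobic_eligible <- function(atoms, nb) {
  el <- .norm_element(atoms$element)
  vapply(seq_len(nrow(atoms)), function(i) {
    if (el[i] != "C") return(FALSE)
    nbs <- nb[[i]]
    !length(nbs) || all(el[nbs] %in% c("C", "H") | is_halogen(el[nbs]))
  }, logical(1))
}

# charged-group membership; sign per atom (+1, -1, 0)
charge_groups <- function(atoms, nb, side = c("ligand", "pocket")) {
  side <- match.arg(side)
  sgn <- integer(nrow(atoms))
  el <- .norm_element(atoms$element)
  if (side == "pocket") {
    res <- toupper(atoms$residue_name)
    nm <- toupper(atoms$atom_name)
    for (r in names(.positive_group_atoms))
      sgn[res == r & nm %in% .positive_group_atoms[[r]]] <- 1L
    for (r in names(.negative_group_atoms))
      sgn[res == r & nm %in% .negative_group_atoms[[r]]] <- -1L
    sgn[is_metal(el)] <- 1L
  } else {
    sgn[atoms$formal_charge > 0] <- 1L
    sgn[atoms$formal_charge < 0] <- -1L
    # expand a charged carboxylate-like oxygen to its resonance sibling
    neg_o <- which(sgn < 0 & el == "O")
    for (o in neg_o) {
      for (cc in nb[[o]]) {
        if (el[cc] != "C") next
        sib <- nb[[cc]]
        sgn[sib[el[sib] == "O" & atoms$degree[sib] == 1]] <- -1L
      }
    }
    # expand protonated amine: hydrogens excluded, heavy atom only
  }
  sgn
}

.new_contacts <- function(lig = integer(), poc = integer(), kind = character(),
                          dist = numeric()) {
  data.frame(ligand_atom = as.integer(lig), pocket_atom = as.integer(poc),
             kind = as.character(kind), distance = as.numeric(dist),
             stringsAsFactors = FALSE)
}

#' Detect protein-ligand interactions
#'
#' Runs the nine category detectors over a pocket/ligand pair and returns the
#' union of their contacts. Both inputs must already carry partial charges
#' (see \code{\link{assign_partial_charges}}); every contact stores the
#' Coulomb energy of its atom pair. For ring-mediated categories the stored
#' atom pair is the closest (ligand member, pocket member/cation) pair, with
#' ties broken by lowest ligand then pocket index, and the stored distance is
#' the category's criterion distance (centroid-centroid or centroid-cation).
#'
#' @param pocket a `plaig_pocket` with charges assigned.
#' @param ligand a `plaig_ligand` with charges assigned.
#' @param cutoff generic contact cutoff in Angstrom (default 3.0); bounds
#'   close-contact creation and the hydrogen-bond donor-acceptor distance.
#' @param rules rule table, see \code{\link{interaction_rules}}.
#' @return a `plaig_interactions` object: list(contacts, cutoff, rules) where
#'   contacts has columns ligand_atom, pocket_atom, kind, distance, energy.
#' @export
detect_interactions <- function(pocket, ligand, cutoff = 3.0,
                                rules = interaction_rules()) {
  stopifnot(inherits(pocket, "plaig_pocket"), inherits(ligand, "plaig_ligand"))
  la <- ligand$atoms; pa <- pocket$atoms
  if (anyNA(la$partial_charge) || anyNA(pa$partial_charge))
    stop("partial charges must be assigned on both molecules before detection")
  lxyz <- atom_xyz(la); pxyz <- atom_xyz(pa)
  nl <- nrow(la); np <- nrow(pa)
  lel <- .norm_element(la$element); pel <- .norm_element(pa$element)
  lnb <- neighbor_list(ligand$bonds, nl)
  pnb <- neighbor_list(pocket$bonds, np)
  # full ligand x pocket distance matrix (complex graphs are small by design)
  dmat <- matrix(0, nl, np)
  for (k in seq_len(np)) {
    dmat[, k] <- sqrt((lxyz[, 1] - pxyz[k, 1])^2 +
                      (lxyz[, 2] - pxyz[k, 2])^2 +
                      (lxyz[, 3] - pxyz[k, 3])^2)
  }
  contacts <- list()
  add <- function(df) contacts[[length(contacts) + 1]] <<- df

  # close contacts
  cc <- which(dmat <= cutoff & dmat > 0, arr.ind = TRUE)
  if (nrow(cc))
    add(.new_contacts(cc[, 1], cc[, 2], "close_contact", dmat[cc]))

  # hydrogen bonds (both directions)
  hb_detect <- function(donor_atoms, donor_nb, donor_xyz, donor_el,
                        acc_xyz, acc_el, lig_is_donor) {
    donors <- which(donor_el %in% c("N", "O", "S") &
                    donor_atoms$n_hydrogens > 0)
    accs <- which(acc_el %in% c("N", "O"))
    res <- .new_contacts()
    for (d in donors) {
      hyds <- donor_nb[[d]][donor_el[donor_nb[[d]]] == "H"]
      if (!length(hyds)) next
      for (a in accs) {
        dda <- if (lig_is_donor) dmat[d, a] else dmat[a, d]
        if (dda > cutoff || dda <= 0) next
        ang <- vapply(hyds, function(h)
          .angle_deg(donor_xyz[d, ], donor_xyz[h, ], acc_xyz[a, ]),
          numeric(1))
        if (any(ang >= rules$hbond_angle)) {
          if (lig_is_donor) res <- rbind(res, .new_contacts(d, a, "hydrogen_bond", dda))
          else res <- rbind(res, .new_contacts(a, d, "hydrogen_bond", dda))
        }
      }
    }
    res
  }
  add(hb_detect(la, lnb, lxyz, lel, pxyz, pel, TRUE))
  add(hb_detect(pa, pnb, pxyz, pel, lxyz, lel, FALSE))

  # halogen bonds: ligand halogen (bonded to C) to pocket O/N/S
  xs <- which(is_halogen(lel))
  accs <- which(pel %in% c("O", "N", "S"))
  for (x in xs) {
    cs <- lnb[[x]][lel[lnb[[x]]] == "C"]
    if (!length(cs)) next
    for (a in accs) {
      dxa <- dmat[x, a]
      if (dxa > cutoff || dxa <= 0) next
      ang <- vapply(cs, function(cc_)
        .angle_deg(lxyz[cc_, ], lxyz[x, ], pxyz[a, ]), numeric(1))
      if (any(ang >= rules$halogen_angle))
        add(.new_contacts(x, a, "halogen_bond", dxa))
    }
  }

  # hydrophobic contacts
  lhp <- which(hydrophobic_eligible(la, lnb))
  php <- which(hydrophobic_eligible(pa, pnb))
  if (length(lhp) && length(php)) {
    sub <- dmat[lhp, php, drop = FALSE]
    hit <- which(sub <= rules$hydrophobic_dist & sub > 0, arr.ind = TRUE)
    if (nrow(hit))
      add(.new_contacts(lhp[hit[, 1]], php[hit[, 2]], "hydrophobic", sub[hit]))
  }

  # metal contacts
  mets <- which(is_metal(pel))
  lpol <- which(lel %in% c("N", "O", "S"))
  if (length(mets) && length(lpol)) {
    sub <- dmat[lpol, mets, drop = FALSE]
    hit <- which(sub <= rules$metal_dist & sub > 0, arr.ind = TRUE)
    if (nrow(hit))
      add(.new_contacts(lpol[hit[, 1]], mets[hit[, 2]], "metal", sub[hit]))
  }

  # salt bridges
  lsgn <- charge_groups(la, lnb, "ligand")
  psgn <- charge_groups(pa, pnb, "pocket")
  psgn[is_metal(pel)] <- 0L   # metal coordination is its own category
  lq <- which(lsgn != 0 & lel != "H")
  pq <- which(psgn != 0 & pel != "H")
  for (i in lq) for (j in pq) {
    if (lsgn[i] * psgn[j] >= 0) next
    d <- dmat[i, j]
    if (d <= rules$salt_bridge_dist && d > 0)
      add(.new_contacts(i, j, "salt_bridge", d))
  }

  # ring geometry
  lrings <- find_aromatic_rings(ligand)
  prings <- find_aromatic_rings(pocket)
  closest_pair <- function(li, pj) {
    # strict-less scan in (ligand, pocket) index order: deterministic ties
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in sort(li)) for (j in sort(pj)) {
      if (dmat[i, j] < bestd) { bestd <- dmat[i, j]; best <- c(i, j) }
    }
    best
  }

  # cation-pi: ligand cation vs pocket ring, pocket cation vs ligand ring
  lcat <- which(lsgn > 0 & lel != "H")
  pcat <- which(psgn > 0 & pel != "H" & !is_metal(pel))
  for (i in lcat) for (r in prings) {
    d <- sqrt(sum((lxyz[i, ] - r$centroid)^2))
    if (d <= rules$cation_pi_dist) {
      j <- r$members[which.min(dmat[i, r$members])]
      add(.new_contacts(i, j, "cation_pi", d))
    }
  }
  for (j in pcat) for (r in lrings) {
    d <- sqrt(sum((pxyz[j, ] - r$centroid)^2))
    if (d <= rules$cation_pi_dist) {
      i <- r$members[which.min(dmat[r$members, j])]
      add(.new_contacts(i, j, "cation_pi", d))
    }
  }

  # pi-pi and T-stacking
  for (rl in lrings) for (rp in prings) {
    d <- sqrt(sum((rl$centroid - rp$centroid)^2))
    ang <- .acute_normal_angle(rl$normal, rp$normal)
    kind <- NULL
    if (d <= rules$pi_pi_dist && ang <= rules$pi_pi_angle) kind <- "pi_pi"
    if (d <= rules$t_stack_dist && ang >= rules$t_stack_angle_min &&
        (180 - ang) >= (180 - rules$t_stack_angle_max))
      kind <- c(kind, "t_stack")
    for (k in kind) {
      pr <- closest_pair(rl$members, rp$members)
      add(.new_contacts(pr[1], pr[2], k, d))
    }
  }

  contacts <- do.call(rbind, contacts)
  if (is.null(contacts)) contacts <- .new_contacts()
  if (nrow(contacts)) {
    contacts <- contacts[!duplicated(contacts[, c("ligand_atom", "pocket_atom",
                                                  "kind")]), , drop = FALSE]
    # energy of the stored atom pair at its actual interatomic distance
    r_pair <- dmat[cbind(contacts$ligand_atom, contacts$pocket_atom)]
    contacts$energy <- electrostatic_energy(
      la$partial_charge[contacts$ligand_atom],
      pa$partial_charge[contacts$pocket_atom], r_pair)
    contacts <- contacts[order(match(contacts$kind, .contact_kinds),
                               contacts$ligand_atom, contacts$pocket_atom), ,
                         drop = FALSE]
    rownames(contacts) <- NULL
  } else {
    contacts$energy <- numeric(0)
  }
  structure(list(contacts = contacts, cutoff = cutoff, rules = rules),
            class = "plaig_interactions")
}

#' @export
print.plaig_interactions <- function(x, ...) {
  cat(sprintf("<plaig_interactions> %d contacts (cutoff %.2f A)\n",
              nrow(x$contacts), x$cutoff))
  if (nrow(x$contacts)) print(table(x$contacts$kind))
  invisible(x)
}
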