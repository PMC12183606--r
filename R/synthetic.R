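# Synthetic docked complexes with known interaction ground truth.
#
# A complex is assembled from independent "sites". Each site couples a small
# ligand probe group (written to the MOL2 file, possibly as a disconnected
# fragment -- the geometry rules do not require a connected ligand) with one
# pocket residue (written to the PDB file) whose business atom is placed at
# the exact geometry of one interaction category. Sites sit on the 20
# vertices of a dodecahedron at 12 Angstrom from the origin (adjacent
# directions subtend 41.8 degrees), so planted geometries satisfy their rule
# thresholds with a stated margin (>= 0.2 Angstrom / >= 10 degrees) while
# cross-site distances stay far outside every threshold. Residue templates
# are rigid idealized fragments with strictly separated non-bonded atoms, so
# distance-based bond perception recovers exactly the intended connectivity.
#
# Ground truth is computed from the file-rounded coordinates using the
# template-declared atom roles (donor/acceptor/halogen/charge/ring/
# hydrophobic eligibility) and the same rule table the detector ships --
# but independently of the detector's perception machinery.

.site_kinds <- c("hydrogen_bond", "halogen_bond", "hydrophobic", "metal",
                 "salt_bridge", "cation_pi", "pi_pi", "t_stack",
                 "close_contact")

# "distant" plants a non-interacting site: the pocket residue sits 20 A from
# its ligand probe, far outside every threshold
.fixture_kinds <- c(.site_kinds, "distant")

.dodecahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)),
    data.frame(x = 0, y = c(-1, -1, 1, 1) / phi, z = c(-phi, phi, -phi, phi)),
    data.frame(x = c(-1, -1, 1, 1) / phi, y = c(-phi, phi, -phi, phi), z = 0),
    data.frame(x = c(-phi, phi, -phi, phi), y = 0, z = c(-1, -1, 1, 1) / phi))
  m <- as.matrix(v)
  m / sqrt(rowSums(m^2))
}

.hexagon <- function(r = 1.4, offset_deg = 0, plane = c("vw", "uv")) {
  ang <- (60 * (0:5) + offset_deg) * pi / 180
  if (match.arg(plane) == "vw")
    cbind(0, r * cos(ang), r * sin(ang))
  else
    cbind(r * cos(ang), r * sin(ang), 0)
}

# each template: lig = list(names, types, elements, xyz, bonds, roles),
# poc = list(names, elements, xyz, residue, roles). Coordinates are local
# (u = outward site axis, v/w = lateral).
.site_templates <- function() {
  L <- function(xyz, names, types, bonds = NULL, donors = NULL,
                halogens = NULL, hphob = integer(), cation = integer(),
                anion = integer(), ring = NULL) {
    list(xyz = xyz, names = names, types = types,
         elements = .sybyl_element(types),
         bonds = bonds, donors = donors, halogens = halogens, hphob = hphob,
         cation = cation, anion = anion, ring = ring)
  }
  P <- function(xyz, names, elements, residue, hphob = integer(),
                cation = integer(), anion = integer(), metal = integer(),
                ring = NULL) {
    list(xyz = xyz, names = names, elements = elements, residue = residue,
         hphob = hphob, cation = cation, anion = anion, metal = metal,
         ring = ring)
  }
  ser_tail <- rbind(c(4.18, 0, 0), c(4.69, -1.44, 0), c(5.98, -1.44, 0.69))
  hex0 <- .hexagon(1.4, 0, "vw")
  hex15 <- .hexagon(1.4, 15, "vw")
  hex15[, 1] <- 4.3
  tyr_ang <- (60 * (0:5) + 15) * pi / 180
  tyr_ring <- cbind(4.4 + 1.4 * cos(tyr_ang), 1.4 * sin(tyr_ang), 0)
  list(
    hydrogen_bond = list(
      lig = L(rbind(c(-2.47, 0, 0), c(0, 0, 0), c(1.01, 0, 0)),
              c("C1", "N1", "H1"), c("C.3", "N.3", "H"),
              bonds = rbind(c(1, 2), c(2, 3)),
              donors = list(list(D = 2L, H = 3L))),
      poc = P(rbind(c(2.75, 0, 0), ser_tail),
              c("OG", "CB", "CA", "N"), c("O", "C", "C", "N"), "SER")),
    halogen_bond = list(
      lig = L(rbind(c(-1.77, 0, 0), c(0, 0, 0)),
              c("C1", "CL1"), c("C.3", "Cl"),
              bonds = rbind(c(1, 2)),
              halogens = list(list(X = 2L, C = 1L)), hphob = 1L),
      poc = P(rbind(c(2.75, 0, 0), c(4.18, 0, 0), c(4.69, 0.72, 1.24),
                    c(4.69, -1.44, 0), c(5.98, -1.44, 0.69)),
              c("OG1", "CB", "CG2", "CA", "N"), c("O", "C", "C", "C", "N"),
              "THR", hphob = 3L)),
    hydrophobic = list(
      lig = L(rbind(c(0, 0, 0), c(-1.53, 0, 0)), c("C1", "C2"),
              c("C.3", "C.3"), bonds = rbind(c(1, 2)), hphob = c(1L, 2L)),
      poc = P(rbind(c(3.6, 0, 0), c(5.13, 0, 0), c(5.62, 1.39, 0),
                    c(5.64, -0.72, 1.25), c(6.75, -1.09, 1.62)),
              c("CB", "CA", "N", "C", "O"), c("C", "C", "N", "C", "O"),
              "ALA", hphob = 1L)),
    metal = list(
      lig = L(rbind(c(-1.43, 0, 0), c(0, 0, 0)), c("C1", "O1"),
              c("C.3", "O.3"), bonds = rbind(c(1, 2))),
      poc = P(rbind(c(2.2, 0, 0)), "ZN", "ZN", "ZN", metal = 1L)),
    salt_bridge = list(
      lig = L(rbind(c(-1.47, 0, 0), c(0, 0, 0)), c("C1", "N1"),
              c("C.3", "N.4"), bonds = rbind(c(1, 2)), cation = 2L),
      poc = P(rbind(c(4, 0, 0), c(5.25, 0, 0), c(5.875, 1.083, 0),
                    c(6.01, -1.316, 0), c(7.54, -1.316, 0), c(8.03, 0.07, 0)),
              c("OD1", "CG", "OD2", "CB", "CA", "N"),
              c("O", "C", "O", "C", "C", "N"), "ASP",
              anion = c(1L, 3L), hphob = 4L)),
    cation_pi = list(
      lig = L(hex0, paste0("C", 1:6), rep("C.ar", 6),
              bonds = cbind(1:6, c(2:6, 1)), hphob = 1:6, ring = 1:6),
      poc = P(rbind(c(4.5, 0.35, 0), c(5.97, 0.35, 0), c(7.5, 0.35, 0),
                    c(9.03, 0.35, 0), c(10.56, 0.35, 0), c(12.09, 0.35, 0),
                    c(12.58, 1.74, 0)),
              c("NZ", "CE", "CD", "CG", "CB", "CA", "N"),
              c("N", "C", "C", "C", "C", "C", "N"), "LYS",
              cation = 1L, hphob = 3:5)),
    pi_pi = list(
      lig = L(hex0, paste0("C", 1:6), rep("C.ar", 6),
              bonds = cbind(1:6, c(2:6, 1)), hphob = 1:6, ring = 1:6),
      poc = P(rbind(hex15, c(5.52, 2.20, 0.59), c(6.87, 2.66, 1.05),
                    c(7.36, 4.05, 1.05)),
              c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB", "CA", "N"),
              rep(c("C", "N"), c(8, 1)), "PHE",
              hphob = c(1:6, 7L), ring = 1:6)),
    t_stack = list(
      lig = L(hex0, paste0("C", 1:6), rep("C.ar", 6),
              bonds = cbind(1:6, c(2:6, 1)), hphob = 1:6, ring = 1:6),
      poc = P(rbind(tyr_ring[c(2, 3, 4, 5, 6, 1), , drop = FALSE],
                    c(3.69, -2.66, 0), c(5.15, 2.82, 0),
                    c(5.99, 3.92, 0.64), c(6.48, 5.31, 0.64)),
              c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH", "CB", "CA",
                "N"),
              c(rep("C", 6), "O", "C", "C", "N"), "TYR",
              hphob = c(1:3, 5:6, 8L), ring = 1:6)),   # CZ bonded to OH: not hydrophobic
    close_contact = list(
      lig = L(rbind(c(0, 0, 0), c(-1.53, 0, 0)), c("C1", "C2"),
              c("C.3", "C.3"), bonds = rbind(c(1, 2)), hphob = c(1L, 2L)),
      poc = P(rbind(c(2.8, 0, 0), c(4.03, 0, 0), c(4.54, 1.43, 0),
                    c(5.83, 1.43, 0.69)),
              c("O", "C", "CA", "N"), c("O", "C", "C", "N"), "GLY")),
    distant = list(
      lig = L(rbind(c(0, 0, 0), c(-1.53, 0, 0)), c("C1", "C2"),
              c("C.3", "C.3"), bonds = rbind(c(1, 2)), hphob = c(1L, 2L)),
      poc = P(rbind(c(22.8, 0, 0), c(24.03, 0, 0), c(24.54, 1.43, 0),
                    c(25.83, 1.43, 0.69)),
              c("O", "C", "CA", "N"), c("O", "C", "C", "N"), "GLY")))
}

#' Synthetic-complex specification
#'
#' @param interactions named integer vector: how many sites of each
#'   interaction kind to plant (names from `hydrogen_bond`, `halogen_bond`,
#'   `hydrophobic`, `metal`, `salt_bridge`, `cation_pi`, `pi_pi`, `t_stack`,
#'   `close_contact`).
#' @param jitter positional jitter sd in Angstrom applied as a rigid random
#'   translation of each pocket residue (default 0).
#' @param seed RNG seed (jitter only; the construction is otherwise
#'   deterministic).
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(interactions = c(hydrogen_bond = 1), jitter = 0,
                         seed = 1L) {
  bad <- setdiff(names(interactions), .fixture_kinds)
  if (length(bad)) stop("unknown interaction kind(s): ",
                        paste(bad, collapse = ", "))
  stopifnot(all(interactions >= 0), jitter >= 0)
  structure(list(interactions = interactions, jitter = jitter,
                 seed = as.integer(seed)), class = "fixture_spec")
}

.local_frame <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(u = u, v = v, w = w)
}

.to_global <- function(local, anchor, fr) {
  t(apply(local, 1, function(l)
    anchor + l[1] * fr$u + l[2] * fr$v + l[3] * fr$w))
}

#' Generate one synthetic docked complex
#'
#' Builds the ligand MOL2 and pocket PDB text for the requested planted
#' interactions, plus the ground-truth contact table computed from the
#' file-rounded coordinates and the declared atom roles. Parsing the two
#' files and running \code{\link{detect_interactions}} reproduces the
#' ground truth exactly (also under jitter: the truth is recomputed from the
#' jittered coordinates).
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param radius distance from the origin to the site anchors (default 12).
#' @return list(ligand_mol2, protein_pdb (character vectors of file lines),
#'   truth (data.frame ligand_atom/pocket_atom/kind/distance), counts).
#' @export
make_complex <- function(spec, radius = 12) {
  stopifnot(inherits(spec, "fixture_spec"))
  counts <- spec$interactions
  total <- sum(counts)
  dirs <- .dodecahedron()
  if (total > nrow(dirs))
    stop("infeasible geometry request: ", total,
         " sites exceed the ", nrow(dirs), " available well-separated",
         " directions")
  set.seed(spec$seed)
  templates <- .site_templates()
  lig_atoms <- list(); lig_bonds <- list(); poc_atoms <- list()
  roles <- list(donors = list(), halogens = list(), lig_hphob = integer(),
                lig_cation = integer(), lig_anion = integer(),
                lig_rings = list(), poc_hphob = integer(),
                poc_cation = integer(), poc_anion = integer(),
                poc_metal = integer(), poc_rings = list())
  site_idx <- 0L
  nl <- 0L; np <- 0L; nres <- 0L
  for (kind in .fixture_kinds) {
    k <- counts[kind]
    if (is.na(k) || k < 1) next
    for (rep_ in seq_len(k)) {
      site_idx <- site_idx + 1L
      fr <- .local_frame(dirs[site_idx, ])
      anchor <- radius * dirs[site_idx, ]
      tp <- templates[[kind]]
      # ligand probe
      gxyz <- round(.to_global(tp$lig$xyz, anchor, fr), 4)
      na_ <- nrow(gxyz)
      lig_atoms[[site_idx]] <- data.frame(
        name = paste0(tp$lig$names, "_", site_idx), type = tp$lig$types,
        element = tp$lig$elements, x = gxyz[, 1], y = gxyz[, 2],
        z = gxyz[, 3], stringsAsFactors = FALSE)
      if (!is.null(tp$lig$bonds))
        lig_bonds[[site_idx]] <- tp$lig$bonds + nl
      for (d in tp$lig$donors %||% list())
        roles$donors[[length(roles$donors) + 1]] <-
          list(D = d$D + nl, H = d$H + nl)
      for (h in tp$lig$halogens %||% list())
        roles$halogens[[length(roles$halogens) + 1]] <-
          list(X = h$X + nl, C = h$C + nl)
      roles$lig_hphob <- c(roles$lig_hphob, tp$lig$hphob + nl)
      roles$lig_cation <- c(roles$lig_cation, tp$lig$cation + nl)
      roles$lig_anion <- c(roles$lig_anion, tp$lig$anion + nl)
      if (!is.null(tp$lig$ring))
        roles$lig_rings[[length(roles$lig_rings) + 1]] <- tp$lig$ring + nl
      nl <- nl + na_
      # pocket residue (rigid jitter translation, then file rounding)
      shift <- if (spec$jitter > 0) rnorm(3, 0, spec$jitter) else c(0, 0, 0)
      pxyz <- .to_global(tp$poc$xyz, anchor, fr)
      pxyz <- round(sweep(pxyz, 2, shift, "+"), 3)
      nres <- nres + 1L
      poc_atoms[[site_idx]] <- data.frame(
        atom_name = tp$poc$names, element = tp$poc$elements,
        residue_name = tp$poc$residue, residue_seq = nres, chain = "A",
        x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3], stringsAsFactors = FALSE)
      roles$poc_hphob <- c(roles$poc_hphob, tp$poc$hphob + np)
      roles$poc_cation <- c(roles$poc_cation, tp$poc$cation + np)
      roles$poc_anion <- c(roles$poc_anion, tp$poc$anion + np)
      roles$poc_metal <- c(roles$poc_metal, tp$poc$metal + np)
      if (!is.null(tp$poc$ring))
        roles$poc_rings[[length(roles$poc_rings) + 1]] <- tp$poc$ring + np
      np <- np + nrow(pxyz)
    }
  }
  if (!site_idx) stop("spec plants no interactions")
  lig <- do.call(rbind, lig_atoms)
  poc <- do.call(rbind, poc_atoms)
  bonds <- do.call(rbind, lig_bonds)
  # clash floor between the two molecules
  lx <- as.matrix(lig[, c("x", "y", "z")])
  px <- as.matrix(poc[, c("x", "y", "z")])
  for (k in seq_len(nrow(px))) {
    d2 <- (lx[, 1] - px[k, 1])^2 + (lx[, 2] - px[k, 2])^2 +
      (lx[, 3] - px[k, 3])^2
    if (any(d2 < 1.5^2))
      stop("infeasible geometry request: ligand/pocket atoms closer than ",
           "1.5 Angstrom (jitter too large for the planted margins?)")
  }
  truth <- .truth_from_roles(lig, poc, bonds, roles)
  list(ligand_mol2 = .mol2_lines(lig, bonds),
       protein_pdb = .pdb_lines(poc),
       truth = truth, counts = counts, roles = roles)
}

.mol2_lines <- function(lig, bonds) {
  nb <- if (is.null(bonds)) 0 else nrow(bonds)
  header <- c("@<TRIPOS>MOLECULE", "synthetic-ligand",
              sprintf(" %d %d 1", nrow(lig), nb), "SMALL", "USER_CHARGES",
              "@<TRIPOS>ATOM")
  atoms <- sprintf("%7d %-10s %9.4f %9.4f %9.4f %-8s %3d %-8s %9.4f",
                   seq_len(nrow(lig)), lig$name, lig$x, lig$y, lig$z,
                   lig$type, 1L, "LIG1", 0)
  bl <- "@<TRIPOS>BOND"
  if (nb) {
    ord <- ifelse(grepl("\\.ar$", lig$type[bonds[, 1]]) &
                  grepl("\\.ar$", lig$type[bonds[, 2]]), "ar", "1")
    bl <- c(bl, sprintf("%6d %5d %5d %s", seq_len(nb), bonds[, 1],
                        bonds[, 2], ord))
  }
  c(header, atoms, bl)
}

.pdb_lines <- function(poc) {
  rec <- ifelse(poc$residue_name %in% .standard_residues, "ATOM", "HETATM")
  name <- ifelse(nchar(poc$atom_name) < 4, paste0(" ", poc$atom_name),
                 poc$atom_name)
  c(sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, seq_len(nrow(poc)), name, poc$residue_name, poc$chain,
            poc$residue_seq, poc$x, poc$y, poc$z, 1, 0, poc$element),
    "END")
}

#' Write a synthetic complex to disk
#' @param cx result of \code{\link{make_complex}}.
#' @param dir output directory (created if missing).
#' @param basename file stem (default "complex").
#' @return named paths (ligand, protein, truth).
#' @export
write_complex <- function(cx, dir, basename = "complex") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- file.path(dir, paste0(basename, "_ligand.mol2"))
  pp <- file.path(dir, paste0(basename, "_pocket.pdb"))
  tp <- file.path(dir, paste0(basename, "_truth.json"))
  writeLines(cx$ligand_mol2, lp)
  writeLines(cx$protein_pdb, pp)
  jsonlite::write_json(cx$truth, tp, digits = NA)
  c(ligand = lp, protein = pp, truth = tp)
}

# role-driven ground-truth enumeration on rounded coordinates
.truth_from_roles <- function(lig, poc, bonds, roles,
                              cutoff = 3.0, rules = interaction_rules()) {
  lx <- as.matrix(lig[, c("x", "y", "z")])
  px <- as.matrix(poc[, c("x", "y", "z")])
  nl <- nrow(lx); np <- nrow(px)
  dm <- matrix(0, nl, np)
  for (k in seq_len(np))
    dm[, k] <- sqrt((lx[, 1] - px[k, 1])^2 + (lx[, 2] - px[k, 2])^2 +
                    (lx[, 3] - px[k, 3])^2)
  out <- list()
  emit <- function(i, j, kind, d)
    out[[length(out) + 1]] <<- data.frame(ligand_atom = i, pocket_atom = j,
                                          kind = kind, distance = d,
                                          stringsAsFactors = FALSE)
  pel <- .norm_element(poc$element)
  lel <- .norm_element(lig$element)
  for (i in seq_len(nl)) for (j in seq_len(np))
    if (dm[i, j] <= cutoff && dm[i, j] > 0)
      emit(i, j, "close_contact", dm[i, j])
  for (d in roles$donors) {
    for (j in which(pel %in% c("N", "O"))) {
      if (dm[d$D, j] > cutoff) next
      ang <- .angle_deg(lx[d$D, ], lx[d$H, ], px[j, ])
      if (ang >= rules$hbond_angle) emit(d$D, j, "hydrogen_bond", dm[d$D, j])
    }
  }
  for (h in roles$halogens) {
    for (j in which(pel %in% c("O", "N", "S"))) {
      if (dm[h$X, j] > cutoff) next
      ang <- .angle_deg(lx[h$C, ], lx[h$X, ], px[j, ])
      if (ang >= rules$halogen_angle) emit(h$X, j, "halogen_bond", dm[h$X, j])
    }
  }
  for (i in roles$lig_hphob) for (j in roles$poc_hphob)
    if (dm[i, j] <= rules$hydrophobic_dist)
      emit(i, j, "hydrophobic", dm[i, j])
  for (i in which(lel %in% c("N", "O", "S"))) for (j in roles$poc_metal)
    if (dm[i, j] <= rules$metal_dist) emit(i, j, "metal", dm[i, j])
  for (i in roles$lig_cation) for (j in roles$poc_anion)
    if (dm[i, j] <= rules$salt_bridge_dist) emit(i, j, "salt_bridge", dm[i, j])
  for (i in roles$lig_anion) for (j in roles$poc_cation)
    if (dm[i, j] <= rules$salt_bridge_dist) emit(i, j, "salt_bridge", dm[i, j])
  ring_geom <- function(x, members) {
    ctr <- colMeans(x[members, , drop = FALSE])
    sv <- svd(sweep(x[members, , drop = FALSE], 2, ctr))
    n <- sv$v[, 3]; list(ctr = ctr, n = n / sqrt(sum(n^2)))
  }
  nearest_pair <- function(li, pj) {
    best <- c(NA, NA); bd <- Inf
    for (i in sort(li)) for (j in sort(pj))
      if (dm[i, j] < bd) { bd <- dm[i, j]; best <- c(i, j) }
    best
  }
  for (i in roles$lig_cation) for (rg in roles$poc_rings) {
    g <- ring_geom(px, rg)
    d <- sqrt(sum((lx[i, ] - g$ctr)^2))
    if (d <= rules$cation_pi_dist)
      emit(i, rg[which.min(dm[i, rg])], "cation_pi", d)
  }
  for (j in roles$poc_cation) for (rg in roles$lig_rings) {
    g <- ring_geom(lx, rg)
    d <- sqrt(sum((px[j, ] - g$ctr)^2))
    if (d <= rules$cation_pi_dist)
      emit(rg[which.min(dm[rg, j])], j, "cation_pi", d)
  }
  for (rl in roles$lig_rings) for (rp in roles$poc_rings) {
    gl <- ring_geom(lx, rl); gp <- ring_geom(px, rp)
    d <- sqrt(sum((gl$ctr - gp$ctr)^2))
    ang <- acos(pmin(1, abs(sum(gl$n * gp$n)))) * 180 / pi
    kinds <- character()
    if (d <= rules$pi_pi_dist && ang <= rules$pi_pi_angle)
      kinds <- "pi_pi"
    if (d <= rules$t_stack_dist && ang >= rules$t_stack_angle_min &&
        ang <= rules$t_stack_angle_max)
      kinds <- c(kinds, "t_stack")
    for (k in kinds) {
      pr <- nearest_pair(rl, rp)
      emit(pr[1], pr[2], k, d)
    }
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    return(data.frame(ligand_atom = integer(), pocket_atom = integer(),
                      kind = character(), distance = numeric()))
  tab <- tab[!duplicated(tab[, c("ligand_atom", "pocket_atom", "kind")]), ,
             drop = FALSE]
  tab <- tab[order(match(tab$kind, .contact_kinds), tab$ligand_atom,
                   tab$pocket_atom), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Synthetic-dataset specification
#'
#' Affinities are linear in the planted interaction counts:
#' `pKd = b0 + sum_k beta_k * count_k + N(0, sigma)`.
#'
#' @param n number of complexes.
#' @param coefficients named vector of per-kind effects in pKd units. The
#'   default spans hydrogen bonds through T-stacks at chemically plausible
#'   magnitudes; `close_contact` acts as a zero-effect distractor.
#' @param intercept baseline affinity b0 (default 4, a weak binder).
#' @param sigma affinity noise sd in pKd units (default 0.3).
#' @param max_count maximum planted sites per kind (default 2).
#' @param jitter positional jitter sd passed to the fixtures (default 0).
#' @param seed RNG seed.
#' @return a `dataset_spec`.
#' @export
dataset_spec <- function(n = 500L,
                         coefficients = c(hydrogen_bond = 0.6,
                                          halogen_bond = 0.4,
                                          hydrophobic = 0.3, metal = 0.8,
                                          salt_bridge = 0.7, cation_pi = 0.5,
                                          pi_pi = 0.5, t_stack = 0.4,
                                          close_contact = 0),
                         intercept = 4, sigma = 0.3, max_count = 2L,
                         jitter = 0, seed = 1L) {
  stopifnot(n >= 1, sigma >= 0, max_count >= 1,
            all(names(coefficients) %in% .site_kinds))
  structure(list(n = as.integer(n), coefficients = coefficients,
                 intercept = intercept, sigma = sigma,
                 max_count = as.integer(max_count), jitter = jitter,
                 seed = as.integer(seed)), class = "dataset_spec")
}

#' Generate a synthetic graph dataset with known coefficients
#'
#' Draws per-kind planted counts uniformly from 0..max_count for each
#' complex, generates the complex, runs it through the real pipeline
#' (parse, Gasteiger charges, interaction detection, graph build) and
#' attaches the linear-model affinity as the target.
#'
#' @param spec a \code{\link{dataset_spec}}.
#' @param cutoff contact cutoff for detection/graph build (default 3.0).
#' @param progress print a dot every 50 complexes.
#' @param build run the full pipeline and return graphs (default TRUE);
#'   FALSE draws only counts and targets, for statistical checks.
#' @return list(graphs (NULL when `build = FALSE`), targets, counts
#'   (n x kinds matrix), coefficients, intercept, sigma).
#' @export
make_dataset <- function(spec, cutoff = 3.0, progress = FALSE,
                         build = TRUE) {
  stopifnot(inherits(spec, "dataset_spec"))
  set.seed(spec$seed)
  kinds <- names(spec$coefficients)
  counts <- matrix(sample(0:spec$max_count, spec$n * length(kinds),
                          replace = TRUE),
                   spec$n, length(kinds), dimnames = list(NULL, kinds))
  # every complex needs at least one site to be a complex at all
  empty <- rowSums(counts) == 0
  counts[empty, which.max(kinds == "close_contact")] <- 1L
  noise <- rnorm(spec$n, 0, spec$sigma)
  targets <- spec$intercept +
    as.numeric(counts %*% spec$coefficients[kinds]) + noise
  if (!build)
    return(list(graphs = NULL, targets = targets, counts = counts,
                coefficients = spec$coefficients,
                intercept = spec$intercept, sigma = spec$sigma))
  tmp <- tempfile("plaig_ds_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  graphs <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    fs <- fixture_spec(counts[i, ], jitter = spec$jitter,
                       seed = spec$seed + i)
    cx <- make_complex(fs)
    paths <- write_complex(cx, tmp, sprintf("c%05d", i))
    lig <- assign_partial_charges(parse_ligand(paths["ligand"], "mol2"))
    poc <- assign_partial_charges(parse_protein_pdb(paths["protein"]))
    ints <- detect_interactions(poc, lig, cutoff = cutoff)
    graphs[[i]] <- build_graph(poc, lig, ints, cutoff = cutoff,
                               id = sprintf("synth-%05d", i),
                               target = targets[i])
    unlink(paths)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(graphs = graphs, targets = targets, counts = counts,
       coefficients = spec$coefficients, intercept = spec$intercept,
       sigma = spec$sigma)
}
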