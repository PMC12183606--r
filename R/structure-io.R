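# Molecular containers and file I/O.
#
# Two S3 containers are used throughout:
#   plaig_ligand: list(atoms = <atom data.frame>, bonds = data.frame(i, j, order))
#   plaig_pocket: list(atoms = <atom data.frame>, bonds = ...) with atoms grouped
#                 by (chain, residue_seq, residue_name)
# The atom table has one row per atom with the columns produced by
# `empty_atoms()`. Coordinates are Angstrom, charges in units of the
# elementary charge. Atom indices are 1-based row numbers.

empty_atoms <- function(n = 0) {
  data.frame(
    element = character(n), atom_name = character(n),
    residue_name = character(n), residue_seq = integer(n),
    chain = character(n), x = numeric(n), y = numeric(n), z = numeric(n),
    formal_charge = integer(n), partial_charge = rep(NA_real_, n),
    is_aromatic = logical(n), hybridization = rep("UNSPECIFIED", n),
    degree = integer(n), n_hydrogens = integer(n), mass = numeric(n),
    stringsAsFactors = FALSE
  )
}

atom_xyz <- function(x) {
  a <- if (is.data.frame(x)) x else x$atoms
  cbind(a$x, a$y, a$z)
}

n_atoms <- function(x) nrow(x$atoms)

validate_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (nrow(atoms) && any(!atoms$hybridization %in% .hybridizations))
    stop("invalid hybridization label")
  invisible(atoms)
}

validate_bonds <- function(bonds, n) {
  if (is.null(bonds) || !nrow(bonds)) return(invisible(bonds))
  if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
    stop("bond references an atom index outside the molecule")
  if (any(bonds$i == bonds$j)) stop("self-bond in bond list")
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  if (anyDuplicated(key)) stop("duplicate bond in bond list")
  invisible(bonds)
}

new_ligand <- function(atoms, bonds) {
  validate_atoms(atoms)
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          order = character())
  validate_bonds(bonds, nrow(atoms))
  atoms <- fill_connectivity_counts(atoms, bonds)
  structure(list(atoms = atoms, bonds = bonds), class = "plaig_ligand")
}

new_pocket <- function(atoms, bonds = NULL) {
  validate_atoms(atoms)
  if (!is.null(bonds)) {
    validate_bonds(bonds, nrow(atoms))
    atoms <- fill_connectivity_counts(atoms, bonds)
  }
  structure(list(atoms = atoms, bonds = bonds), class = "plaig_pocket")
}

#' @export
print.plaig_ligand <- function(x, ...) {
  cat(sprintf("<plaig_ligand> %d atoms, %d bonds\n",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' @export
print.plaig_pocket <- function(x, ...) {
  key <- residue_key(x$atoms)
  cat(sprintf("<plaig_pocket> %d atoms in %d residues\n",
              nrow(x$atoms), length(unique(key))))
  invisible(x)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$residue_seq, atoms$residue_name, sep = "|")
}

fill_connectivity_counts <- function(atoms, bonds) {
  n <- nrow(atoms)
  deg <- integer(n); nh <- integer(n)
  if (!is.null(bonds) && nrow(bonds)) {
    tab <- tabulate(c(bonds$i, bonds$j), nbins = n)
    deg <- tab
    hyd <- .norm_element(atoms$element) == "H"
    for (k in seq_len(nrow(bonds))) {
      if (hyd[bonds$j[k]]) nh[bonds$i[k]] <- nh[bonds$i[k]] + 1L
      if (hyd[bonds$i[k]]) nh[bonds$j[k]] <- nh[bonds$j[k]] + 1L
    }
  }
  atoms$degree <- deg
  atoms$n_hydrogens <- nh
  atoms$mass <- element_mass(atoms$element)
  atoms
}

# ---------------------------------------------------------------------------
# Bond perception from interatomic distances.

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' \code{tol} times the sum of their covalent radii (and is above a
#' 0.4 Angstrom clash floor). Uses a spatial grid so perception stays fast on
#' whole proteins.
#'
#' @param atoms atom table (see package containers).
#' @param tol multiplier on the covalent-radius sum, default 1.3.
#' @return data.frame with columns i, j (i < j) and order (all "1").
#' @keywords internal
perceive_bonds <- function(atoms, tol = 1.3) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(), j = integer(), order = character()))
  xyz <- atom_xyz(atoms)
  rc <- covalent_radius(atoms$element)
  rc[is.na(rc)] <- 0.8
  cell <- 2 * max(rc) * tol + 1e-9
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  cid <- paste(key[, 1], key[, 2], key[, 3])
  cells <- split(seq_len(n), cid)
  coords <- unique(key)
  res_i <- integer(0); res_j <- integer(0)
  # compare each cell with itself and forward half of its 26 neighbours
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[order(offs$dx, offs$dy, offs$dz), ]
  for (ci in names(cells)) {
    a <- cells[[ci]]
    base <- as.numeric(strsplit(ci, " ")[[1]])
    for (r in seq_len(nrow(offs))) {
      nb <- paste(base[1] + offs$dx[r], base[2] + offs$dy[r], base[3] + offs$dz[r])
      b <- cells[[nb]]
      if (is.null(b)) next
      if (nb < ci) next            # visit each unordered cell pair once
      if (nb == ci) {
        if (length(a) < 2) next
        pr <- utils::combn(a, 2)
        ii <- pr[1, ]; jj <- pr[2, ]
      } else {
        ii <- rep(a, each = length(b)); jj <- rep(b, length(a))
      }
      d2 <- rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2)
      lim <- (tol * (rc[ii] + rc[jj]))^2
      keep <- d2 <= lim & d2 >= 0.16
      if (any(keep)) {
        res_i <- c(res_i, pmin(ii[keep], jj[keep]))
        res_j <- c(res_j, pmax(ii[keep], jj[keep]))
      }
    }
  }
  ord <- order(res_i, res_j)
  data.frame(i = res_i[ord], j = res_j[ord],
             order = rep("1", length(res_i)), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Residue chemistry templates (aromaticity, hybridization, formal charge).

.residue_sp2 <- list(
  backbone = c("C", "O", "OXT"),
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"),
  ASN = c("CG", "OD1", "ND2"), GLN = c("CD", "OE1", "NE2"),
  ARG = c("CZ", "NE", "NH1", "NH2")
)

.residue_aromatic <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# rings used for pi-geometry on the pocket side (atom-name sets per residue)
.residue_rings <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# formally charged protein groups: representative atom carries the unit charge
.residue_formal_charge <- list(
  LYS = c(NZ = 1L), ARG = c(NH1 = 1L), ASP = c(OD2 = -1L), GLU = c(OE2 = -1L)
)

# full charged-group membership used by the salt-bridge / cation-pi detectors
.positive_group_atoms <- list(
  LYS = "NZ", ARG = c("NH1", "NH2", "NE"), HIS = c("ND1", "NE2"))
.negative_group_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

annotate_pocket_chemistry <- function(atoms) {
  el <- .norm_element(atoms$element)
  res <- toupper(atoms$residue_name)
  nm <- toupper(atoms$atom_name)
  hyb <- rep("UNSPECIFIED", nrow(atoms))
  hyb[el %in% c("C", "N", "O")] <- "SP3"
  hyb[el == "S"] <- "SP3"
  hyb[el == "P"] <- "SP3"
  hyb[el == "H"] <- "S"
  hyb[is_halogen(el)] <- "SP3"
  hyb[is_metal(el)] <- "OTHER"
  arom <- rep(FALSE, nrow(atoms))
  fc <- integer(nrow(atoms))
  # amide nitrogens of the backbone are planar
  hyb[nm == "N" & res %in% .standard_residues] <- "SP2"
  hyb[nm %in% .residue_sp2$backbone & res %in% .standard_residues] <- "SP2"
  for (r in names(.residue_sp2)) {
    if (r == "backbone") next
    hyb[res == r & nm %in% .residue_sp2[[r]]] <- "SP2"
  }
  for (r in names(.residue_aromatic)) {
    hit <- res == r & nm %in% .residue_aromatic[[r]]
    arom[hit] <- TRUE
    hyb[hit] <- "SP2"
  }
  for (r in names(.residue_formal_charge)) {
    chg <- .residue_formal_charge[[r]]
    for (a in names(chg)) fc[res == r & nm == a] <- chg[[a]]
  }
  ion <- is_metal(el)
  fc[ion] <- as.integer(.metal_formal_charge[el[ion]])
  atoms$hybridization <- hyb
  atoms$is_aromatic <- arom
  atoms$formal_charge <- fc
  atoms
}

# ---------------------------------------------------------------------------
# PDB parsing (protein side) via bio3d, with alternate-location resolution.

#' Parse a protein PDB file
#'
#' Reads ATOM/HETATM records (model 1 only), drops waters, resolves alternate
#' locations to the highest-occupancy copy (first record on ties), ignores
#' insertion codes, and annotates residue-template chemistry (aromaticity,
#' hybridization, formal charges of Lys/Arg/Asp/Glu side chains and metal
#' ions). Covalent bonds are perceived from interatomic distances so that
#' hydrogen counts and degrees are available for featurization.
#'
#' @param path path to a PDB file.
#' @param perceive also perceive bonds (default TRUE; set FALSE to skip the
#'   distance scan on very large structures when connectivity is not needed).
#' @return a `plaig_pocket` object (the container is the same whether it holds
#'   a full protein or an extracted pocket).
#' @export
parse_protein_pdb <- function(path, perceive = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[!toupper(at$resid) %in% .water_residues, , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no non-water atoms in ", path)
  if (any(!is.na(at$insert)))
    message("insertion codes present in ", basename(path), "; ignored")
  # alternate locations: keep the highest-occupancy copy per atom site
  alt <- !is.na(at$alt) & at$alt != "" & at$alt != "A" |
    (!is.na(at$alt) & at$alt == "A")
  if (any(!is.na(at$alt))) {
    site <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (s in unique(site[!is.na(at$alt)])) {
      idx <- which(site == s)
      if (length(idx) > 1) {
        best <- idx[which.max(occ[idx])]   # first index wins ties
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  atoms <- empty_atoms(nrow(at))
  el <- at$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- gsub("[^A-Za-z]", "", substr(at$elety[miss], 1, 2))
  atoms$element <- .norm_element(el)
  atoms$atom_name <- at$elety
  atoms$residue_name <- toupper(at$resid)
  atoms$residue_seq <- as.integer(at$resno)
  atoms$chain <- ifelse(is.na(at$chain), "A", at$chain)
  atoms$x <- at$x; atoms$y <- at$y; atoms$z <- at$z
  atoms <- annotate_pocket_chemistry(atoms)
  bonds <- if (perceive) perceive_bonds(atoms) else NULL
  new_pocket(atoms, bonds)
}

# ---------------------------------------------------------------------------
# Ligand parsing: MOL2 (TRIPOS), PDB, PDBQT.

.sybyl_hybridization <- function(type) {
  base <- sub("\\..*$", "", type)
  suffix <- ifelse(grepl("\\.", type), sub("^[^.]*\\.", "", type), "")
  hyb <- rep("UNSPECIFIED", length(type))
  hyb[suffix == "1"] <- "SP"
  hyb[suffix %in% c("2", "ar", "co2", "am", "pl3", "O2")] <- "SP2"
  hyb[suffix %in% c("3", "4", "o", "o2", "t3p", "spc")] <- "SP3"
  hyb[base %in% c("H")] <- "S"
  hyb[base %in% c("F", "Cl", "Br", "I")] <- "SP3"
  hyb[toupper(base) %in% .metal_symbols] <- "OTHER"
  hyb
}

.sybyl_element <- function(type) {
  base <- sub("\\..*$", "", type)
  .norm_element(base)
}

parse_ligand_mol2 <- function(path) {
  m <- tryCatch(suppressWarnings(bio3d::read.mol2(path)),
                error = function(e) stop("MOL2 parse error in ", path, ": ",
                                         conditionMessage(e)))
  at <- m$atom
  if (!nrow(at)) stop("empty structure: no atoms in ", path)
  atoms <- empty_atoms(nrow(at))
  type <- at$elety
  atoms$element <- .sybyl_element(type)
  atoms$atom_name <- at$elena
  atoms$residue_name <- "LIG"
  atoms$residue_seq <- 1L
  atoms$chain <- "L"
  atoms$x <- at$x; atoms$y <- at$y; atoms$z <- at$z
  atoms$hybridization <- .sybyl_hybridization(type)
  atoms$is_aromatic <- grepl("\\.ar$", type)
  atoms$partial_charge <- if ("charge" %in% names(at)) at$charge else NA_real_
  bd <- m$bond
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  if (!is.null(bd) && nrow(bd)) {
    if (any(bd$origin > nrow(at) | bd$target > nrow(at) |
            bd$origin < 1 | bd$target < 1))
      stop("MOL2 bond block references a missing atom in ", path)
    ord <- tolower(bd$type)
    ord[ord == "am"] <- "1"
    ord[ord %in% c("du", "un")] <- "1"
    keep <- ord %in% c("1", "2", "3", "ar")
    bonds <- data.frame(i = pmin(bd$origin, bd$target)[keep],
                        j = pmax(bd$origin, bd$target)[keep],
                        order = ord[keep], stringsAsFactors = FALSE)
  }
  # formal charges from SYBYL types: quaternary/protonated N; one unit of
  # negative charge per carboxylate group (lowest-index O.co2 of the group)
  fc <- integer(nrow(at))
  fc[type == "N.4"] <- 1L
  co2 <- which(type == "O.co2")
  if (length(co2)) {
    nb <- lapply(seq_len(nrow(at)), function(i)
      c(bonds$j[bonds$i == i], bonds$i[bonds$j == i]))
    carbons <- unique(unlist(lapply(co2, function(o) nb[[o]])))
    assigned <- logical(nrow(at))
    for (cc in sort(carbons)) {
      os <- sort(intersect(nb[[cc]], co2))
      if (length(os) && !any(assigned[os])) {
        fc[os[1]] <- -1L
        assigned[os] <- TRUE
      }
    }
    orphan <- co2[!assigned[co2] & !co2 %in% which(fc < 0)]
    fc[setdiff(orphan, which(assigned))] <- -1L
  }
  atoms$formal_charge <- fc
  new_ligand(atoms, bonds)
}

.pdb_fixed_fields <- function(lines, with_charge = FALSE) {
  rec <- substr(lines, 1, 6)
  sel <- grepl("^(ATOM|HETATM)", rec)
  lines <- lines[sel]
  if (!length(lines)) return(NULL)
  num <- function(s) suppressWarnings(as.numeric(s))
  out <- data.frame(
    atom_name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    residue_seq = suppressWarnings(as.integer(substr(lines, 23, 26))),
    x = num(substr(lines, 31, 38)), y = num(substr(lines, 39, 46)),
    z = num(substr(lines, 47, 54)),
    occupancy = num(substr(lines, 55, 60)),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  if (with_charge) {
    # charge nominally occupies columns 71-76; writers differ by a column or
    # in sign placement, so take the last token of the 67-76 window
    win <- trimws(substr(lines, 67, 76))
    tok <- vapply(strsplit(win, "\\s+"), function(x) x[length(x)],
                  character(1))
    out$partial_charge <- num(tok)
  }
  out
}

parse_ligand_pdbqt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # a PDBQT torsion tree may repeat coordinates across BRANCH blocks; the
  # ATOM/HETATM records themselves are unique, torsion keywords are skipped
  ff <- .pdb_fixed_fields(lines, with_charge = TRUE)
  if (is.null(ff) || !nrow(ff)) stop("empty structure: no atoms in ", path)
  bad <- which(!is.finite(ff$x) | !is.finite(ff$y) | !is.finite(ff$z))
  if (length(bad))
    stop("PDBQT parse error in ", path, ": bad coordinates at atom record ",
         bad[1])
  atoms <- empty_atoms(nrow(ff))
  # element from the AutoDock type column; AD types like A (aromatic C),
  # OA/NA/SA (acceptors), HD (polar H) map back to plain elements
  adt <- toupper(ff$element)
  el <- adt
  el[adt == "A"] <- "C"
  el[adt %in% c("OA", "OS")] <- "O"
  el[adt %in% c("NA", "NS") & !adt %in% .metal_symbols] <- "N"
  el[adt == "SA"] <- "S"
  el[adt %in% c("HD", "HS")] <- "H"
  guess <- gsub("[^A-Za-z]", "", substr(ff$atom_name, 1, 1))
  el[el == ""] <- toupper(guess[el == ""])
  atoms$element <- .norm_element(el)
  atoms$atom_name <- ff$atom_name
  atoms$residue_name <- "LIG"
  atoms$residue_seq <- 1L
  atoms$chain <- "L"
  atoms$x <- ff$x; atoms$y <- ff$y; atoms$z <- ff$z
  atoms$partial_charge <- ff$partial_charge
  atoms$is_aromatic <- adt == "A"
  bonds <- perceive_bonds(atoms)
  lig <- new_ligand(atoms, bonds)
  lig$atoms <- perceive_ligand_chemistry(lig$atoms, lig$bonds)
  lig
}

parse_ligand_pdb <- function(path) {
  p <- parse_protein_pdb(path, perceive = FALSE)
  atoms <- p$atoms
  atoms$residue_name <- "LIG"
  atoms$residue_seq <- 1L
  atoms$chain <- "L"
  atoms$is_aromatic <- FALSE
  atoms$formal_charge <- 0L
  bonds <- perceive_bonds(atoms)
  lig <- new_ligand(atoms, bonds)
  lig$atoms <- perceive_ligand_chemistry(lig$atoms, lig$bonds)
  lig
}

# degree/planar-ring based hybridization and aromaticity for ligands whose
# bonds were perceived from distances (PDB/PDBQT input)
perceive_ligand_chemistry <- function(atoms, bonds) {
  el <- .norm_element(atoms$element)
  deg <- atoms$degree
  hyb <- rep("UNSPECIFIED", nrow(atoms))
  hyb[el == "H"] <- "S"
  hyb[el == "C"] <- ifelse(deg[el == "C"] >= 4, "SP3",
                           ifelse(deg[el == "C"] == 3, "SP2", "SP"))
  hyb[el == "N"] <- ifelse(deg[el == "N"] >= 3, "SP3", "SP2")
  hyb[el == "O"] <- ifelse(deg[el == "O"] >= 2, "SP3", "SP2")
  hyb[el %in% c("S", "P")] <- "SP3"
  hyb[is_halogen(el)] <- "SP3"
  hyb[is_metal(el)] <- "OTHER"
  atoms$hybridization <- hyb
  # aromatic flag: member of a planar 5/6-ring of C/N/O/S
  rings <- find_rings(bonds, nrow(atoms), sizes = c(5L, 6L))
  xyz <- atom_xyz(atoms)
  for (r in rings) {
    if (!all(el[r] %in% c("C", "N", "O", "S"))) next
    pts <- xyz[r, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    nrm <- sv$v[, 3]
    dev <- abs(sweep(pts, 2, ctr) %*% nrm)
    if (max(dev) < 0.15) {
      atoms$is_aromatic[r] <- TRUE
      atoms$hybridization[r] <- "SP2"
    }
  }
  atoms
}

# enumerate simple cycles of the given sizes (molecular graphs are tiny)
find_rings <- function(bonds, n, sizes = c(5L, 6L)) {
  if (!nrow(bonds)) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  found <- list(); seen <- character(0)
  maxlen <- max(sizes)
  walk <- function(path) {
    tip <- path[length(path)]
    for (nb in adj[[tip]]) {
      if (nb == path[1] && length(path) >= 3 && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1]] <<- path
        }
      } else if (!nb %in% path && length(path) < maxlen &&
                 nb > path[1]) {       # canonical start = smallest index
        walk(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  found
}

#' Parse a docked ligand file
#'
#' @param path path to the ligand file.
#' @param fmt one of "mol2", "pdb", "pdbqt". MOL2 bonds come from the TRIPOS
#'   bond block; for PDB/PDBQT input bonds are perceived from interatomic
#'   distances against covalent radii (see \code{\link{perceive_bonds}}).
#'   PDBQT partial charges are read from columns 71-76.
#' @return a `plaig_ligand`.
#' @export
parse_ligand <- function(path, fmt = c("mol2", "pdb", "pdbqt")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("cannot read ligand file: ", path)
  switch(fmt,
         mol2 = parse_ligand_mol2(path),
         pdb = parse_ligand_pdb(path),
         pdbqt = parse_ligand_pdbqt(path))
}

# ---------------------------------------------------------------------------
# Gasteiger (PEOE) partial charges.

# Gasteiger-Marsili electronegativity coefficients a + b q + c q^2, keyed by
# element and hybridization state
.peoe_params <- local({
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
key        a     b      c
H.S     7.17  6.24  -0.56
C.SP3   7.98  9.18   1.88
C.SP2   8.79  9.32   1.51
C.SP   10.39  9.45   0.73
N.SP3  11.54 10.82   1.36
N.SP2  12.87 11.15   0.85
N.SP   15.68 11.70  -0.27
O.SP3  14.18 12.92   1.39
O.SP2  17.07 13.79   0.47
F.SP3  14.66 13.85   2.31
CL.SP3 11.00  9.69   1.35
BR.SP3 10.08  8.47   1.16
I.SP3   9.90  7.96   0.96
S.SP3  10.14  9.13   1.38
S.SP2  10.14  9.13   1.38
P.SP3   8.90  8.24   0.96
")
  rownames(tab) <- tab$key
  tab
})

.peoe_key <- function(element, hybridization) {
  el <- .norm_element(element)
  hyb <- hybridization
  hyb[el == "H"] <- "S"
  # fall back to the tetrahedral row when a state is not tabulated
  key <- paste(el, hyb, sep = ".")
  alt <- paste(el, "SP3", sep = ".")
  key[!key %in% rownames(.peoe_params) & alt %in% rownames(.peoe_params)] <-
    alt[!key %in% rownames(.peoe_params) & alt %in% rownames(.peoe_params)]
  key[el == "H"] <- "H.S"
  key
}

#' Assign Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativity over the
#' covalent bond network. Charges are seeded with the formal charges, and
#' each iteration transfers charge along every bond from the less to the more
#' electronegative atom, damped by 0.5^iteration, so the total molecular
#' charge is conserved exactly. Atoms of elements outside the parameter table
#' receive charge 0 with a warning and do not exchange charge.
#'
#' @param x a `plaig_ligand` or `plaig_pocket`. Pockets without a perceived
#'   bond table get one on the fly.
#' @param n_iter number of damped iterations (default 6).
#' @return the same object with `partial_charge` filled on every atom.
#' @export
assign_partial_charges <- function(x, n_iter = 6L) {
  atoms <- x$atoms
  bonds <- x$bonds
  if (is.null(bonds)) {
    bonds <- perceive_bonds(atoms)
    x$bonds <- bonds
    atoms <- fill_connectivity_counts(atoms, bonds)
  }
  key <- .peoe_key(atoms$element, atoms$hybridization)
  ok <- key %in% rownames(.peoe_params) & !is_metal(atoms$element)
  if (any(!ok))
    warning(sum(!ok), " atom(s) with elements outside the PEOE table; ",
            "their partial charge is set to 0")
  q <- as.numeric(atoms$formal_charge)
  q[!ok] <- 0
  a <- .peoe_params[key, "a"]; b <- .peoe_params[key, "b"]
  cc <- .peoe_params[key, "c"]
  chi_plus <- a + b + cc
  chi_plus[.norm_element(atoms$element) == "H"] <- 20.02
  if (nrow(bonds)) {
    bi <- bonds$i; bj <- bonds$j
    live <- ok[bi] & ok[bj]
    bi <- bi[live]; bj <- bj[live]
    for (it in seq_len(n_iter)) {
      damp <- 0.5^it
      chi <- a + b * q + cc * q^2
      for (k in seq_along(bi)) {
        i <- bi[k]; j <- bj[k]
        # electron density flows toward the more electronegative atom, which
        # becomes more negative; normalized by the donor's cation
        # electronegativity
        if (chi[j] > chi[i]) {
          dq <- (chi[j] - chi[i]) / chi_plus[i] * damp
          q[i] <- q[i] + dq; q[j] <- q[j] - dq
        } else if (chi[i] > chi[j]) {
          dq <- (chi[i] - chi[j]) / chi_plus[j] * damp
          q[j] <- q[j] + dq; q[i] <- q[i] - dq
        }
      }
    }
  }
  x$atoms$partial_charge <- q
  x
}

# ---------------------------------------------------------------------------
# PDB writing.

#' Write a pocket (or any atom collection) as a PDB file
#'
#' Fixed-column PDB v3 ATOM/HETATM records; coordinates are serialized with
#' three decimals, so `parse_protein_pdb(write_pocket_pdb(x))` preserves
#' elements, names, residues and coordinates to 1e-3 Angstrom.
#'
#' @param pocket a `plaig_pocket`.
#' @param path output file path.
#' @export
write_pocket_pdb <- function(pocket, path) {
  atoms <- pocket$atoms
  if (!nrow(atoms)) stop("refusing to write an empty pocket")
  rec <- ifelse(atoms$residue_name %in% .standard_residues, "ATOM", "HETATM")
  name <- atoms$atom_name
  # short names start in column 14 by convention
  name <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  lines <- sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(atoms)) %% 100000, name,
                   substr(atoms$residue_name, 1, 3), substr(atoms$chain, 1, 1),
                   atoms$residue_seq %% 10000, atoms$x, atoms$y, atoms$z,
                   1, 0, atoms$element)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}
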