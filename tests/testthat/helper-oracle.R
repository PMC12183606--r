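# Independent brute-force oracles used to cross-check the package.

# --- brute-force interaction detector -------------------------------------
# Straight nested loops over every atom pair and ring pair, deriving donor/
# acceptor/charge/eligibility roles from the parsed objects on the spot.

oracle_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- replicate(n, integer(0), simplify = FALSE)
  b <- mol$bonds
  if (!is.null(b)) for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], b$j[k])
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], b$i[k])
  }
  nb
}

oracle_rings <- function(mol, pocket_side) {
  # all 5/6-cycles of aromatic atoms; for pockets fall back to the canonical
  # side-chain ring atom names
  atoms <- mol$atoms
  if (pocket_side) {
    defs <- list(
      PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
      TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
      HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
      TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                 c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))
    key <- paste(atoms$chain, atoms$residue_seq, atoms$residue_name)
    out <- list()
    for (res in unique(key)) {
      idx <- which(key == res)
      for (d in defs[[atoms$residue_name[idx[1]]]] %||% list()) {
        mem <- idx[match(d, atoms$atom_name[idx])]
        if (!anyNA(mem) && all(atoms$is_aromatic[mem]))
          out[[length(out) + 1]] <- sort(mem)
      }
    }
    return(out)
  }
  nb <- oracle_neighbors(mol)
  n <- nrow(atoms)
  found <- list(); keys <- character(0)
  # enumerate simple paths up to length 6 starting at every vertex
  grow <- function(path) {
    last <- path[length(path)]
    for (nxt in nb[[last]]) {
      if (nxt == path[1] && length(path) %in% c(5, 6)) {
        key <- paste(sort(path), collapse = ".")
        if (!key %in% keys && all(atoms$is_aromatic[path])) {
          keys <<- c(keys, key)
          found[[length(found) + 1]] <<- sort(path)
        }
      } else if (!(nxt %in% path) && length(path) < 6) grow(c(path, nxt))
    }
  }
  for (s in seq_len(n)) grow(s)
  found
}

oracle_ring_geom <- function(atoms, members) {
  pts <- as.matrix(atoms[members, c("x", "y", "z")])
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  nrm <- s$v[, 3] / sqrt(sum(s$v[, 3]^2))
  list(ctr = ctr, nrm = nrm)
}

oracle_detect <- function(pocket, ligand, cutoff = 3.0,
                          rules = interaction_rules()) {
  la <- ligand$atoms; pa <- pocket$atoms
  lnb <- oracle_neighbors(ligand); pnb <- oracle_neighbors(pocket)
  lel <- toupper(la$element); pel <- toupper(pa$element)
  metals <- c("NA", "MG", "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN")
  halos <- c("F", "CL", "BR", "I")
  lx <- as.matrix(la[, c("x", "y", "z")])
  px <- as.matrix(pa[, c("x", "y", "z")])
  dd <- function(i, j) sqrt(sum((lx[i, ] - px[j, ])^2))
  ang_at <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  eligible <- function(el, nbr, elems) {
    el == "C" && (length(nbr) == 0 ||
                  all(elems[nbr] %in% c("C", "H") | elems[nbr] %in% halos))
  }
  lig_sign <- function(i) {
    s <- sign(la$formal_charge[i])
    if (s < 0) return(-1)
    if (s > 0) return(1)
    # resonance sibling of a charged carboxylate oxygen
    if (lel[i] == "O") {
      for (cc in lnb[[i]]) {
        if (lel[cc] != "C") next
        for (o2 in lnb[[cc]])
          if (lel[o2] == "O" && la$formal_charge[o2] < 0 &&
              la$degree[o2] == 1 && la$degree[i] == 1) return(-1)
      }
    }
    0
  }
  poc_sign <- function(j) {
    res <- pa$residue_name[j]; nm <- toupper(pa$atom_name[j])
    if (res == "LYS" && nm == "NZ") return(1)
    if (res == "ARG" && nm %in% c("NH1", "NH2", "NE")) return(1)
    if (res == "HIS" && nm %in% c("ND1", "NE2")) return(1)
    if (res == "ASP" && nm %in% c("OD1", "OD2")) return(-1)
    if (res == "GLU" && nm %in% c("OE1", "OE2")) return(-1)
    0
  }
  res <- list()
  put <- function(i, j, kind, d)
    res[[length(res) + 1]] <<- data.frame(ligand_atom = as.integer(i),
                                          pocket_atom = as.integer(j),
                                          kind = kind, distance = d)
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(pa))) {
    d <- dd(i, j)
    if (d > 0 && d <= cutoff) put(i, j, "close_contact", d)
    # hydrogen bond, ligand donor
    if (d > 0 && d <= cutoff && lel[i] %in% c("N", "O", "S") &&
        pel[j] %in% c("N", "O")) {
      for (h in lnb[[i]]) if (lel[h] == "H" &&
        ang_at(lx[i, ], lx[h, ], px[j, ]) >= rules$hbond_angle) {
        put(i, j, "hydrogen_bond", d); break
      }
    }
    # hydrogen bond, pocket donor
    if (d > 0 && d <= cutoff && pel[j] %in% c("N", "O", "S") &&
        lel[i] %in% c("N", "O")) {
      for (h in pnb[[j]]) if (pel[h] == "H" &&
        ang_at(px[j, ], px[h, ], lx[i, ]) >= rules$hbond_angle) {
        put(i, j, "hydrogen_bond", d); break
      }
    }
    # halogen bond
    if (d > 0 && d <= cutoff && lel[i] %in% halos &&
        pel[j] %in% c("O", "N", "S")) {
      for (cc in lnb[[i]]) if (lel[cc] == "C" &&
        ang_at(lx[cc, ], lx[i, ], px[j, ]) >= rules$halogen_angle) {
        put(i, j, "halogen_bond", d); break
      }
    }
    if (d > 0 && d <= rules$hydrophobic_dist &&
        eligible(lel[i], lnb[[i]], lel) && eligible(pel[j], pnb[[j]], pel))
      put(i, j, "hydrophobic", d)
    if (d > 0 && d <= rules$metal_dist && lel[i] %in% c("N", "O", "S") &&
        pel[j] %in% metals)
      put(i, j, "metal", d)
    if (d > 0 && d <= rules$salt_bridge_dist && lel[i] != "H" &&
        pel[j] != "H" && !pel[j] %in% metals &&
        lig_sign(i) * poc_sign(j) == -1)
      put(i, j, "salt_bridge", d)
  }
  lrings <- oracle_rings(ligand, FALSE)
  prings <- oracle_rings(pocket, TRUE)
  for (i in seq_len(nrow(la)))
    if (lig_sign(i) > 0 && lel[i] != "H") for (rg in prings) {
      g <- oracle_ring_geom(pa, rg)
      d <- sqrt(sum((lx[i, ] - g$ctr)^2))
      if (d <= rules$cation_pi_dist) {
        ds <- vapply(rg, function(j) dd(i, j), numeric(1))
        put(i, rg[which.min(ds)], "cation_pi", d)
      }
    }
  for (j in seq_len(nrow(pa)))
    if (poc_sign(j) > 0 && !pel[j] %in% metals) for (rg in lrings) {
      g <- oracle_ring_geom(la, rg)
      d <- sqrt(sum((px[j, ] - g$ctr)^2))
      if (d <= rules$cation_pi_dist) {
        ds <- vapply(rg, function(i) dd(i, j), numeric(1))
        put(rg[which.min(ds)], j, "cation_pi", d)
      }
    }
  for (rl in lrings) for (rp in prings) {
    gl <- oracle_ring_geom(la, rl); gp <- oracle_ring_geom(pa, rp)
    d <- sqrt(sum((gl$ctr - gp$ctr)^2))
    theta <- acos(min(1, abs(sum(gl$nrm * gp$nrm)))) * 180 / pi
    hits <- character(0)
    if (d <= rules$pi_pi_dist && theta <= rules$pi_pi_angle)
      hits <- "pi_pi"
    if (d <= rules$t_stack_dist && theta >= rules$t_stack_angle_min &&
        theta <= rules$t_stack_angle_max)
      hits <- c(hits, "t_stack")
    if (length(hits)) {
      best <- c(NA, NA); bd <- Inf
      for (i in sort(rl)) for (j in sort(rp))
        if (dd(i, j) < bd) { bd <- dd(i, j); best <- c(i, j) }
      for (k in hits) put(best[1], best[2], k, d)
    }
  }
  tab <- do.call(rbind, res)
  if (is.null(tab))
    return(data.frame(ligand_atom = integer(), pocket_atom = integer(),
                      kind = character(), distance = numeric()))
  tab <- tab[!duplicated(tab[, c("ligand_atom", "pocket_atom", "kind")]), ]
  kinds_order <- c("hydrogen_bond", "halogen_bond", "hydrophobic", "metal",
                   "pi_pi", "t_stack", "salt_bridge", "cation_pi",
                   "close_contact")
  tab <- tab[order(match(tab$kind, kinds_order), tab$ligand_atom,
                   tab$pocket_atom), ]
  rownames(tab) <- NULL
  tab
}

# --- textbook regression metrics ------------------------------------------

oracle_metrics <- function(pred, actual) {
  n <- length(pred)
  mp <- sum(pred) / n; ma <- sum(actual) / n
  pcc <- sum((pred - mp) * (actual - ma)) /
    sqrt(sum((pred - mp)^2) * sum((actual - ma)^2))
  mse <- sum((pred - actual)^2) / n
  mae <- sum(abs(pred - actual)) / n
  r2 <- 1 - sum((actual - pred)^2) / sum((actual - ma)^2)
  list(pcc = pcc, mse = mse, mae = mae, r2 = r2)
}

# pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
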