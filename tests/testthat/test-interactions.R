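test_that("Coulomb energy follows 332.06 q1 q2 / r", {
  expect_equal(electrostatic_energy(0, 0, 2.5), 0)
  expect_equal(electrostatic_energy(1, -1, 3.3206), -100.0)
  expect_error(electrostatic_energy(1, 1, 0), "positive")
  expect_error(electrostatic_energy(1, 1, -2), "positive")
  set.seed(1)
  for (k in 1:20) {
    q1 <- rnorm(1); q2 <- rnorm(1); r <- runif(1, 0.5, 10)
    expect_equal(sign(electrostatic_energy(q1, q2, r)), sign(q1 * q2))
    expect_equal(electrostatic_energy(q1, q2, r), 332.06 * q1 * q2 / r)
  }
})

test_that("aromatic ring finding: geometry, aromaticity gate", {
  bz <- benzene_ligand()
  rings <- find_aromatic_rings(bz)
  expect_length(rings, 1)
  expect_equal(sort(rings[[1]]$members), 1:6)
  # all atoms lie in z = 0, so the normal is +-z and unit length
  expect_equal(abs(rings[[1]]$normal[3]), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(rings[[1]]$normal^2)), 1, tolerance = 1e-12)
  # ideal flat hexagon: centroid at the geometric center
  bz2 <- benzene_ligand(bond = 1.0, center = c(3, -2, 5))
  expect_equal(find_aromatic_rings(bz2)[[1]]$centroid, c(3, -2, 5),
               tolerance = 1e-6)
  # non-aromatic ring of the same size is not reported
  ang <- 2 * pi * (0:5) / 6
  chair <- data.frame(name = paste0("C", 1:6), type = "C.3",
                      x = 1.5 * cos(ang), y = 1.5 * sin(ang),
                      z = rep(c(0.25, -0.25), 3))
  cyclohexane <- parse_ligand(write_lines_tmp(
    mol2_text(chair, data.frame(i = 1:6, j = c(2:6, 1), order = "1")),
    ".mol2"), "mol2")
  expect_length(find_aromatic_rings(cyclohexane), 0)
})

make_hbond_pair <- function(shift = 0) {
  # ligand N-H donor aimed at a pocket serine OG acceptor
  atoms <- data.frame(name = c("C1", "N1", "H1"),
                      type = c("C.3", "N.3", "H"),
                      x = c(-1.47, 0, 1.01), y = 0, z = 0)
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), order = "1")
  lig <- parse_ligand(write_lines_tmp(mol2_text(atoms, bonds), ".mol2"),
                      "mol2")
  poc <- parse_protein_pdb(write_lines_tmp(c(
    pdb_line(1, "OG", "SER", "A", 1, 2.91 + shift, 0, 0, element = "O"),
    pdb_line(2, "CB", "SER", "A", 1, 4.34 + shift, 0, 0, element = "C"),
    "END"), ".pdb"))
  list(lig = suppressWarnings(assign_partial_charges(lig)),
       poc = suppressWarnings(assign_partial_charges(poc)))
}

test_that("hydrogen bonds require donor H geometry within the thresholds", {
  pair <- make_hbond_pair()
  ints <- detect_interactions(pair$poc, pair$lig)
  expect_true("hydrogen_bond" %in% ints$contacts$kind)
  hb <- ints$contacts[ints$contacts$kind == "hydrogen_bond", ]
  expect_equal(hb$ligand_atom, 2)      # stored pair is heavy donor/acceptor
  expect_equal(hb$pocket_atom, 1)
  expect_equal(hb$distance, 2.91)      # donor-acceptor distance
  # translating the acceptor to 8 A removes every contact with it
  far <- make_hbond_pair(shift = 6)
  ints_far <- detect_interactions(far$poc, far$lig)
  expect_false(any(ints_far$contacts$pocket_atom == 1))
  # charges are a precondition
  raw <- parse_ligand(write_lines_tmp(mol2_text(
    data.frame(name = "C1", type = "C.3", x = 0, y = 0, z = 0)), ".mol2"),
    "mol2")
  raw$atoms$partial_charge <- NA_real_
  expect_error(detect_interactions(pair$poc, raw), "charges")
})

make_ring_pair <- function(t_stack = FALSE) {
  lig <- suppressWarnings(assign_partial_charges(benzene_ligand()))
  # pocket phenylalanine ring at 4.3 A (parallel) or rotated edge-on at 4.4 A
  ang <- (60 * (0:5) + 15) * pi / 180
  if (!t_stack) {
    xyz <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 4.3)
  } else {
    xyz <- cbind(1.4 * cos(ang), 0, 4.4 + 1.4 * sin(ang))
  }
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  lines <- c(vapply(1:6, function(k)
    pdb_line(k, nm[k], "PHE", "A", 1, xyz[k, 1], xyz[k, 2], xyz[k, 3],
             element = "C"), character(1)), "END")
  poc <- suppressWarnings(assign_partial_charges(
    parse_protein_pdb(write_lines_tmp(lines, ".pdb"))))
  list(lig = lig, poc = poc)
}

test_that("parallel rings give pi-pi stacking; perpendicular give T-stacks", {
  par <- make_ring_pair(FALSE)
  kinds <- detect_interactions(par$poc, par$lig)$contacts$kind
  expect_true("pi_pi" %in% kinds)
  expect_false("t_stack" %in% kinds)
  pp <- detect_interactions(par$poc, par$lig)$contacts
  expect_equal(pp$distance[pp$kind == "pi_pi"], 4.3, tolerance = 1e-9)
  perp <- make_ring_pair(TRUE)
  kinds2 <- detect_interactions(perp$poc, perp$lig)$contacts$kind
  expect_true("t_stack" %in% kinds2)
  expect_false("pi_pi" %in% kinds2)
})

test_that("the detector equals the brute-force oracle on planted fixtures", {
  for (seed in 31:36) {
    px <- parsed_complex(random_fixture_spec(seed))
    fast <- detect_interactions(px$pocket, px$ligand)
    slow <- oracle_detect(px$pocket, px$ligand)
    expect_equal(fast$contacts[, c("ligand_atom", "pocket_atom", "kind")],
                 slow[, c("ligand_atom", "pocket_atom", "kind")])
    expect_equal(fast$contacts$distance, slow$distance, tolerance = 1e-12)
    # and both match the generator's declared ground truth
    expect_equal(fast$contacts[, c("ligand_atom", "pocket_atom", "kind")],
                 px$truth[, c("ligand_atom", "pocket_atom", "kind")])
  }
})

test_that("the interaction set is invariant under rigid motion", {
  px <- parsed_complex(random_fixture_spec(44))
  ref <- detect_interactions(px$pocket, px$ligand)
  set.seed(9)
  for (k in 1:3) {
    R <- random_rotation(); t <- rnorm(3, 0, 20)
    lig2 <- rigid_transform(px$ligand, R, t)
    poc2 <- rigid_transform(px$pocket, R, t)
    moved <- detect_interactions(poc2, lig2)
    expect_equal(moved$contacts[, c("ligand_atom", "pocket_atom", "kind")],
                 ref$contacts[, c("ligand_atom", "pocket_atom", "kind")])
    expect_equal(moved$contacts$distance, ref$contacts$distance,
                 tolerance = 1e-9)
  }
})

test_that("enlarging the cutoff never removes a close contact", {
  px <- parsed_complex(random_fixture_spec(55))
  cc <- function(cut) {
    ct <- detect_interactions(px$pocket, px$ligand, cutoff = cut)$contacts
    ct <- ct[ct$kind == "close_contact", ]
    paste(ct$ligand_atom, ct$pocket_atom)
  }
  prev <- cc(2.0)
  for (cut in c(2.5, 3.0, 3.5, 4.5)) {
    cur <- cc(cut)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})
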