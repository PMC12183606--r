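test_that("PDB parsing transcribes atoms, drops waters, rejects empty files", {
  f <- write_lines_tmp(c(
    pdb_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147),
    pdb_line(3, "C", "ALA", "A", 1, 12.685, 7.159, -4.948),
    pdb_line(4, "O", "HOH", "A", 99, 5, 5, 5, record = "HETATM"),
    "END"), ".pdb")
  p <- parse_protein_pdb(f)
  expect_equal(nrow(p$atoms), 3)
  expect_equal(p$atoms$residue_name, rep("ALA", 3))
  expect_equal(p$atoms$atom_name, c("N", "CA", "C"))
  expect_equal(p$atoms$element, c("N", "C", "C"))
  expect_equal(p$atoms$x, c(11.104, 11.639, 12.685))
  expect_equal(p$atoms$residue_seq, rep(1L, 3))

  water_only <- write_lines_tmp(c(
    pdb_line(1, "O", "HOH", "A", 1, 1, 1, 1, record = "HETATM"), "END"),
    ".pdb")
  expect_error(parse_protein_pdb(water_only), "empty structure")
  expect_error(parse_protein_pdb(tempfile()), "cannot read")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  f <- write_lines_tmp(c(
    pdb_line_alt(1, "CA", "A", "ALA", "A", 1, 1.0, 0, 0, 0.6),
    pdb_line_alt(2, "CA", "B", "ALA", "A", 1, 9.0, 0, 0, 0.4),
    pdb_line(3, "CB", "ALA", "A", 1, 2.5, 0, 0),
    "END"), ".pdb")
  p <- parse_protein_pdb(f)
  ca <- p$atoms[p$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)
  # the B copy wins when it has the higher occupancy
  h <- write_lines_tmp(c(
    pdb_line_alt(1, "CA", "A", "ALA", "A", 1, 1.0, 0, 0, 0.3),
    pdb_line_alt(2, "CA", "B", "ALA", "A", 1, 9.0, 0, 0, 0.7),
    "END"), ".pdb")
  expect_equal(parse_protein_pdb(h)$atoms$x, 9.0)
  # tie goes to the first record
  g <- write_lines_tmp(c(
    pdb_line_alt(1, "CA", "A", "ALA", "A", 1, 1.0, 0, 0, 0.5),
    pdb_line_alt(2, "CA", "B", "ALA", "A", 1, 9.0, 0, 0, 0.5),
    "END"), ".pdb")
  expect_equal(parse_protein_pdb(g)$atoms$x, 1.0)
})

test_that("parsing the same bytes twice gives identical records", {
  cx <- make_complex(fixture_spec(c(hydrogen_bond = 1, pi_pi = 1), seed = 5))
  f <- write_lines_tmp(cx$protein_pdb, ".pdb")
  expect_identical(parse_protein_pdb(f)$atoms, parse_protein_pdb(f)$atoms)
  m <- write_lines_tmp(cx$ligand_mol2, ".mol2")
  expect_identical(parse_ligand(m, "mol2")$atoms, parse_ligand(m, "mol2")$atoms)
})

test_that("MOL2 ligands carry bonds, types and charges from the file", {
  atoms <- data.frame(name = c("C1", "C2", "O1"),
                      type = c("C.3", "C.3", "O.3"),
                      x = c(0, 1.52, 2.0), y = c(0, 0, 1.3), z = 0,
                      charge = c(-0.06, 0.04, -0.39))
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), order = "1")
  lig <- parse_ligand(write_lines_tmp(mol2_text(atoms, bonds), ".mol2"),
                      "mol2")
  expect_equal(nrow(lig$bonds), 2)
  expect_equal(lig$bonds$order, c("1", "1"))
  expect_equal(lig$atoms$partial_charge, c(-0.06, 0.04, -0.39))
  expect_equal(lig$atoms$hybridization, c("SP3", "SP3", "SP3"))
  expect_equal(lig$atoms$degree, c(1L, 2L, 1L))
  # bond block referencing a missing atom is a parse error
  bad <- mol2_text(atoms, data.frame(i = 1, j = 9, order = "1"))
  expect_error(parse_ligand(write_lines_tmp(bad, ".mol2"), "mol2"),
               "missing atom")
})

test_that("PDBQT charges come from columns 71-76", {
  lines <- c(
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.4f %-2s",
            "ATOM", 1, " C1", "LIG", "L", 1, 0, 0, 0, 1, 0, 0.1230, "C"),
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f   %7.4f %-2s",
            "ATOM", 2, " O1", "LIG", "L", 1, 1.43, 0, 0, 1, 0, -0.3456, "OA"))
  lig <- parse_ligand(write_lines_tmp(lines, ".pdbqt"), "pdbqt")
  expect_equal(lig$atoms$partial_charge, c(0.1230, -0.3456))
  expect_equal(lig$atoms$element, c("C", "O"))
  expect_equal(nrow(lig$bonds), 1)  # C-O at 1.43 A perceived
})

test_that("PDB ligand bonds are perceived from covalent radii", {
  two_c <- function(d) {
    f <- write_lines_tmp(c(
      pdb_line(1, "C1", "LIG", "L", 1, 0, 0, 0, record = "HETATM"),
      pdb_line(2, "C2", "LIG", "L", 1, d, 0, 0, record = "HETATM"),
      "END"), ".pdb")
    parse_ligand(f, "pdb")
  }
  expect_equal(nrow(two_c(1.52)$bonds), 1)
  expect_equal(two_c(1.52)$bonds$order, "1")
  expect_equal(nrow(two_c(3.0)$bonds), 0)
  # threshold: 1.3 * (0.76 + 0.76) = 1.976
  expect_equal(nrow(two_c(1.97)$bonds), 1)
  expect_equal(nrow(two_c(1.99)$bonds), 0)
})

test_that("Gasteiger charges respect symmetry, neutrality and conservation", {
  ch4 <- assign_partial_charges(parse_ligand(methane_mol2(), "mol2"))
  q <- ch4$atoms$partial_charge
  expect_lt(q[1], 0)                    # carbon pulls charge from hydrogens
  expect_true(all(q[2:5] > 0))
  expect_equal(max(q[2:5]) - min(q[2:5]), 0, tolerance = 1e-12)
  expect_equal(sum(q), 0, tolerance = 1e-3)

  fo <- assign_partial_charges(parse_ligand(formate_mol2(), "mol2"))
  expect_equal(sum(fo$atoms$partial_charge), -1, tolerance = 1e-3)

  ar <- data.frame(name = "AR1", type = "Ar", x = 0, y = 0, z = 0)
  lig <- parse_ligand(write_lines_tmp(mol2_text(ar), ".mol2"), "mol2")
  expect_warning(lig <- assign_partial_charges(lig), "PEOE")
  expect_equal(lig$atoms$partial_charge, 0)
})

test_that("charge conservation holds across random synthetic ligands", {
  for (seed in 1:5) {
    px <- parsed_complex(random_fixture_spec(seed))
    expect_equal(sum(px$ligand$atoms$partial_charge),
                 sum(px$ligand$atoms$formal_charge), tolerance = 1e-3)
  }
})

test_that("pocket PDB writing round-trips atoms at 3-decimal precision", {
  cx <- make_complex(fixture_spec(c(salt_bridge = 1, t_stack = 1), seed = 2))
  f <- write_lines_tmp(cx$protein_pdb, ".pdb")
  p <- parse_protein_pdb(f)
  out <- tempfile(fileext = ".pdb")
  write_pocket_pdb(p, out)
  p2 <- parse_protein_pdb(out)
  expect_equal(p2$atoms$element, p$atoms$element)
  expect_equal(p2$atoms$atom_name, p$atoms$atom_name)
  expect_equal(p2$atoms$residue_name, p$atoms$residue_name)
  expect_equal(p2$atoms$residue_seq, p$atoms$residue_seq)
  expect_equal(p2$atoms$x, p$atoms$x, tolerance = 1e-9)

  expect_error(write_pocket_pdb(empty_pocket(), tempfile()), "empty")

  # fixed-column serialization rounds to three decimals
  one <- p; one$atoms <- one$atoms[1, , drop = FALSE]
  one$atoms$x <- 12.3456
  write_pocket_pdb(one, out)
  expect_match(readLines(out)[1], "12\\.346")
})
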