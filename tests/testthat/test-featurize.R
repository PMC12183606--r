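test_that("feature schemas have the frozen dimensionalities", {
  sc <- feature_schema()
  expect_length(sc$node_names, 40)
  expect_length(sc$edge_names, 11)
  expect_length(sc$ligand_descriptors, 88)
  expect_length(sc$pocket_descriptors, 74)
  expect_false(anyDuplicated(sc$ligand_descriptors) > 0)
  expect_false(anyDuplicated(sc$pocket_descriptors) > 0)
  expect_length(sc$residues, 22)
  expect_length(sc$hybridizations, 8)
  # the packaged JSON copy matches the in-code schema
  js <- jsonlite::fromJSON(system.file("extdata", "feature_schema.json",
                                       package = "plaig"))
  expect_equal(js$node_names, sc$node_names)
  expect_equal(js$edge_names, sc$edge_names)
  expect_equal(js$ligand_descriptors, sc$ligand_descriptors)
  expect_equal(js$pocket_descriptors, sc$pocket_descriptors)
})

test_that("node features: one-hots, locality of the coordinate block", {
  px <- parsed_complex(fixture_spec(c(pi_pi = 1, hydrogen_bond = 1),
                                    seed = 3))
  sc <- feature_schema()
  nf <- node_features(px$ligand$atoms, sc)
  expect_equal(ncol(nf), 40)
  res_block <- nf[, grepl("^res_", colnames(nf))]
  hyb_block <- nf[, grepl("^hyb_", colnames(nf))]
  expect_true(all(rowSums(res_block) == 1))
  expect_true(all(rowSums(hyb_block) == 1))
  expect_true(all(res_block[, "res_LIG"] == 1))      # ligand atoms hit LIG
  # aromatic carbon of the planted ring
  ar <- which(px$ligand$atoms$is_aromatic)[1]
  expect_equal(unname(nf[ar, "is_aromatic"]), 1)
  expect_equal(unname(nf[ar, "hyb_SP2"]), 1)
  # translation only moves the coordinate slots
  shifted <- px$ligand
  shifted$atoms$x <- shifted$atoms$x + 5
  nf2 <- node_features(shifted$atoms, sc)
  delta <- which(colSums(abs(nf2 - nf)) > 0)
  expect_equal(colnames(nf)[delta], "x")
  # unknown residues land in the OTHER bucket, not an error
  odd <- px$pocket$atoms[1, , drop = FALSE]
  odd$residue_name <- "XYZ"
  expect_equal(unname(node_features(odd, sc)[1, "res_OTHER"]), 1)
})

test_that("edge features encode energy, flags, bond type and distance", {
  sc <- feature_schema()
  e1 <- edge_features(-2.5, character(), "1", 1.54, sc)
  expect_length(e1, 11)
  expect_equal(unname(e1[c(1, 10, 11)]), c(-2.5, 1, 1.54))
  expect_true(all(e1[2:9] == 0))
  e2 <- edge_features(0.3, c("hydrogen_bond", "close_contact"), NULL, 2.9, sc)
  expect_equal(unname(e2["flag_hydrogen_bond"]), 1)
  expect_equal(sum(e2[2:9]), 1)         # close_contact sets no flag
  expect_equal(unname(e2["bond_type"]), 0)
  e3 <- edge_features(0, character(), "ar", 1.4, sc)
  expect_equal(unname(e3["bond_type"]), 4)
})

test_that("global descriptors are complete, finite and deterministic", {
  px <- parsed_complex(random_fixture_spec(12))
  lg <- global_ligand_features(px$ligand)
  pg <- global_pocket_features(px$pocket)
  expect_length(lg, 88)
  expect_length(pg, 74)
  expect_true(all(is.finite(lg)))
  expect_true(all(is.finite(pg)))
  expect_identical(lg, global_ligand_features(px$ligand))
  # molecular weight is the sum of atomic masses
  expect_equal(unname(lg["molecular_weight"]),
               sum(plaig:::element_mass(px$ligand$atoms$element)))
  # residue composition counts the planted pocket residues
  expect_equal(unname(pg["n_residues"]), sum(px$counts))
  expect_error(global_ligand_features(list(atoms = data.frame(),
                                           bonds = data.frame())), "empty")
})

build_raw_graphs <- function(seeds) {
  lapply(seeds, function(s) {
    px <- parsed_complex(random_fixture_spec(s))
    ints <- detect_interactions(px$pocket, px$ligand)
    build_graph(px$pocket, px$ligand, ints, id = paste0("g", s),
                target = 5 + s / 10)
  })
}

test_that("scalers: min-max, z-score, clamping, refit guard", {
  graphs <- build_raw_graphs(c(61, 62, 63))
  sc <- suppressWarnings(fit_scalers(graphs))
  scaled <- lapply(graphs, function(g) suppressWarnings(scale_graph(g, sc)))
  # two-point min-max sanity on a constructed scaler
  sc2 <- sc
  sc2$edge_distance <- c(min = 2, max = 3)
  expect_equal(plaig:::.apply_minmax(c(2, 3), sc2$edge_distance), c(0, 1))
  expect_equal(plaig:::.apply_minmax(4, sc2$edge_distance), 1)  # clamped
  expect_equal(plaig:::.apply_minmax(1.5, sc2$edge_distance), 0)
  # z-scored training columns have mean ~0, sd ~1 across the training set
  gast <- unlist(lapply(scaled, function(g) g$node_matrix[, "gasteiger_charge"]))
  expect_lt(abs(mean(gast)), 1e-9)
  expect_equal(sd(gast), 1, tolerance = 1e-6)
  masses <- unlist(lapply(scaled, function(g) g$node_matrix[, "mass"]))
  expect_true(all(masses >= 0 & masses <= 1))
  # scaling is guarded against re-application
  expect_error(scale_graph(scaled[[1]], sc), "already scaled")
  expect_error(fit_scalers(scaled), "raw")
  expect_error(fit_scalers(graphs[1]), "at least 2")
})

test_that("PCA elbow finds planted low-rank structure", {
  set.seed(7)
  n <- 60
  basis <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:2]
  flat <- matrix(rnorm(n * 2, sd = 3), n) %*% t(basis) +
    matrix(rnorm(n * 10, sd = 1e-4), n)
  res <- pca_elbow(scale(flat, scale = FALSE))
  expect_equal(res$n_components, 2)
  expect_true(all(diff(res$cumulative_variance) >= -1e-12))
  expect_equal(res$cumulative_variance[length(res$cumulative_variance)], 1,
               tolerance = 1e-9)
  # isotropic noise has no elbow: capped at the rank
  iso <- matrix(rnorm(n * 6), n)
  expect_equal(pca_elbow(iso)$n_components, 6)
  # duplicated column cannot raise the component count above the rank
  dup <- cbind(iso, iso[, 1])
  expect_lte(pca_elbow(dup)$n_components, 6)
  expect_error(pca_elbow(iso[1, , drop = FALSE]), "2 rows")
})
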