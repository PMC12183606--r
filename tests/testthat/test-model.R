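test_that("training reduces the MAE loss on a learnable synthetic set", {
  graphs <- scaled_small()
  gnn <- train_gnn(graphs, small_cfg())
  expect_length(gnn$history, 8)
  expect_lt(gnn$history[8], gnn$history[1])
})

test_that("a constant-target dataset converges to the constant", {
  graphs <- scaled_small()
  graphs <- lapply(graphs, function(g) { g$target <- 5.5; g })
  gnn <- train_gnn(graphs, gnn_config(hidden_channels = 16, conv_layers = 2,
                                      epochs = 50, batch_size = 16,
                                      learning_rate = 0.05,
                                      dropout = 0, seed = 3))
  preds <- vapply(graphs[1:10], function(g) gnn_predict(gnn, g), numeric(1))
  expect_true(all(abs(preds - 5.5) < 0.1))
})

test_that("identical seeds give identical training trajectories", {
  graphs <- scaled_small()
  g1 <- train_gnn(graphs, small_cfg())
  g2 <- train_gnn(graphs, small_cfg())
  expect_equal(g1$history[1], g2$history[1], tolerance = 1e-6)
  expect_identical(g1$params, g2$params)
})

test_that("the embedding decomposes the prediction and is permutation-invariant", {
  graphs <- scaled_small()
  gnn <- train_gnn(graphs, small_cfg())
  g <- graphs[[5]]
  e <- gnn_embed(gnn, g)
  expect_length(e, 24)
  expect_equal(sum(gnn$params$head$w * e) + gnn$params$head$b,
               gnn_predict(gnn, g), tolerance = 1e-6)
  expect_identical(gnn_embed(gnn, g), gnn_embed(gnn, g))
  set.seed(11)
  for (k in 1:3) {
    perm <- sample(nrow(g$node_matrix))
    gp <- permute_graph_nodes(g, perm)
    expect_equal(gnn_embed(gnn, gp), e, tolerance = 1e-5)
  }
})

test_that("stacking learns an exact linear map of the embeddings", {
  set.seed(5)
  emb <- matrix(rnorm(80 * 16), 80)
  y <- 2 * emb[, 1] - emb[, 2] + 4
  st <- train_stacking(emb, y, seed = 1, n_trees = 150)
  pred <- predict_stacking(st, emb)
  expect_lt(sqrt(mean((pred - y)^2)), 0.6)  # tree ensembles approximate
  # the ridge meta-learner on top cannot be worse than useless on constants
  yc <- rep(3.25, 80)
  stc <- suppressWarnings(train_stacking(emb, yc, seed = 1, n_trees = 50))
  expect_equal(predict_stacking(stc, emb), yc, tolerance = 1e-6)
  # determinism under a fixed seed
  st2 <- train_stacking(emb, y, seed = 1, n_trees = 150)
  expect_identical(predict_stacking(st2, emb), pred)
  expect_error(train_stacking(emb[1:20, ], y[1:20]), "at least 50")
})

test_that("model save/load round-trips predictions exactly", {
  ds <- small_dataset()
  m <- suppressWarnings(train_affinity_model(ds$graphs, small_cfg()))
  p0 <- predict(m, ds$graphs[1:8])
  expect_true(all(is.finite(p0)))
  f <- tempfile(fileext = ".plaig")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, ds$graphs[1:8]), p0)
  # corrupt artifacts are rejected with diagnostics
  saveRDS(list(a = 1), f)
  expect_error(load_model(f), "not a plaig model")
  writeLines("garbage", f)
  expect_error(load_model(f), "cannot load")
})

test_that("ablation variants mask the intended feature blocks", {
  ds <- small_dataset()
  m <- suppressWarnings(
    ablate(ds$graphs, small_cfg(), variant = "no_interactions"))
  g <- ds$graphs[[3]]
  gs <- scale_graph(g, m$scaler)
  # interaction slots (energy + 8 flags) have no influence on the output
  gz <- gs
  gz$edge_matrix[, 1:9] <- rnorm(length(gz$edge_matrix[, 1:9]))
  expect_equal(gnn_embed(m$gnn, gz), gnn_embed(m$gnn, gs), tolerance = 1e-12)
  m2 <- suppressWarnings(ablate(ds$graphs, small_cfg(), variant = "no_globals"))
  gz2 <- scale_graph(g, m2$scaler)
  gz2$ligand_global[] <- rnorm(88)
  gz2$pocket_global[] <- rnorm(74)
  expect_equal(gnn_embed(m2$gnn, gz2),
               gnn_embed(m2$gnn, scale_graph(g, m2$scaler)),
               tolerance = 1e-12)
  # variant = "full" is the plain training path
  expect_identical(
    suppressWarnings(ablate(ds$graphs, small_cfg(), variant = "full",
                            stack = FALSE))$gnn$params,
    suppressWarnings(train_affinity_model(ds$graphs, small_cfg(),
                                          stack = FALSE))$gnn$params)
})

test_that("sequential tuning respects the budget and finds rigged optima", {
  ds <- small_dataset()
  graphs <- ds$graphs[1:40]
  one_point <- list(hidden_channels = 16L, conv_layers = 2L, dropout = 0.2,
                    learning_rate = 0.005, batch_size = 16L, epochs = 4L)
  best <- suppressWarnings(tune_gnn(graphs, space = one_point, max_evals = 5,
                                    folds = 4, seed = 2))
  trials <- attr(best, "trials")
  expect_equal(nrow(trials), 1)         # a single-point space needs one trial
  expect_equal(best$hidden_channels, 16L)
  # two-point space rigged so that training for 0 epochs must lose
  two_point <- modifyList(one_point, list(epochs = c(1L, 12L)))
  best2 <- suppressWarnings(tune_gnn(graphs, space = two_point, max_evals = 4,
                                     folds = 4, seed = 2))
  expect_lte(nrow(attr(best2, "trials")), 4)
  expect_equal(best2$epochs, 12L)
})
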