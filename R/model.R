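# Stacking ensemble over GNN embeddings and the full hybrid affinity model.

#' Train the stacking ensemble on GNN embeddings
#'
#' Two base tree-ensemble regressors (random forest and gradient-boosted
#' trees, 500 trees each) are fit on the embedding matrix; a
#' ridge-regularized linear meta-learner is fit on their out-of-fold
#' predictions from an internal 5-fold split, then the base learners are
#' refit on all data.
#'
#' @param embeddings n x H numeric matrix of graph embeddings.
#' @param targets numeric vector of length n (pKd/pKi), n >= 50.
#' @param seed RNG seed for fold assignment and the tree ensembles.
#' @param n_trees trees per base learner (default 500).
#' @param folds internal folds for the meta-learner (default 5).
#' @return a `plaig_stacking`.
#' @export
train_stacking <- function(embeddings, targets, seed = 42L, n_trees = 500L,
                           folds = 5L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 50) stop("need at least 50 training complexes for stacking, got ", n)
  stopifnot(length(targets) == n, all(is.finite(targets)))
  colnames(embeddings) <- paste0("e", seq_len(ncol(embeddings)))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  oof <- matrix(NA_real_, n, 2)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    set.seed(seed + f)
    rf <- randomForest::randomForest(embeddings[tr, , drop = FALSE],
                                     targets[tr], ntree = n_trees)
    xgb <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", seed = seed + f,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(embeddings[tr, , drop = FALSE],
                                  label = targets[tr]),
      nrounds = n_trees)
    oof[te, 1] <- predict(rf, embeddings[te, , drop = FALSE])
    oof[te, 2] <- predict(xgb, embeddings[te, , drop = FALSE])
  }
  # ridge meta-learner on out-of-fold base predictions (intercept free)
  A <- cbind(1, oof)
  lambda <- 1e-3
  pen <- diag(c(0, lambda, lambda))
  beta <- solve(crossprod(A) + pen, crossprod(A, targets))
  set.seed(seed)
  rf_full <- randomForest::randomForest(embeddings, targets, ntree = n_trees)
  xgb_full <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", seed = seed, nthread = 1),
    data = xgboost::xgb.DMatrix(embeddings, label = targets),
    nrounds = n_trees)
  structure(list(rf = rf_full, xgb_raw = xgboost::xgb.save.raw(xgb_full),
                 beta = as.numeric(beta), seed = seed, n_trees = n_trees,
                 n_features = ncol(embeddings)),
            class = "plaig_stacking")
}

.stacking_xgb <- function(stack) {
  # rebuild the booster handle from raw bytes (survives save/load)
  if (is.null(attr(stack, "xgb_handle", exact = TRUE))) {
    attr(stack, "xgb_handle") <- xgboost::xgb.load.raw(stack$xgb_raw)
  }
  attr(stack, "xgb_handle")
}

#' Predict with a stacking ensemble
#' @param stack a `plaig_stacking`.
#' @param embeddings n x H matrix (or single embedding vector).
#' @return numeric predictions.
#' @export
predict_stacking <- function(stack, embeddings) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1)
  colnames(embeddings) <- paste0("e", seq_len(ncol(embeddings)))
  p_rf <- predict(stack$rf, embeddings)
  p_xgb <- predict(.stacking_xgb(stack), xgboost::xgb.DMatrix(embeddings))
  as.numeric(cbind(1, p_rf, p_xgb) %*% stack$beta)
}

#' Train the full hybrid affinity model
#'
#' Runs the complete training path: fit feature scalers on the raw training
#' graphs, scale, train the message-passing network, extract its graph-level
#' embeddings, and fit the stacking ensemble on them. The `variant` argument
#' provides the ablation switches: \describe{
#'   \item{full}{all features;}
#'   \item{no_interactions}{the electrostatic-energy slot and the 8
#'     interaction flags on every edge are zeroed;}
#'   \item{no_globals}{both global vectors are zeroed and their
#'     fully connected branches are bypassed;}
#'   \item{atoms_only}{both of the above.}}
#'
#' @param graphs list of raw (unscaled) `plaig_graph`s with finite targets.
#' @param cfg a \code{\link{gnn_config}}.
#' @param variant ablation variant (default "full").
#' @param stack fit the stacking stage (default TRUE; FALSE gives the bare
#'   GNN predictions through the same interface).
#' @param verbose print training progress.
#' @return a `plaig_model`.
#' @export
train_affinity_model <- function(graphs, cfg = gnn_config(),
                                 variant = "full", stack = TRUE,
                                 verbose = FALSE) {
  scaler <- fit_scalers(graphs)
  scaled <- lapply(graphs, scale_graph, scaler = scaler)
  gnn <- train_gnn(scaled, cfg, variant = variant, verbose = verbose)
  stacking <- NULL
  if (stack) {
    emb <- t(vapply(scaled, function(g) gnn_embed(gnn, g),
                    numeric(cfg$hidden_channels)))
    ys <- vapply(scaled, `[[`, numeric(1), "target")
    stacking <- train_stacking(emb, ys, seed = cfg$seed)
  }
  structure(list(gnn = gnn, stacking = stacking, scaler = scaler,
                 cfg = cfg, variant = variant,
                 schema_version = feature_schema()$version),
            class = "plaig_model")
}

#' Train an ablation variant
#'
#' Convenience wrapper over \code{\link{train_affinity_model}} with the
#' variant switches exposed as the first argument.
#' @param graphs raw training graphs.
#' @param cfg a \code{\link{gnn_config}}.
#' @param variant "full", "no_interactions", "no_globals" or "atoms_only".
#' @param ... passed on.
#' @return a `plaig_model`.
#' @export
ablate <- function(graphs, cfg = gnn_config(),
                   variant = c("full", "no_interactions", "no_globals",
                               "atoms_only"), ...) {
  variant <- match.arg(variant)
  train_affinity_model(graphs, cfg, variant = variant, ...)
}

#' Predict binding affinity for complex graphs
#'
#' @param object a trained `plaig_model`.
#' @param graphs a `plaig_graph` or list of them; raw graphs are scaled with
#'   the model's stored scaler, already-scaled graphs pass through.
#' @param ... unused.
#' @return numeric vector of predictions in pKd/pKi units.
#' @export
predict.plaig_model <- function(object, graphs, ...) {
  if (inherits(graphs, "plaig_graph")) graphs <- list(graphs)
  vapply(graphs, function(g) {
    if (!isTRUE(g$scaled)) g <- scale_graph(g, object$scaler)
    e <- gnn_embed(object$gnn, g)
    if (is.null(object$stacking)) {
      sum(object$gnn$params$head$w * e) + object$gnn$params$head$b
    } else {
      predict_stacking(object$stacking, e)
    }
  }, numeric(1))
}

#' @export
print.plaig_model <- function(x, ...) {
  cat(sprintf("<plaig_model> variant '%s', H=%d, %d conv layers%s\n",
              x$variant, x$cfg$hidden_channels, x$cfg$conv_layers,
              if (is.null(x$stacking)) " (GNN only)" else " + stacking"))
  invisible(x)
}

#' Save / load a trained model as one artifact
#'
#' The artifact bundles scalers, network weights and both ensembles
#' (the boosted ensemble as raw bytes) in a single file;
#' `load_model(save_model(m))` gives bit-identical predictions.
#'
#' @param model a `plaig_model`.
#' @param path artifact path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "plaig_model"))
  if (!is.null(model$stacking))
    attr(model$stacking, "xgb_handle") <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `plaig_model`.
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("cannot load model artifact ",
                                             path, ": ", conditionMessage(e)))
  if (!inherits(model, "plaig_model"))
    stop("artifact ", path, " is not a plaig model (class: ",
         paste(class(model), collapse = ","), ")")
  if (!identical(model$schema_version, feature_schema()$version))
    stop("artifact schema version ", model$schema_version,
         " does not match this package's ", feature_schema()$version)
  model
}

# ---------------------------------------------------------------------------
# Sequential hyperparameter search.

.sample_config <- function(space, base = NULL) {
  pick <- function(nm) space[[nm]][sample.int(length(space[[nm]]), 1)]
  vals <- lapply(names(space), pick)
  names(vals) <- names(space)
  if (!is.null(base)) {
    # local move: perturb one dimension of the base config
    vals <- base[names(space)]
    dim_ <- sample(names(space), 1)
    vals[[dim_]] <- pick(dim_)
  }
  do.call(gnn_config, c(vals, list(seed = base$seed %||% 42L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequential hyperparameter search over the GNN grid
#'
#' Evaluates up to `max_evals` configurations by 5-fold cross-validated
#' Pearson correlation of the network stage (the objective is the negative
#' mean CV PCC, minimized). The search is sequential: the first half of the
#' budget explores random draws from the space, the second half perturbs the
#' best configuration found so far one dimension at a time. The full trial
#' log is attached as `attr(, "trials")`.
#'
#' @param graphs raw training graphs with targets.
#' @param space candidate grid, see \code{\link{gnn_search_space}}.
#' @param max_evals evaluation budget (default 20).
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @return the best `gnn_config`, with the trial log attached.
#' @export
tune_gnn <- function(graphs, space = gnn_search_space(), max_evals = 20L,
                     folds = 5L, seed = 42L) {
  stopifnot(length(graphs) >= folds)
  set.seed(seed)
  n <- length(graphs)
  fold_id <- sample(rep_len(seq_len(folds), n))
  n_grid <- prod(vapply(space, length, numeric(1)))
  max_evals <- min(max_evals, n_grid)
  seen <- character(0)
  trials <- list()
  best_cfg <- NULL; best_obj <- Inf
  cv_pcc <- function(cfg) {
    pccs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      scaler <- fit_scalers(graphs[tr])
      strain <- lapply(graphs[tr], scale_graph, scaler = scaler)
      stest <- lapply(graphs[te], scale_graph, scaler = scaler)
      cfg_f <- cfg; cfg_f$batch_size <- min(cfg$batch_size,
                                            max(1L, length(tr) %/% 2L))
      gnn <- train_gnn(strain, cfg_f)
      pred <- vapply(stest, function(g) gnn_predict(gnn, g), numeric(1))
      act <- vapply(stest, `[[`, numeric(1), "target")
      pccs[f] <- suppressWarnings(cor(pred, act))
    }
    mean(pccs, na.rm = TRUE)
  }
  ev <- 0L
  while (ev < max_evals) {
    base <- if (ev >= ceiling(max_evals / 2) && !is.null(best_cfg))
      best_cfg else NULL
    cfg <- .sample_config(space, base)
    cfg$seed <- as.integer(seed)
    key <- paste(unlist(cfg[names(space)]), collapse = "|")
    if (key %in% seen) {
      if (length(seen) >= n_grid) break
      next
    }
    seen <- c(seen, key)
    ev <- ev + 1L
    pcc <- cv_pcc(cfg)
    obj <- -pcc
    trials[[ev]] <- data.frame(trial = ev, key = key, mean_cv_pcc = pcc)
    if (is.finite(obj) && obj < best_obj) { best_obj <- obj; best_cfg <- cfg }
  }
  if (is.null(best_cfg)) stop("no successful tuning trial")
  attr(best_cfg, "trials") <- do.call(rbind, trials)
  best_cfg
}
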