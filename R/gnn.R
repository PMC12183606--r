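# Edge-conditioned message-passing network, written directly on matrix
# algebra with hand-derived gradients.
#
# Architecture (hidden width H, default 256):
#   L message-passing layers (default 4): node 40 -> H, then H -> H. Each
#   layer computes messages as a learned linear function of the source node
#   vector and the 11-d edge vector, aggregates incoming messages by mean,
#   adds a learned self-loop term and a bias, and applies ReLU. Edges are
#   undirected: messages pass in both directions.
#   Global mean pooling over nodes -> H.
#   In parallel the 88-d ligand-global and 74-d pocket-global vectors each
#   pass through their own H-unit fully connected ReLU layer.
#   The three H-d streams are concatenated -> fully connected H ("final
#   embedding", ReLU) -> dropout (training only) -> linear scalar head.
# Loss is mean absolute error; the optimizer is Adagrad (per-parameter
# accumulated squared gradients). No early stopping: a fixed epoch budget.

#' GNN training configuration
#'
#' Defaults follow the reference configuration: 256 hidden channels, 4
#' message-passing layers, dropout 0.2, learning rate 0.001, batches of 32,
#' 50 epochs. All values are overridable; the tuning search space is
#' \code{\link{gnn_search_space}}.
#'
#' @param hidden_channels hidden width H.
#' @param conv_layers number of message-passing layers.
#' @param dropout dropout rate on the final embedding during training.
#' @param learning_rate Adagrad learning rate.
#' @param batch_size graphs per optimizer step.
#' @param epochs training epochs.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return a `gnn_config`.
#' @export
gnn_config <- function(hidden_channels = 256L, conv_layers = 4L,
                       dropout = 0.2, learning_rate = 0.001,
                       batch_size = 32L, epochs = 50L, seed = 42L) {
  cfg <- list(hidden_channels = as.integer(hidden_channels),
              conv_layers = as.integer(conv_layers), dropout = dropout,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed))
  stopifnot(cfg$hidden_channels > 0, cfg$conv_layers > 0,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$learning_rate > 0,
            cfg$batch_size > 0, cfg$epochs > 0)
  structure(cfg, class = "gnn_config")
}

#' Hyperparameter search space
#'
#' The grid explored by \code{\link{tune_gnn}}: hidden channels 64/128/256,
#' 2-5 layers, dropout 0.2-0.5, learning rate 0.001-0.05, batch size 32-256,
#' 50-100 epochs.
#' @return named list of candidate values.
#' @export
gnn_search_space <- function() {
  list(hidden_channels = c(64L, 128L, 256L),
       conv_layers = c(2L, 3L, 4L, 5L),
       dropout = c(0.2, 0.3, 0.4, 0.5),
       learning_rate = c(0.001, 0.005, 0.01, 0.05),
       batch_size = c(32L, 64L, 128L, 256L),
       epochs = c(50L, 75L, 100L))
}

.glorot <- function(nout, nin) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nout * nin, -s, s), nout, nin)
}

.init_params <- function(cfg, node_dim = 40L, edge_dim = 11L,
                         lig_dim = 88L, pocket_dim = 74L) {
  H <- cfg$hidden_channels
  conv <- vector("list", cfg$conv_layers)
  din <- node_dim
  for (l in seq_len(cfg$conv_layers)) {
    conv[[l]] <- list(Wself = .glorot(H, din), Wmsg = .glorot(H, din),
                      Wedge = .glorot(H, edge_dim), b = numeric(H))
    din <- H
  }
  list(conv = conv,
       fc_lig = list(W = .glorot(H, lig_dim), b = numeric(H)),
       fc_pocket = list(W = .glorot(H, pocket_dim), b = numeric(H)),
       fc_comb = list(W = .glorot(H, 3L * H), b = numeric(H)),
       head = list(w = as.numeric(.glorot(1, H)), b = 0))
}

# apply an ablation variant to a graph's inputs
mask_graph_variant <- function(graph, variant) {
  if (variant %in% c("no_interactions", "atoms_only") &&
      nrow(graph$edge_matrix)) {
    graph$edge_matrix[, 1:9] <- 0   # energy + the 8 interaction flags
  }
  if (variant %in% c("no_globals", "atoms_only")) {
    graph$ligand_global[] <- 0
    graph$pocket_global[] <- 0
  }
  graph
}

# precompute the per-graph arrays the forward/backward passes need
.prepare_graph <- function(graph, variant = "full") {
  graph <- mask_graph_variant(graph, variant)
  n <- nrow(graph$node_matrix)
  m <- nrow(graph$edge_list)
  if (m > 0) {
    src <- c(graph$edge_list[, 1], graph$edge_list[, 2])
    dst <- c(graph$edge_list[, 2], graph$edge_list[, 1])
    E2 <- rbind(graph$edge_matrix, graph$edge_matrix)
    deg <- tabulate(dst, nbins = n)
  } else {
    src <- integer(0); dst <- integer(0)
    E2 <- matrix(0, 0, 11); deg <- integer(n)
  }
  list(X0 = unname(graph$node_matrix), E2 = unname(E2), src = src, dst = dst,
       deg = pmax(deg, 0L), n = n,
       lig = unname(graph$ligand_global), poc = unname(graph$pocket_global),
       y = graph$target, id = graph$id)
}

.mean_aggregate <- function(Msg, dst, deg, n, H) {
  Agg <- matrix(0, n, H)
  if (length(dst)) {
    S <- rowsum(Msg, group = dst)                 # rows sorted by unique dst
    tgt <- as.integer(rownames(S))
    Agg[tgt, ] <- S / deg[tgt]
  }
  Agg
}

.gnn_forward <- function(params, prep, no_globals = FALSE,
                         dropout_mask = NULL, dropout = 0) {
  H <- length(params$fc_comb$b)
  X <- prep$X0
  L <- length(params$conv)
  cache <- list(Xin = vector("list", L), P = vector("list", L))
  for (l in seq_len(L)) {
    ly <- params$conv[[l]]
    cache$Xin[[l]] <- X
    if (length(prep$src)) {
      Msg <- X[prep$src, , drop = FALSE] %*% t(ly$Wmsg) +
        prep$E2 %*% t(ly$Wedge)
      Agg <- .mean_aggregate(Msg, prep$dst, prep$deg, prep$n, H)
    } else Agg <- matrix(0, prep$n, H)
    P <- X %*% t(ly$Wself) + Agg
    P <- sweep(P, 2, ly$b, "+")
    cache$P[[l]] <- P
    X <- P * (P > 0)
  }
  pool <- colMeans(X)
  if (no_globals) {
    ligp <- numeric(H); poch_p <- numeric(H)
    ligh <- numeric(H); poch <- numeric(H)
  } else {
    ligp <- as.numeric(params$fc_lig$W %*% prep$lig) + params$fc_lig$b
    poch_p <- as.numeric(params$fc_pocket$W %*% prep$poc) + params$fc_pocket$b
    ligh <- pmax(ligp, 0); poch <- pmax(poch_p, 0)
  }
  z <- c(pool, ligh, poch)
  cp <- as.numeric(params$fc_comb$W %*% z) + params$fc_comb$b
  e <- pmax(cp, 0)
  if (!is.null(dropout_mask)) {
    ed <- e * dropout_mask / (1 - dropout)
  } else ed <- e
  pred <- sum(params$head$w * ed) + params$head$b
  list(pred = pred, embedding = e, ed = ed, cp = cp, z = z, pool = pool,
       ligp = ligp, pocp = poch_p, Xlast = X, cache = cache)
}

.zero_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

.gnn_backward <- function(params, prep, fw, dpred, no_globals = FALSE,
                          dropout_mask = NULL, dropout = 0) {
  H <- length(params$fc_comb$b)
  n <- prep$n
  g <- list()
  d_ed <- dpred * params$head$w
  g$head <- list(w = dpred * fw$ed, b = dpred)
  d_e <- if (!is.null(dropout_mask)) d_ed * dropout_mask / (1 - dropout)
         else d_ed
  d_cp <- d_e * (fw$cp > 0)
  g$fc_comb <- list(W = outer(d_cp, fw$z), b = d_cp)
  d_z <- as.numeric(t(params$fc_comb$W) %*% d_cp)
  d_pool <- d_z[seq_len(H)]
  if (no_globals) {
    g$fc_lig <- list(W = params$fc_lig$W * 0, b = numeric(H))
    g$fc_pocket <- list(W = params$fc_pocket$W * 0, b = numeric(H))
  } else {
    d_ligh <- d_z[H + seq_len(H)]
    d_poch <- d_z[2 * H + seq_len(H)]
    d_ligp <- d_ligh * (fw$ligp > 0)
    d_pocp <- d_poch * (fw$pocp > 0)
    g$fc_lig <- list(W = outer(d_ligp, prep$lig), b = d_ligp)
    g$fc_pocket <- list(W = outer(d_pocp, prep$poc), b = d_pocp)
  }
  dX <- matrix(d_pool / n, n, H, byrow = TRUE)
  L <- length(params$conv)
  g$conv <- vector("list", L)
  for (l in rev(seq_len(L))) {
    ly <- params$conv[[l]]
    P <- fw$cache$P[[l]]
    Xin <- fw$cache$Xin[[l]]
    dP <- dX * (P > 0)
    gb <- colSums(dP)
    gWself <- t(dP) %*% Xin
    dXin <- dP %*% ly$Wself
    if (length(prep$src)) {
      dMsg <- dP[prep$dst, , drop = FALSE] / prep$deg[prep$dst]
      gWmsg <- t(dMsg) %*% Xin[prep$src, , drop = FALSE]
      gWedge <- t(dMsg) %*% prep$E2
      back <- rowsum(dMsg %*% ly$Wmsg, group = prep$src)
      tgt <- as.integer(rownames(back))
      dXin[tgt, ] <- dXin[tgt, ] + back
    } else {
      gWmsg <- ly$Wmsg * 0
      gWedge <- ly$Wedge * 0
    }
    g$conv[[l]] <- list(Wself = gWself, Wmsg = gWmsg, Wedge = gWedge, b = gb)
    dX <- dXin
  }
  g[c("conv", "fc_lig", "fc_pocket", "fc_comb", "head")]
}

.walk_update <- function(params, grads, accum, lr, eps = 1e-10) {
  rec <- function(p, g, a) {
    if (is.list(p)) {
      out_p <- p; out_a <- a
      for (nm in names(p)) {
        r <- rec(p[[nm]], g[[nm]], a[[nm]])
        out_p[[nm]] <- r$p; out_a[[nm]] <- r$a
      }
      list(p = out_p, a = out_a)
    } else {
      a2 <- a + g * g
      list(p = p - lr * g / (sqrt(a2) + eps), a = a2)
    }
  }
  rec(params, grads, accum)
}

.accumulate <- function(g1, g2) {
  if (is.list(g1)) {
    for (nm in names(g1)) g1[[nm]] <- .accumulate(g1[[nm]], g2[[nm]])
    g1
  } else g1 + g2
}

#' Train the message-passing network
#'
#' Trains with mean-absolute-error loss and the Adagrad optimizer on
#' mini-batches. Fully deterministic given `cfg$seed`. Per-epoch mean
#' training MAE is recorded in `$history`.
#'
#' @param graphs list of scaled `plaig_graph`s with finite targets; at least
#'   `2 * cfg$batch_size` of them.
#' @param cfg a \code{\link{gnn_config}}.
#' @param variant ablation variant: "full", "no_interactions", "no_globals"
#'   or "atoms_only" (see \code{\link{train_affinity_model}}).
#' @param verbose print per-epoch loss.
#' @return a `plaig_gnn`: list(params, cfg, variant, history).
#' @export
train_gnn <- function(graphs, cfg = gnn_config(), variant = "full",
                      verbose = FALSE) {
  variant <- match.arg(variant,
                       c("full", "no_interactions", "no_globals", "atoms_only"))
  ng <- length(graphs)
  if (ng < 2 * cfg$batch_size)
    stop("need at least 2 * batch_size = ", 2 * cfg$batch_size, " graphs")
  ys <- vapply(graphs, `[[`, numeric(1), "target")
  if (any(!is.finite(ys))) stop("all training targets must be finite")
  no_glob <- variant %in% c("no_globals", "atoms_only")
  set.seed(cfg$seed)
  preps <- lapply(graphs, .prepare_graph, variant = variant)
  params <- .init_params(cfg)
  # start the scalar head at the mean target so the MAE loss optimizes
  # deviations rather than spending epochs drifting to the right offset
  params$head$b <- mean(ys)
  accum <- .zero_like(params)
  H <- cfg$hidden_channels
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(ng)
    ep_loss <- 0
    for (start in seq(1, ng, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, ng)]
      bs <- length(idx)
      gsum <- NULL
      for (gi in idx) {
        prep <- preps[[gi]]
        mask <- if (cfg$dropout > 0)
          as.numeric(runif(H) >= cfg$dropout) else NULL
        fw <- .gnn_forward(params, prep, no_globals = no_glob,
                           dropout_mask = mask, dropout = cfg$dropout)
        err <- fw$pred - prep$y
        if (!is.finite(err))
          stop(sprintf(
            "non-finite loss at epoch %d on graph '%s' (pred=%g, target=%g)",
            ep, prep$id, fw$pred, prep$y))
        ep_loss <- ep_loss + abs(err)
        dpred <- sign(err) / bs
        gr <- .gnn_backward(params, prep, fw, dpred, no_globals = no_glob,
                            dropout_mask = mask, dropout = cfg$dropout)
        gsum <- if (is.null(gsum)) gr else .accumulate(gsum, gr)
      }
      upd <- .walk_update(params, gsum, accum, cfg$learning_rate)
      params <- upd$p; accum <- upd$a
    }
    history[ep] <- ep_loss / ng
    if (verbose)
      message(sprintf("epoch %3d  train MAE %.4f", ep, history[ep]))
  }
  structure(list(params = params, cfg = cfg, variant = variant,
                 history = history, schema_version = feature_schema()$version),
            class = "plaig_gnn")
}

#' Graph-level embedding
#'
#' Returns the final-embedding activation (the input to the dropout/linear
#' head), with dropout disabled.
#'
#' @param gnn a trained `plaig_gnn`.
#' @param graph a scaled `plaig_graph`.
#' @return numeric vector of length `hidden_channels`.
#' @export
gnn_embed <- function(gnn, graph) {
  stopifnot(inherits(gnn, "plaig_gnn"))
  if (!identical(graph$schema_version, gnn$schema_version))
    stop("graph schema version ", graph$schema_version,
         " does not match the model's ", gnn$schema_version)
  prep <- .prepare_graph(graph, gnn$variant)
  fw <- .gnn_forward(gnn$params, prep,
                     no_globals = gnn$variant %in% c("no_globals", "atoms_only"))
  fw$embedding
}

#' Direct GNN prediction (linear head on the embedding)
#' @param gnn a trained `plaig_gnn`.
#' @param graph a scaled `plaig_graph`.
#' @return predicted affinity (pKd/pKi).
#' @export
gnn_predict <- function(gnn, graph) {
  e <- gnn_embed(gnn, graph)
  sum(gnn$params$head$w * e) + gnn$params$head$b
}
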