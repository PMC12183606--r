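# Metrics, cross-validation, outlier removal, active/decoy discrimination,
# and free-energy conversion.

# rank-statistic ROC AUC with tie averaging; positives = labels TRUE
.rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression evaluation metrics
#'
#' Pearson correlation, mean squared error, mean absolute error, coefficient
#' of determination (1 - SSres/SStot), and the median-split AUC: how well
#' the predictions separate complexes whose actual affinity lies above the
#' median from those at or below it (ties assigned to the low class).
#'
#' @param pred,actual numeric vectors of equal length >= 2.
#' @return a `plaig_eval` list with pcc, mse, mae, r2, auc, n.
#' @export
eval_metrics <- function(pred, actual) {
  stopifnot(length(pred) == length(actual), length(pred) >= 2)
  if (sd(actual) == 0) {
    warning("constant actual values: pcc, r2 and auc are undefined")
    pcc <- NaN; r2 <- NaN; auc <- NaN
  } else {
    pcc <- cor(pred, actual)
    r2 <- 1 - sum((actual - pred)^2) / sum((actual - mean(actual))^2)
    auc <- .rank_auc(pred, actual > median(actual))
  }
  structure(list(pcc = pcc, mse = mean((pred - actual)^2),
                 mae = mean(abs(pred - actual)), r2 = r2, auc = auc,
                 n = length(pred)), class = "plaig_eval")
}

#' @export
print.plaig_eval <- function(x, ...) {
  cat(sprintf("PCC %.3f | MSE %.3f | MAE %.3f | R2 %.3f | AUC %.3f (n=%d)\n",
              x$pcc, x$mse, x$mae, x$r2, x$auc, x$n))
  invisible(x)
}

#' Repeated-split cross-validation
#'
#' Default scheme: `folds` independent randomized train/test splits at the
#' given training fraction (80:20). The classic partitioned k-fold scheme is
#' available via `method = "kfold"` (where the train fraction is implied by
#' the fold count).
#'
#' @param graphs list of raw `plaig_graph`s with targets.
#' @param model_factory function(train_graphs) returning an object with a
#'   `predict(object, graphs)` method (e.g. a wrapper around
#'   \code{\link{train_affinity_model}}).
#' @param folds number of splits (default 10).
#' @param train_frac training fraction for the repeated scheme (default 0.8).
#' @param seed RNG seed for fold memberships.
#' @param method "repeated" (default) or "kfold".
#' @return data.frame with one row per fold (pcc, mse, mae, r2, auc, n_test,
#'   runtime_s) plus mean/sd summary rows as attributes.
#' @export
crossvalidate <- function(graphs, model_factory, folds = 10L,
                          train_frac = 0.8, seed = 42L,
                          method = c("repeated", "kfold")) {
  method <- match.arg(method)
  n <- length(graphs)
  stopifnot(n >= 5)
  set.seed(seed)
  rows <- vector("list", folds)
  if (method == "kfold") fold_id <- sample(rep_len(seq_len(folds), n))
  for (f in seq_len(folds)) {
    if (method == "repeated") {
      tr <- sort(sample.int(n, round(train_frac * n)))
    } else {
      tr <- which(fold_id != f)
    }
    te <- setdiff(seq_len(n), tr)
    t0 <- proc.time()[["elapsed"]]
    model <- model_factory(graphs[tr])
    pred <- predict(model, graphs[te])
    rt <- proc.time()[["elapsed"]] - t0
    act <- vapply(graphs[te], `[[`, numeric(1), "target")
    m <- eval_metrics(pred, act)
    rows[[f]] <- data.frame(fold = f, pcc = m$pcc, mse = m$mse, mae = m$mae,
                            r2 = m$r2, auc = m$auc, n_test = length(te),
                            runtime_s = rt)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "mean") <- colMeans(tab[, c("pcc", "mse", "mae", "r2", "auc")])
  attr(tab, "sd") <- apply(tab[, c("pcc", "mse", "mae", "r2", "auc")], 2, sd)
  tab
}

#' Residual z-score outlier filter
#'
#' Drops complexes whose prediction residual lies more than `z_max` standard
#' deviations from the mean residual (single pass; the statistics are
#' computed once on the full input, matching a one-shot training-set
#' filtering step).
#'
#' @param pred,actual numeric vectors of equal length.
#' @param ids complex identifiers (default positional indices).
#' @param z_max z-score threshold (default 3).
#' @return surviving ids, in input order.
#' @export
remove_outliers <- function(pred, actual, ids = seq_along(pred), z_max = 3.0) {
  stopifnot(length(pred) == length(actual), length(ids) == length(pred))
  r <- pred - actual
  s <- sd(r)
  if (!is.finite(s) || s == 0) return(ids)
  z <- abs(r - mean(r)) / s
  ids[z <= z_max]
}

#' Active/decoy discrimination report
#'
#' ROC AUC of affinity predictions against active/decoy labels, a Welch
#' two-sample t-test comparing the group means, classification rates at the
#' activity cutoff (default pKd 6, i.e. 1 uM), and per-group distribution
#' summaries for violin-style plotting.
#'
#' @param pred_pkd predicted affinities in pKd/pKi units.
#' @param labels factor/character with values "active" and "decoy".
#' @param cutoff_pkd active/decoy affinity threshold (default 6.0).
#' @return list(auc, p_value, t_statistic, cutoff_pkd, group_summary,
#'   accuracy_at_cutoff).
#' @export
active_decoy_report <- function(pred_pkd, labels, cutoff_pkd = 6.0) {
  labels <- as.character(labels)
  stopifnot(length(pred_pkd) == length(labels),
            all(labels %in% c("active", "decoy")))
  if (length(unique(labels)) < 2)
    stop("both classes (active and decoy) must be present")
  act <- labels == "active"
  auc <- .rank_auc(pred_pkd, act)
  # Welch by default; degenerate (constant) samples give an NA p-value
  tt <- tryCatch(t.test(pred_pkd[act], pred_pkd[!act]),
                 error = function(e) list(p.value = NA_real_,
                                          statistic = c(t = NA_real_)))
  summarise <- function(v) {
    qs <- quantile(v, c(0.25, 0.5, 0.75))
    data.frame(n = length(v), mean = mean(v), sd = sd(v), min = min(v),
               q25 = qs[1], median = qs[2], q75 = qs[3], max = max(v))
  }
  gs <- rbind(active = summarise(pred_pkd[act]),
              decoy = summarise(pred_pkd[!act]))
  acc <- mean((pred_pkd >= cutoff_pkd) == act)
  list(auc = auc, p_value = tt$p.value, t_statistic = unname(tt$statistic),
       cutoff_pkd = cutoff_pkd, group_summary = gs,
       accuracy_at_cutoff = acc)
}

#' Convert a binding free energy to Kd and pKd
#'
#' `Kd = exp(dG / (R T))` with R = 1.9872e-3 kcal/(mol K); pKd = -log10(Kd).
#' At dG = 0 the dissociation constant is 1 M (pKd 0); more negative free
#' energies give tighter binding.
#'
#' @param delta_g binding free energy in kcal/mol (vectorized).
#' @param temperature temperature in Kelvin (default 298).
#' @return data.frame with columns delta_g, Kd (molar), pKd.
#' @export
dg_to_pkd <- function(delta_g, temperature = 298) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  R <- 1.9872e-3
  Kd <- exp(delta_g / (R * temperature))
  data.frame(delta_g = delta_g, Kd = Kd, pKd = -log10(Kd))
}

#' Inverse of \code{\link{dg_to_pkd}}
#' @param pkd affinity in pKd units.
#' @param temperature Kelvin (default 298).
#' @return free energy in kcal/mol.
#' @export
pkd_to_dg <- function(pkd, temperature = 298) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  R <- 1.9872e-3
  log(10^(-pkd)) * R * temperature
}
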