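#' Remove highly correlated features
#'
#' Drops zero-variance features first, then scans feature pairs in catalog
#' (column) order: when the absolute Pearson correlation of a candidate with
#' any already-kept earlier feature exceeds the threshold, the later-ordered
#' feature is dropped. The audit log of (kept, dropped, r) triples is
#' attached as the `drop_log` attribute. Idempotent.
#'
#' @param table feature table (data frame) with at least 2 rows.
#' @param threshold correlation threshold in (0, 1\] (default 0.9).
#' @return The reduced table, with attributes `drop_log` and `dropped`.
#' @export
drop_correlated <- function(table, threshold = 0.9) {
  X <- as.data.frame(table)
  if (nrow(X) < 2) stop("need at least 2 rows to estimate correlations")
  stopifnot(threshold > 0, threshold <= 1)
  nm <- colnames(X)
  variances <- vapply(X, function(col) stats::var(col), numeric(1))
  zero_var <- nm[variances == 0 | is.na(variances)]
  keep <- setdiff(nm, zero_var)
  log <- data.frame(kept = character(0), dropped = character(0), r = numeric(0),
                    stringsAsFactors = FALSE)
  kept <- character(0)
  for (j in keep) {
    r_with_kept <- if (length(kept)) {
      as.numeric(cor(X[[j]], X[, kept, drop = FALSE]))
    } else numeric(0)
    r_with_kept[is.na(r_with_kept)] <- 0
    hit <- which(abs(r_with_kept) > threshold)
    if (length(hit)) {
      log <- rbind(log, data.frame(kept = kept[hit[1]], dropped = j,
                                   r = r_with_kept[hit[1]],
                                   stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, j)
    }
  }
  out <- X[, kept, drop = FALSE]
  attr(out, "paradigm") <- attr(table, "paradigm", exact = TRUE)
  attr(out, "drop_log") <- log
  attr(out, "dropped") <- c(zero_var, log$dropped)
  class(out) <- class(table)
  out
}

# One run of recursive feature elimination with internal cross-validation:
# per fold, features are eliminated one at a time by lowest impurity
# importance and the held-out weighted F1 is recorded at every subset size;
# the size maximizing the fold-averaged score (ties -> smaller) is selected,
# the elimination is replayed on the full data down to that size, and the
# final refit's normalized importances are returned (unselected features 0).
rfecv_once <- function(X, y, hp, seed, folds = 5) {
  p <- ncol(X)
  nm <- colnames(X)
  fold <- stratified_folds(y, folds, seed)
  scores <- matrix(NA_real_, nrow = p, ncol = folds)  # row k = subset size k
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    active <- nm
    for (k in seq(p, 1)) {
      m <- train_balanced_forest(X[tr, active, drop = FALSE], y[tr], hp, seed = seed)
      pr <- predict(m, X[!tr, active, drop = FALSE])
      scores[k, f] <- weighted_f1_labels(y[!tr], pr$labels)
      if (k > 1) {
        imp <- forest_importance(m)[active]
        imp[is.na(imp)] <- 0
        active <- active[-which.min(imp)]   # which.min: earliest tie dropped
      }
    }
  }
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  k_star <- which.max(mean_scores)          # ties -> smaller subset
  # replay elimination on the full data down to k_star
  active <- nm
  while (length(active) > k_star) {
    m <- train_balanced_forest(X[, active, drop = FALSE], y, hp, seed = seed)
    imp <- forest_importance(m)[active]
    imp[is.na(imp)] <- 0
    active <- active[-which.min(imp)]
  }
  m <- train_balanced_forest(X[, active, drop = FALSE], y, hp, seed = seed)
  imp <- forest_importance(m)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- stats::setNames(numeric(p), nm)
  out[names(imp)] <- imp
  out
}

#' Seed-averaged recursive-feature-elimination importance
#'
#' Runs recursive feature elimination with internal stratified k-fold
#' cross-validation once per seed (`seed_offset + 0 .. n_iter - 1`); each
#' run contributes the normalized impurity importances of its selected
#' subset (unselected features contribute 0 that iteration). The accumulated
#' scores are normalized by their grand total, yielding importances that sum
#' to 1 and a cumulative rank order.
#'
#' @param table feature table (data frame).
#' @param labels class labels; both classes required.
#' @param hp a [hyperparameters()] for the internal estimator.
#' @param n_iter number of seeded repetitions (>= 1).
#' @param folds internal cross-validation folds.
#' @param seed_offset first seed.
#' @return An object of class `importance_ranking`: data frame with
#'   `feature`, `importance`, `rank`, sorted by descending importance
#'   (ties broken by catalog order).
#' @export
aggregate_importance <- function(table, labels, hp = hyperparameters(),
                                 n_iter = 100, folds = 5, seed_offset = 0) {
  X <- as.data.frame(table)
  y <- as_class_factor(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(n_iter >= 1)
  acc <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (it in seq_len(n_iter)) {
    acc <- acc + rfecv_once(X, y, hp, seed = seed_offset + it - 1, folds = folds)
  }
  if (sum(acc) > 0) acc <- acc / sum(acc) else acc[] <- 1 / length(acc)
  ord <- order(-acc, seq_along(acc))
  out <- data.frame(feature = names(acc)[ord], importance = unname(acc[ord]),
                    rank = seq_along(acc), stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Backward elimination over the cumulative importance order
#'
#' For every subset size k (full set down to 1), evaluates the top-k features
#' by seed-averaged leave-one-subject-out weighted F1 and returns the
#' performance curve together with the subset maximizing the mean score
#' (ties resolve to fewer features).
#'
#' @param table feature table.
#' @param labels class labels.
#' @param ranking an `importance_ranking` covering exactly the table's features.
#' @param hp a [hyperparameters()].
#' @param n_seeds seeds per subset size.
#' @param seed_offset first seed.
#' @return An object of class `selection_curve`: `curve` (data frame `k`,
#'   `mean_f1`, `sd_f1`, `chosen`), `k`, `features` (the selected subset).
#' @export
backward_elimination <- function(table, labels, ranking,
                                 hp = hyperparameters(), n_seeds = 100,
                                 seed_offset = 0) {
  X <- as.data.frame(table)
  y <- as_class_factor(labels)
  if (!setequal(ranking$feature, colnames(X))) {
    stop("ranking does not cover the table's features")
  }
  ordered_feats <- ranking$feature[order(ranking$rank)]
  p <- length(ordered_feats)
  mean_f1 <- sd_f1 <- numeric(p)
  for (k in seq_len(p)) {
    feats <- ordered_feats[seq_len(k)]
    f1 <- vapply(seq_len(n_seeds) - 1, function(s) {
      res <- loso_predict(X[, feats, drop = FALSE], y, hp, seed = seed_offset + s)
      weighted_f1_labels(res$truth, res$pred)
    }, numeric(1))
    mean_f1[k] <- mean(f1)
    sd_f1[k] <- if (n_seeds > 1) sd(f1) else 0
  }
  k_star <- which.max(mean_f1)   # ties -> smaller k (parsimony)
  curve <- data.frame(k = seq_len(p), mean_f1 = mean_f1, sd_f1 = sd_f1,
                      chosen = seq_len(p) == k_star)
  structure(list(curve = curve, k = k_star,
                 features = ordered_feats[seq_len(k_star)]),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("<selection_curve> chose k = %d (mean weighted F1 = %.3f)\n",
              x$k, x$curve$mean_f1[x$k]))
  cat("features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
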