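#' Balanced-random-forest hyperparameters
#'
#' The tunable set: number of trees, maximum depth (`NULL` = unlimited),
#' minimum node size to attempt a split, minimum terminal-node size, and the
#' rule for the number of candidate features per split (`"auto"`/`"sqrt"`
#' use `floor(sqrt(p))`, `"log2"` uses `floor(log2(p))`).
#'
#' @param n_estimators number of trees (>= 1).
#' @param max_depth maximum tree depth, `NULL` for unlimited.
#' @param min_samples_split minimum node size eligible for splitting (>= 2).
#' @param min_samples_leaf minimum terminal node size (>= 1).
#' @param max_features_mode `"auto"`, `"sqrt"`, or `"log2"`.
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(n_estimators = 100, max_depth = NULL,
                            min_samples_split = 2, min_samples_leaf = 1,
                            max_features_mode = c("auto", "sqrt", "log2")) {
  max_features_mode <- match.arg(max_features_mode)
  stopifnot(n_estimators >= 1, min_samples_split >= 2, min_samples_leaf >= 1,
            is.null(max_depth) || max_depth >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_features_mode = max_features_mode),
            class = "hyperparameters")
}

hp_key <- function(hp) {
  paste(hp$n_estimators, hp$max_depth %||% 0, hp$min_samples_split,
        hp$min_samples_leaf, hp$max_features_mode, sep = "|")
}

mtry_for <- function(mode, p) {
  switch(mode,
         auto = , sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))))
}

as_class_factor <- function(y) {
  y <- ambulation_factor(as.character(y))
  if (any(is.na(y))) stop("labels must be 'community' or 'household'")
  y
}

#' Train a balanced random forest
#'
#' Each tree is grown on an exactly class-balanced bootstrap: `n_min` draws
#' with replacement from each class, where `n_min` is the minority-class
#' count. This per-tree undersampling of the majority class counteracts the
#' strong class imbalance (most cohorts have far more community than
#' household ambulators at discharge). The aggregate prediction is the mean
#' of per-tree class probabilities. Deterministic given `seed`.
#'
#' @param X data frame or matrix of features (no missing values).
#' @param y class labels (`community` / `household`); both must be present.
#' @param hp a [hyperparameters()] object.
#' @param seed integer seed for the forest.
#' @return An object of class `balanced_forest`.
#' @export
train_balanced_forest <- function(X, y, hp = hyperparameters(), seed = 0) {
  X <- as.data.frame(X)
  y <- as_class_factor(y)
  if (anyNA(X)) stop("feature matrix contains missing values")
  tab <- table(y)
  if (any(tab == 0)) stop("both ambulation classes must be present")
  n_min <- min(tab)
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = hp$n_estimators,
    mtry = mtry_for(hp$max_features_mode, ncol(X)),
    min.node.size = hp$min_samples_split,
    min.bucket = hp$min_samples_leaf,
    max.depth = hp$max_depth %||% 0,
    replace = TRUE,
    sample.fraction = rep(n_min / length(y), 2),  # class-balanced per-tree bootstrap
    probability = TRUE,
    importance = "impurity",
    keep.inbag = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(fit = fit, feature_names = colnames(X),
                 classes = AMBULATION_CLASSES, seed = seed, hp = hp),
            class = "balanced_forest")
}

#' Predict ambulation class and community probability
#'
#' The label is the argmax class; an exact 0.5 tie resolves to household,
#' the clinically conservative choice (a support plan is made for a patient
#' predicted not to reach community ambulation).
#'
#' @param object a `balanced_forest`.
#' @param newdata data frame whose columns match the training features.
#' @param ... unused.
#' @return A list with `labels` (factor) and `prob_community` (numeric).
#' @export
predict.balanced_forest <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!identical(sort(colnames(newdata)), sort(object$feature_names))) {
    stop("feature names of newdata do not match the training features")
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  pr <- predict(object$fit, data = newdata, num.threads = 1)$predictions
  p_comm <- pr[, "community"]
  labels <- ambulation_factor(ifelse(p_comm > 0.5, "community", "household"))
  list(labels = labels, prob_community = as.numeric(p_comm))
}

#' Impurity-decrease feature importance of a balanced forest
#' @param model a `balanced_forest`.
#' @return Named numeric vector of raw impurity importances.
#' @export
forest_importance <- function(model) model$fit$variable.importance

# Stratified k-fold assignment; error if any class cannot cover the folds
# structure at all (n < k).
stratified_folds <- function(y, k, seed) {
  y <- as_class_factor(y)
  if (length(y) < k) stop("fewer samples than folds")
  local_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Default randomized-search space
#'
#' Candidate values for each tunable hyperparameter; `max_depth = 0` encodes
#' an unlimited depth. Override any axis via the arguments.
#' @param n_estimators,max_depth,min_samples_split,min_samples_leaf,max_features_mode
#'   candidate vectors.
#' @return A named list of candidate vectors.
#' @export
default_search_space <- function(n_estimators = c(50, 100, 200, 400),
                                 max_depth = c(0, 2, 4, 8, 16),
                                 min_samples_split = c(2, 4, 8),
                                 min_samples_leaf = c(1, 2, 4),
                                 max_features_mode = c("auto", "log2", "sqrt")) {
  list(n_estimators = n_estimators, max_depth = max_depth,
       min_samples_split = min_samples_split,
       min_samples_leaf = min_samples_leaf,
       max_features_mode = max_features_mode)
}

draw_config <- function(space) {
  pick <- function(v) v[[sample.int(length(v), 1)]]
  md <- pick(space$max_depth)
  hyperparameters(
    n_estimators = pick(space$n_estimators),
    max_depth = if (md == 0) NULL else md,
    min_samples_split = pick(space$min_samples_split),
    min_samples_leaf = pick(space$min_samples_leaf),
    max_features_mode = pick(space$max_features_mode))
}

cv_weighted_f1 <- function(X, y, hp, folds, seed) {
  fold <- stratified_folds(y, folds, seed)
  scores <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
    m <- train_balanced_forest(X[tr, , drop = FALSE], y[tr], hp, seed = seed)
    p <- predict(m, X[!tr, , drop = FALSE])
    scores[f] <- weighted_f1(confusion_counts(y[!tr], p$labels))
  }
  mean(scores)
}

#' Majority-vote randomized hyperparameter search
#'
#' Repeats a randomized search `n_iter` times with incremented seeds: each
#' iteration draws `n_draws` configurations from the space, scores each by
#' stratified k-fold cross-validated weighted F1, and records the winner
#' (ties to the earliest draw). The configuration winning the most iterations
#' is returned; vote ties resolve to the earliest-seed winner.
#'
#' @param table feature table (data frame).
#' @param labels class labels.
#' @param space candidate space from [default_search_space()].
#' @param n_iter number of search repetitions.
#' @param n_draws configurations sampled per repetition.
#' @param folds cross-validation folds (default 5).
#' @param seed_offset added to the 0-based iteration seeds.
#' @return The winning [hyperparameters()], with a `votes` attribute.
#' @export
tune_hyperparameters <- function(table, labels, space = default_search_space(),
                                 n_iter = 100, n_draws = 50, folds = 5,
                                 seed_offset = 0) {
  X <- as.data.frame(table)
  y <- as_class_factor(labels)
  if (nrow(X) < folds) stop("need at least as many samples as folds")
  if (nrow(X) < 10) stop("need at least 10 samples to tune")
  if (length(unique(y)) < 2) stop("both classes must be present")

  winners <- character(n_iter)
  configs <- list()
  for (it in seq_len(n_iter)) {
    seed <- seed_offset + it - 1
    cands <- local_seed(seed, replicate(n_draws, draw_config(space), simplify = FALSE))
    best <- NULL; best_score <- -Inf
    for (cfg in cands) {
      sc <- cv_weighted_f1(X, y, cfg, folds, seed)
      if (!is.na(sc) && sc > best_score) { best_score <- sc; best <- cfg }
    }
    winners[it] <- hp_key(best)
    if (is.null(configs[[winners[it]]])) configs[[winners[it]]] <- best
  }
  votes <- table(winners)
  top <- max(votes)
  # earliest-seed winner among the vote-tied configurations
  chosen_key <- winners[match(TRUE, winners %in% names(votes)[votes == top])]
  out <- configs[[chosen_key]]
  attr(out, "votes") <- sort(votes, decreasing = TRUE)
  out
}
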