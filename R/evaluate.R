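#' Confusion counts for the two ambulation classes
#'
#' @param truth,pred true and predicted class labels.
#' @return A 2 x 2 integer matrix (rows = truth, cols = predicted) of class
#'   `confusion_counts`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as_class_factor(truth); pred <- as_class_factor(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  m <- table(truth = truth, pred = pred)
  structure(unclass(m), class = c("confusion_counts", "matrix"))
}

#' Build confusion counts from per-class correct counts
#'
#' Convenience for worked examples quoted as "k of n community correct":
#' misclassified patients are assigned to the opposite class.
#'
#' @param community_correct,community_total,household_correct,household_total
#'   per-class correct and total counts.
#' @return A `confusion_counts` matrix.
#' @export
confusion_from_recall <- function(community_correct, community_total,
                                  household_correct, household_total) {
  m <- matrix(c(community_correct, community_total - community_correct,
                household_total - household_correct, household_correct),
              nrow = 2, byrow = TRUE,
              dimnames = list(truth = AMBULATION_CLASSES,
                              pred = AMBULATION_CLASSES))
  structure(m, class = c("confusion_counts", "matrix"))
}

check_cc <- function(cc) {
  if (!is.matrix(cc) || !all(dim(cc) == 2)) stop("need a 2 x 2 confusion matrix")
  if (sum(cc) < 1) stop("confusion matrix is empty")
  cc
}

#' Support-weighted F1 score
#'
#' Per-class F1 = 2PR/(P+R) (0 when P + R = 0), averaged with weights equal
#' to the class supports divided by the total count. This is the primary
#' performance metric for the imbalanced two-class problem.
#'
#' @param cc a `confusion_counts` matrix (rows = truth, cols = predicted).
#' @return Weighted F1 in \[0, 1\].
#' @export
weighted_f1 <- function(cc) {
  cc <- check_cc(cc)
  support <- rowSums(cc)
  f1 <- numeric(2)
  for (k in 1:2) {
    tp <- cc[k, k]
    prec_den <- sum(cc[, k]); rec_den <- support[k]
    p <- if (prec_den > 0) tp / prec_den else 0
    r <- if (rec_den > 0) tp / rec_den else 0
    f1[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  sum(f1 * support) / sum(support)
}

#' Classification accuracy
#' @param cc a `confusion_counts` matrix.
#' @return Proportion of correctly classified patients.
#' @export
accuracy <- function(cc) {
  cc <- check_cc(cc)
  sum(diag(cc)) / sum(cc)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen community ambulator receives a
#' higher community-probability score than a randomly chosen household
#' ambulator, with ties counted one half. Computed from rank sums.
#'
#' @param scores community-class probability (or any monotone score).
#' @param labels true class labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as_class_factor(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  n_pos <- sum(labels == "community"); n_neg <- sum(labels == "household")
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "community"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-subject-out predictions
#'
#' For each patient, trains a balanced random forest on all other patients
#' and predicts the held-out one. Deterministic given `seed` (the same forest
#' seed is used in every fold).
#'
#' @param table feature table (data frame; row names are patient ids).
#' @param labels true discharge class labels.
#' @param hp a [hyperparameters()].
#' @param seed forest seed.
#' @return Data frame with `patient`, `truth`, `pred`, `prob_community`.
#' @export
loso_predict <- function(table, labels, hp = hyperparameters(), seed = 0) {
  X <- as.data.frame(table)
  y <- as_class_factor(labels)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 patients for leave-one-subject-out")
  ids <- rownames(X) %||% as.character(seq_len(n))
  pred <- character(n); prob <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      stop("training fold excluding patient ", ids[i], " has a single class")
    }
    m <- train_balanced_forest(X[-i, , drop = FALSE], ytr, hp, seed = seed)
    p <- predict(m, X[i, , drop = FALSE])
    pred[i] <- as.character(p$labels)
    prob[i] <- p$prob_community
  }
  data.frame(patient = ids, truth = as.character(y), pred = pred,
             prob_community = prob, stringsAsFactors = FALSE)
}

# weighted F1 straight from label vectors (used by internal CV scoring)
weighted_f1_labels <- function(truth, pred) weighted_f1(confusion_counts(truth, pred))

#' Seed-averaged leave-one-subject-out evaluation
#'
#' Runs [loso_predict()] for seeds `seed_offset + 0 .. n_seeds - 1`
#' (incremented seeds), averages weighted F1, accuracy and AUROC across
#' seeds with their SDs, reports the modal confusion matrix, and flags
#' whether any patient's predicted label fluctuated across seeds.
#'
#' @param table feature table.
#' @param labels true discharge labels.
#' @param hp a [hyperparameters()].
#' @param n_seeds number of seeds (>= 1).
#' @param seed_offset first seed (default 0).
#' @return An object of class `evaluation_report`: `metrics` (mean/sd per
#'   metric), `confusion` (modal), `per_seed` (per-seed metrics and
#'   confusion matrices), `predictions` (per patient, per seed labels),
#'   `fluctuated` (logical).
#' @export
seed_averaged_evaluation <- function(table, labels, hp = hyperparameters(),
                                     n_seeds = 100, seed_offset = 0) {
  stopifnot(n_seeds >= 1)
  wf1 <- acc <- auc <- numeric(n_seeds)
  mats <- vector("list", n_seeds)
  pred_mat <- NULL
  for (s in seq_len(n_seeds)) {
    res <- loso_predict(table, labels, hp, seed = seed_offset + s - 1)
    cc <- confusion_counts(res$truth, res$pred)
    wf1[s] <- weighted_f1(cc); acc[s] <- accuracy(cc)
    auc[s] <- auroc(res$prob_community, res$truth)
    mats[[s]] <- cc
    if (is.null(pred_mat)) {
      pred_mat <- matrix(NA_character_, nrow(res), n_seeds,
                         dimnames = list(res$patient, NULL))
    }
    pred_mat[, s] <- res$pred
  }
  keys <- vapply(mats, function(m) paste(m, collapse = ","), character(1))
  modal <- mats[[match(names(which.max(table(keys))), keys)]]
  fluctuated <- any(apply(pred_mat, 1, function(z) length(unique(z)) > 1))
  metrics <- data.frame(
    metric = c("weighted_f1", "accuracy", "auroc"),
    mean = c(mean(wf1), mean(acc), mean(auc)),
    sd = c(sd(wf1), sd(acc), sd(auc)))
  metrics$sd[is.na(metrics$sd)] <- 0   # single seed
  structure(list(metrics = metrics, confusion = modal,
                 per_seed = data.frame(seed = seed_offset + seq_len(n_seeds) - 1,
                                       weighted_f1 = wf1, accuracy = acc,
                                       auroc = auc),
                 per_seed_confusion = mats,
                 predictions = pred_mat, fluctuated = fluctuated),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$metrics, row.names = FALSE)
  cat(if (x$fluctuated) "patient classifications fluctuated across seeds\n"
      else "patient classifications stable across seeds\n")
  invisible(x)
}

#' Admission-to-discharge transition-group analysis
#'
#' Partitions patients by their admission and discharge ambulation classes
#' (household-to-household, community-to-community, household-to-community,
#' community-to-household) and reports the fraction of correct discharge
#' predictions in each non-empty group. The household-to-community group —
#' patients who improve past the threshold during rehabilitation — is the
#' discriminating test between models.
#'
#' @param adm_labels,dis_labels admission and discharge classes.
#' @param predictions predicted discharge classes.
#' @return Data frame with `group`, `n`, `n_correct`, `pct_correct`.
#' @export
transition_analysis <- function(adm_labels, dis_labels, predictions) {
  adm <- as_class_factor(adm_labels); dis <- as_class_factor(dis_labels)
  pred <- as_class_factor(predictions)
  if (length(adm) != length(dis) || length(dis) != length(pred)) {
    stop("label vectors must have equal length")
  }
  short <- c(community = "C", household = "H")
  grp <- paste0(short[as.character(adm)], "->", short[as.character(dis)])
  out <- do.call(rbind, lapply(c("H->H", "C->C", "H->C", "C->H"), function(g) {
    idx <- grp == g
    if (!any(idx)) return(NULL)
    data.frame(group = g, n = sum(idx),
               n_correct = sum(pred[idx] == dis[idx]),
               stringsAsFactors = FALSE)
  }))
  out$pct_correct <- 100 * out$n_correct / out$n
  out
}
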