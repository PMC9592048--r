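# Independent oracles used to cross-check the package's implementations.

# Sample entropy by naive exhaustive template counting (same convention:
# templates i = 1..n-m for both the m- and (m+1)-length counts).
sampen_brute <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(0)
  tol <- r * s
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

# Weighted F1 and accuracy recomputed by expanding the confusion matrix into
# label vectors and scoring per class one-vs-rest from scratch.
f1_oracle <- function(cc) {
  classes <- rownames(cc)
  truth <- rep(rep(classes, each = 2), times = as.vector(t(cc)))
  pred <- rep(rep(classes, times = 2), times = as.vector(t(cc)))
  total <- length(truth)
  wsum <- 0
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    wsum <- wsum + f1 * sum(truth == cl)
  }
  list(weighted_f1 = wsum / total, accuracy = mean(truth == pred))
}

# AUROC by exhaustive concordant-pair counting.
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == "community"]
  neg <- scores[labels == "household"]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Shared default synthetic cohort (33 patients), built once per test run.
.cohort_cache <- new.env(parent = emptyenv())
default_test_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    .cohort_cache$co <- simulate_cohort(cohort_config(seed = 7))
  }
  .cohort_cache$co
}

default_test_features <- function() {
  if (is.null(.cohort_cache$ft)) {
    .cohort_cache$ft <- extract_feature_table(default_test_cohort(),
                                              bout_spec("fixed_distance"))
  }
  .cohort_cache$ft
}
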