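#' Experiment configuration
#'
#' Bundles every knob of the end-to-end experiment. Stage seeds are derived
#' from the master seed by fixed offsets (cohort +1, RFECV +1000, selection
#' curve +2000, tuning +3000, evaluation +4000, each scaled by 10000) so
#' stages can be rerun independently yet reproducibly.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read one).
#' @param cohort a [cohort_config()] (synthetic mode); its own seed is
#'   overridden by the derived stage seed unless `keep_cohort_seed = TRUE`.
#' @param input_dir cohort directory (files mode).
#' @param paradigm `"fixed_distance"` or `"fixed_duration"`.
#' @param duration_s fixed-duration bout length (seconds).
#' @param durations duration sweep candidates.
#' @param variants model variants to run.
#' @param include_pi_only add the PI-only variant (reference model; usually
#'   near chance since patient information is class-independent).
#' @param catalog feature catalog.
#' @param correlation_threshold multicollinearity filter threshold.
#' @param rfecv_iter,curve_seeds,tune_iter,tune_draws,eval_seeds,folds
#'   repetition counts for the optimization and evaluation stages.
#' @param hp default [hyperparameters()] used before tuning.
#' @param space randomized-search space; `NULL` disables tuning.
#' @param seed master seed.
#' @param keep_cohort_seed use `cohort$seed` as-is instead of the derived one.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("synthetic", "files"),
                              cohort = cohort_config(),
                              input_dir = NULL,
                              paradigm = c("fixed_distance", "fixed_duration"),
                              duration_s = 60,
                              durations = c(10, 20, 30, 60, 90, 120, 180, 240, 300, 360),
                              variants = c("PI+FA", "PI+IMU", "PI+FA+IMU"),
                              include_pi_only = FALSE,
                              catalog = feature_catalog(),
                              correlation_threshold = 0.9,
                              rfecv_iter = 100, curve_seeds = 100,
                              tune_iter = 100, tune_draws = 50,
                              eval_seeds = 100, folds = 5,
                              hp = hyperparameters(),
                              space = default_search_space(),
                              seed = 1,
                              keep_cohort_seed = FALSE) {
  mode <- match.arg(mode)
  paradigm <- match.arg(paradigm)
  if (include_pi_only) variants <- union("PI", variants)
  stopifnot(length(variants) >= 1)
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 paradigm = paradigm, duration_s = duration_s,
                 durations = durations, variants = variants,
                 catalog = catalog,
                 correlation_threshold = correlation_threshold,
                 rfecv_iter = rfecv_iter, curve_seeds = curve_seeds,
                 tune_iter = tune_iter, tune_draws = tune_draws,
                 eval_seeds = eval_seeds, folds = folds,
                 hp = hp, space = space, seed = as.integer(seed),
                 keep_cohort_seed = keep_cohort_seed),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Scalar fields map directly onto [experiment_config()] arguments; the
#' `cohort` block maps onto [cohort_config()] counts/threshold/seed, and the
#' `hp` block onto [hyperparameters()]. Unknown fields are rejected.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohort_config, raw$cohort)
  if (!is.null(raw$hp)) args$hp <- do.call(hyperparameters, raw$hp)
  if (!is.null(raw$space)) args$space <- do.call(default_search_space, raw$space)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  do.call(experiment_config, args)
}

stage_seed <- function(master, stage) {
  offsets <- c(cohort = 1, rfecv = 1000, curve = 2000, tune = 3000, eval = 4000)
  (abs(master) %% 100000L) * 10000L + offsets[[stage]]
}

load_experiment_cohort <- function(config) {
  if (config$mode == "synthetic") {
    cc <- config$cohort
    if (!config$keep_cohort_seed) cc$seed <- stage_seed(config$seed, "cohort")
    simulate_cohort(cc)
  } else {
    read_cohort_csv(config$input_dir)
  }
}

modal_labels <- function(pred_mat) {
  apply(pred_mat, 1, function(z) names(which.max(table(z))))
}

#' Run the full experiment for every model variant
#'
#' Executes, per variant: feature extraction under the configured paradigm,
#' the correlation filter, seed-averaged RFECV importance aggregation,
#' backward elimination to the F1-maximizing subset, majority-vote
#' randomized hyperparameter tuning on the selected features, and
#' seed-averaged leave-one-subject-out evaluation with transition-group
#' analysis of the modal predictions. Deterministic given the config.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return A bundle: `cohort`, per-variant results (`filtered`, `ranking`,
#'   `selection`, `hp`, `report`, `transition`), and a `summary` data frame.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- load_experiment_cohort(config)
  patients <- cohort$patients
  dis <- ambulation_factor(patients$class_dis)
  adm <- ambulation_factor(patients$class_adm)
  spec <- if (config$paradigm == "fixed_distance") {
    bout_spec("fixed_distance", distance_m = 10)
  } else {
    bout_spec("fixed_duration", duration_s = config$duration_s)
  }
  full <- extract_feature_table(cohort, spec, config$catalog)
  keep <- match(rownames(full), patients$patient_id)
  dis <- dis[keep]; adm <- adm[keep]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    suffix <- if (config$paradigm == "fixed_duration") {
      paste0("_", config$duration_s)
    } else ""
    write_feature_csv(full, file.path(out_dir, paste0(
      "features_", config$paradigm, suffix, ".csv")))
  }

  results <- list()
  for (v in config$variants) {
    tab <- full[, variant_features(config$catalog, v), drop = FALSE]
    filt <- drop_correlated(tab, config$correlation_threshold)
    rank <- aggregate_importance(filt, dis, config$hp,
                                 n_iter = config$rfecv_iter,
                                 folds = config$folds,
                                 seed_offset = stage_seed(config$seed, "rfecv"))
    sel <- backward_elimination(filt, dis, rank, config$hp,
                                n_seeds = config$curve_seeds,
                                seed_offset = stage_seed(config$seed, "curve"))
    Xsel <- filt[, sel$features, drop = FALSE]
    hp_final <- if (!is.null(config$space) && config$tune_iter > 0) {
      tune_hyperparameters(Xsel, dis, config$space,
                           n_iter = config$tune_iter,
                           n_draws = config$tune_draws,
                           folds = config$folds,
                           seed_offset = stage_seed(config$seed, "tune"))
    } else config$hp
    rep <- seed_averaged_evaluation(Xsel, dis, hp_final,
                                    n_seeds = config$eval_seeds,
                                    seed_offset = stage_seed(config$seed, "eval"))
    trans <- transition_analysis(adm, dis, modal_labels(rep$predictions))
    results[[v]] <- list(filtered = filt, ranking = rank, selection = sel,
                         hp = hp_final, report = rep, transition = trans)
    if (!is.null(out_dir)) write_variant_artifacts(results[[v]], v, out_dir)
  }

  summary <- do.call(rbind, lapply(config$variants, function(v) {
    m <- results[[v]]$report$metrics
    data.frame(variant = v, k = results[[v]]$selection$k,
               features = paste(results[[v]]$selection$features, collapse = ";"),
               weighted_f1 = m$mean[m$metric == "weighted_f1"],
               weighted_f1_sd = m$sd[m$metric == "weighted_f1"],
               accuracy = m$mean[m$metric == "accuracy"],
               auroc = m$mean[m$metric == "auroc"],
               stringsAsFactors = FALSE)
  }))
  bundle <- list(cohort = cohort, results = results, summary = summary,
                 config = config)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = config$seed, paradigm = config$paradigm,
           variants = config$variants, summary = summary),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  bundle
}

write_variant_artifacts <- function(res, variant, out_dir) {
  tag <- gsub("\\+", "_", variant)
  write.csv(res$ranking, file.path(out_dir, paste0("importance_", tag, ".csv")),
            row.names = FALSE)
  write.csv(res$selection$curve,
            file.path(out_dir, paste0("selection_curve_", tag, ".csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(n_estimators = res$hp$n_estimators,
         max_depth = res$hp$max_depth %||% "unlimited",
         min_samples_split = res$hp$min_samples_split,
         min_samples_leaf = res$hp$min_samples_leaf,
         max_features_mode = res$hp$max_features_mode,
         votes = as.list(attr(res$hp, "votes"))),
    file.path(out_dir, paste0("hyperparameters_", tag, ".json")),
    auto_unbox = TRUE)
  write.csv(as.data.frame(res$report$confusion),
            file.path(out_dir, paste0("confusion_", tag, ".csv")))
  jsonlite::write_json(
    list(metrics = res$report$metrics, fluctuated = res$report$fluctuated,
         transition = res$transition),
    file.path(out_dir, paste0("report_", tag, ".json")),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Pre-optimization duration sweep
#'
#' Evaluates each candidate fixed duration with default hyperparameters and
#' no feature selection or tuning, by seed-averaged leave-one-subject-out
#' weighted F1, and selects the best-performing duration (ties to the
#' shorter). Durations longer than the available recordings are skipped
#' with a warning.
#'
#' @param cohort a `gait_cohort` with 6-minute-walk recordings.
#' @param durations candidate durations in seconds.
#' @param variant model variant evaluated during the sweep.
#' @param catalog feature catalog.
#' @param hp default [hyperparameters()].
#' @param n_seeds seeds per duration.
#' @param seed_offset first seed.
#' @return A list: `table` (duration, mean_f1, sd_f1, selected) and
#'   `duration` (the selected one).
#' @export
run_duration_sweep <- function(cohort,
                               durations = c(10, 20, 30, 60, 90, 120, 180, 240, 300, 360),
                               variant = "PI+IMU", catalog = feature_catalog(),
                               hp = hyperparameters(), n_seeds = 10,
                               seed_offset = 0) {
  dis <- ambulation_factor(cohort$patients$class_dis)
  min_len <- min(vapply(cohort$recordings, function(r) {
    min(vapply(r[["6mwt"]], function(x) x$n_samples / x$fs_hz, numeric(1)))
  }, numeric(1)))
  rows <- list()
  for (d in sort(durations)) {
    if (d > min_len) {
      warning("duration ", d, " s exceeds the shortest recording (",
              round(min_len, 1), " s); skipped")
      next
    }
    tab <- extract_feature_table(cohort, bout_spec("fixed_duration", duration_s = d),
                                 catalog)
    tab <- tab[, variant_features(catalog, variant), drop = FALSE]
    f1 <- vapply(seq_len(n_seeds) - 1, function(s) {
      res <- loso_predict(tab, dis[match(rownames(tab), cohort$patients$patient_id)],
                          hp, seed = seed_offset + s)
      weighted_f1_labels(res$truth, res$pred)
    }, numeric(1))
    rows[[as.character(d)]] <- data.frame(duration = d, mean_f1 = mean(f1),
                                          sd_f1 = if (n_seeds > 1) sd(f1) else 0)
  }
  if (!length(rows)) stop("no duration could be evaluated")
  out <- do.call(rbind, rows)
  best <- out$duration[which.max(out$mean_f1)]  # ties -> shorter (sorted)
  out$selected <- out$duration == best
  list(table = out, duration = best)
}

#' Recompute the published worked-example metrics
#'
#' Rebuilds each reported confusion matrix from its per-class correct counts
#' (fixed-distance cohort: 27 community / 6 household at discharge) and the
#' admission-to-discharge transition groups (8 household-stable, 21
#' community-stable, 4 household-to-community), recomputes weighted F1,
#' accuracy, community recall and transition-group recall with the package's
#' own metric functions, and compares them with the published values at
#' 3-decimal tolerance.
#'
#' @param tolerance absolute tolerance on proportions (default 5e-4, i.e.
#'   agreement with 3-decimal rounding).
#' @return Data frame with `model`, `metric`, `expected`, `computed`, `pass`.
#' @export
verify_worked_examples <- function(tolerance = 5e-4) {
  # per-model community/household correct counts as published
  counts <- list(
    "PI+FA" = c(23, 27, 6, 6),
    "PI+IMU" = c(25, 27, 6, 6),
    "PI+FA+IMU" = c(24, 27, 6, 6))
  expected <- list(
    "PI+FA" = c(weighted_f1 = 0.889, accuracy = 0.879, recall_community_pct = 85),
    "PI+IMU" = c(weighted_f1 = 0.943, accuracy = 0.939, recall_community_pct = 93),
    "PI+FA+IMU" = c(weighted_f1 = 0.916, accuracy = 0.909, recall_community_pct = 89))
  hc_correct <- c("PI+FA" = 0, "PI+IMU" = 2, "PI+FA+IMU" = 1)
  hc_expected_pct <- c("PI+FA" = 0, "PI+IMU" = 50, "PI+FA+IMU" = 25)

  rows <- list()
  for (m in names(counts)) {
    cc <- do.call(confusion_from_recall, as.list(counts[[m]]))
    comp <- c(weighted_f1 = weighted_f1(cc), accuracy = accuracy(cc),
              recall_community_pct = 100 * counts[[m]][1] / counts[[m]][2])
    for (metric in names(comp)) {
      exp_v <- expected[[m]][[metric]]
      pass <- if (metric == "recall_community_pct") {
        round(comp[[metric]]) == exp_v
      } else {
        abs(comp[[metric]] - exp_v) < tolerance
      }
      rows[[paste(m, metric)]] <- data.frame(
        model = m, metric = metric, expected = exp_v,
        computed = unname(comp[[metric]]), pass = pass,
        stringsAsFactors = FALSE)
    }
    # transition groups: 8 H->H, 21 C->C, 4 H->C; stable groups all correct
    adm <- rep(c("household", "community", "household"), c(8, 21, 4))
    dis_l <- rep(c("household", "community", "community"), c(8, 21, 4))
    k <- hc_correct[[m]]
    pred <- c(rep("household", 8), rep("community", 21),
              rep(c("community", "household"), c(k, 4 - k)))
    tr <- transition_analysis(adm, dis_l, pred)
    comp_hc <- tr$pct_correct[tr$group == "H->C"]
    rows[[paste(m, "transition")]] <- data.frame(
      model = m, metric = "transition_HtoC_pct",
      expected = hc_expected_pct[[m]], computed = comp_hc,
      pass = abs(comp_hc - hc_expected_pct[[m]]) < 1e-9 &&
        all(tr$pct_correct[tr$group %in% c("H->H", "C->C")] == 100),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
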