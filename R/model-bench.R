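#' Chronological train/validation versus test split
#'
#' Splits by the chronological index with no shuffling: the first `n_train`
#' cases form the training/validation set, the remainder the independent
#' test set.
#'
#' @param labels tibble with `case_id`, `chrono_index`, `mvi_label`.
#' @param n_train number of training/validation cases (default 88).
#' @return list with tibbles `train` and `test`.
#' @export
chronological_split <- function(labels, n_train = 88) {
  abort_if(!all(c("case_id", "chrono_index", "mvi_label") %in% names(labels)),
           "`labels` must have case_id, chrono_index and mvi_label columns")
  abort_if(n_train >= nrow(labels),
           "`n_train` must be smaller than the cohort size")
  abort_if(n_train < 1, "`n_train` must be positive")
  ordered <- dplyr::arrange(labels, .data$chrono_index)
  list(train = ordered[seq_len(n_train), ],
       test = ordered[-seq_len(n_train), ])
}

# stratified fold assignment: within each class, cases are shuffled once
# (seeded) and dealt round-robin across folds
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Ten-fold cross-validation of one selector/classifier model
#'
#' Stratified k-fold CV with feature selection refit inside every fold
#' (selection sees only that fold's training portion, so no information
#' leaks from the validation fold). Folds whose training portion contains a
#' single class, or whose validation portion cannot support the metrics,
#' are marked degenerate and excluded with a warning.
#'
#' @param data wide feature tibble from [feature_matrix()] (needs
#'   `mvi_label` plus feature columns; `case_id`/`chrono_index` ignored).
#' @param selector selector id, see [selector_registry()].
#' @param classifier classifier id, see [classifier_registry()].
#' @param k_features number of features selected per fold (default 10).
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and stochastic fits.
#' @return object of class `cv_result`: per-fold metrics and selected
#'   features, mean metrics, and the configuration. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
tenfold_cv <- function(data, selector = "t_score", classifier = "lda",
                       k_features = 10, n_folds = 10, seed = 1L) {
  feat_cols <- setdiff(names(data), c("case_id", "chrono_index", "mvi_label"))
  x <- as.matrix(data[, feat_cols])
  y <- data$mvi_label
  abort_if(length(unique(y)) < 2, "both classes must be present")
  k_features <- min(k_features, ncol(x))
  folds <- stratified_folds(y, n_folds, derive_seed(seed, "folds"))
  rows <- purrr::map(seq_len(n_folds), function(f) {
    tr <- folds != f; va <- folds == f
    if (!any(va)) return(NULL)
    if (length(unique(y[tr])) < 2) {
      rlang::warn(sprintf("fold %d degenerate (single-class training portion); excluded", f))
      return(NULL)
    }
    sel <- select_features(x[tr, , drop = FALSE], y[tr], selector, k_features)
    model <- fit_classifier(x[tr, sel, drop = FALSE], y[tr], classifier,
                            seed = derive_seed(seed, "fit", f))
    prob <- predict_prob(model, x[va, sel, drop = FALSE])
    m <- if (length(unique(y[va])) < 2) {
      pred <- as.integer(prob >= 0.5)
      c(auc = NA_real_, acc = mean(pred == y[va]), sen = NA_real_, spe = NA_real_)
    } else {
      mm <- classification_metrics(prob, y[va])
      c(auc = mm$auc, acc = mm$acc, sen = mm$sen, spe = mm$spe)
    }
    tibble::tibble(fold = f, n_valid = sum(va), auc = m["auc"], acc = m["acc"],
                   sen = m["sen"], spe = m["spe"], selected = list(sel))
  })
  folds_tbl <- dplyr::bind_rows(rows)
  abort_if(nrow(folds_tbl) == 0, "all folds degenerate")
  means <- folds_tbl |>
    dplyr::summarise(dplyr::across(c("auc", "acc", "sen", "spe"),
                                   ~ mean(.x, na.rm = TRUE)))
  structure(
    list(folds = folds_tbl, mean_auc = means$auc, mean_acc = means$acc,
         mean_sen = means$sen, mean_spe = means$spe,
         selector = selector, classifier = classifier,
         k_features = k_features, n_folds = n_folds, seed = seed),
    class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s + %s: AUC %.3f, ACC %.3f (%d folds)\n",
              x$classifier, x$selector, x$mean_auc, x$mean_acc,
              nrow(x$folds)))
  invisible(x)
}

#' Enumerate the full benchmarking grid
#'
#' Crosses selectors, classifiers, phase combinations and region options into
#' the full configuration grid: with the defaults
#' `15 x 10 x 15 x 15 = 33,750` configurations.
#'
#' @param selectors selector ids (default all 15).
#' @param classifiers classifier ids (default all 10).
#' @param combos phase-combination labels (default all 15, see
#'   [phase_combos()]).
#' @param regions region ids (default all 15, see [region_options()]).
#' @return tibble with `config_id`, `selector`, `classifier`, `phase_combo`,
#'   `region`, in stable order.
#' @export
enumerate_configs <- function(selectors = selector_registry(),
                              classifiers = classifier_registry(),
                              combos = phase_combos()$combo,
                              regions = region_options()) {
  grid <- tidyr::expand_grid(phase_combo = combos, region = regions,
                             selector = selectors, classifier = classifiers)
  dplyr::mutate(grid,
                config_id = sprintf("%s|%s|%s|%s", .data$phase_combo,
                                    .data$region, .data$selector,
                                    .data$classifier),
                .before = 1)
}

#' Run the benchmark over a configuration grid
#'
#' Cross-validates every configuration on the training/validation set. Each
#' configuration draws a deterministic seed from the master seed, so the
#' full benchmark is reproducible bit-for-bit.
#'
#' @param store long feature store from [extract_cohort()].
#' @param labels label tibble for the training/validation cases only.
#' @param configs configuration tibble from [enumerate_configs()].
#' @param k_features features selected per fold.
#' @param n_folds CV folds.
#' @param seed master seed.
#' @return tibble: one row per configuration with mean CV metrics and a
#'   `cv` list column holding each [tenfold_cv()] result.
#' @export
run_benchmark <- function(store, labels, configs, k_features = 10,
                          n_folds = 10, seed = 1L) {
  combos <- phase_combos()
  purrr::map_dfr(seq_len(nrow(configs)), function(i) {
    cfg <- configs[i, ]
    phases <- combos$phases[[match(cfg$phase_combo, combos$combo)]]
    abort_if(is.null(phases), sprintf("unknown phase combo `%s`", cfg$phase_combo))
    mat <- feature_matrix(store, labels, phases, cfg$region)
    cv <- tenfold_cv(mat, cfg$selector, cfg$classifier, k_features, n_folds,
                     seed = derive_seed(seed, "config", i))
    tibble::tibble(cfg, mean_auc = cv$mean_auc, mean_acc = cv$mean_acc,
                   mean_sen = cv$mean_sen, mean_spe = cv$mean_spe,
                   cv = list(cv))
  })
}

#' Rank benchmarked models
#'
#' Descending mean validation AUC with a deterministic tie-break: higher
#' mean accuracy first, then lexicographic configuration id.
#'
#' @param results tibble from [run_benchmark()].
#' @return the same tibble, ranked, with a `rank` column.
#' @export
rank_models <- function(results) {
  results |>
    dplyr::arrange(dplyr::desc(.data$mean_auc), dplyr::desc(.data$mean_acc),
                   .data$config_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Top-k benchmarked models
#' @param results tibble from [run_benchmark()].
#' @param k number of models (default 3).
#' @return the `k` top-ranked rows.
#' @export
top_k_models <- function(results, k = 3) {
  abort_if(nrow(results) < k, sprintf("need at least %d results", k))
  head(rank_models(results), k)
}

#' Aggregate benchmark results by phase combination and region class
#'
#' Averages the mean CV AUC uniformly over all configurations (all models,
#' all peritumoral distances) within each phase combination and region class
#' (`V_tc`, `V_pt`, `V_tc+V_pt`), and computes the distance trend: mean AUC
#' per peritumoral distance within each region class.
#'
#' @param results tibble from [run_benchmark()].
#' @return object of class `benchmark_summary`: list with tibbles
#'   `phase_region` (phase_combo x region_class means), `distance_trend`
#'   (region_class x distance means), and `best` (argmax row of
#'   `phase_region`).
#' @export
aggregate_phase_region <- function(results) {
  res <- results |>
    dplyr::mutate(region_class = region_class(.data$region),
                  distance = region_distance(.data$region))
  phase_region <- res |>
    dplyr::group_by(.data$phase_combo, .data$region_class) |>
    dplyr::summarise(mean_auc = mean(.data$mean_auc),
                     n_configs = dplyr::n(), .groups = "drop")
  distance_trend <- res |>
    dplyr::filter(!is.na(.data$distance)) |>
    dplyr::group_by(.data$region_class, .data$distance) |>
    dplyr::summarise(mean_auc = mean(.data$mean_auc),
                     n_configs = dplyr::n(), .groups = "drop")
  best <- phase_region |>
    dplyr::arrange(dplyr::desc(.data$mean_auc), .data$phase_combo,
                   .data$region_class) |>
    dplyr::slice(1)
  structure(list(phase_region = phase_region,
                 distance_trend = distance_trend, best = best),
            class = "benchmark_summary")
}

#' @exportS3Method base::print
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark_summary> best setting: %s / %s (mean AUC %.3f)\n",
              x$best$phase_combo, x$best$region_class, x$best$mean_auc))
  invisible(x)
}

#' Census of top-selected features
#'
#' Over every configuration whose mean CV AUC exceeds `auc_min`, counts how
#' often each feature appears among the first `top_n` features selected in a
#' CV fold, as a percentage of all qualifying fold-selections (so the
#' percentages over all features sum to 100).
#'
#' @param results tibble from [run_benchmark()].
#' @param auc_min qualification threshold on the mean CV AUC (default 0.7).
#' @param top_n number of top-ranked per-fold features counted (default 10).
#' @return tibble `feature`, `count`, `percentage`, sorted descending; empty
#'   (with a warning) when no configuration qualifies.
#' @export
top_feature_census <- function(results, auc_min = 0.7, top_n = 10) {
  qual <- dplyr::filter(results, .data$mean_auc > auc_min)
  if (nrow(qual) == 0) {
    rlang::warn("no configuration qualifies for the feature census")
    return(tibble::tibble(feature = character(), count = integer(),
                          percentage = numeric()))
  }
  picks <- unlist(purrr::map(qual$cv, function(cv) {
    purrr::map(cv$folds$selected, ~ head(.x, top_n))
  }))
  tab <- sort(table(picks), decreasing = TRUE)
  tibble::tibble(feature = names(tab), count = as.integer(tab),
                 percentage = 100 * as.integer(tab) / length(picks))
}
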