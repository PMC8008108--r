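#' Plurality vote over member predictions
#'
#' Assigns the class with the most votes. With an even number of members a
#' tied vote is broken deterministically to the positive class (logged via a
#' message), since a consensus rule must return a decision.
#'
#' @param votes vector of binary member votes (0/1), length >= 2.
#' @return the winning label (0 or 1).
#' @export
plurality_vote <- function(votes) {
  abort_if(length(votes) < 2, "plurality voting needs at least 2 members")
  abort_if(!all(votes %in% c(0, 1)), "votes must be binary")
  n1 <- sum(votes == 1)
  n0 <- sum(votes == 0)
  if (n1 == n0) {
    rlang::inform("tied vote broken to the positive class")
    return(1L)
  }
  as.integer(n1 > n0)
}

#' Accuracy-proportional fusion weights
#'
#' `w_i = acc_i / sum(acc)`: each member of the ensemble is weighted by its
#' validation accuracy, normalized to sum to one.
#'
#' @param accs vector of member validation accuracies, all > 0.
#' @return numeric weights summing to 1.
#' @export
compute_weights <- function(accs) {
  abort_if(length(accs) < 2, "need at least 2 member accuracies")
  abort_if(any(!is.finite(accs)) || any(accs <= 0),
           "all accuracies must be positive")
  accs / sum(accs)
}

#' Weighted fusion of member probabilities
#'
#' The fused score is the weighted linear combination
#' `H(x) = sum_i w_i c_i(x)` of the member probabilities; the fused label
#' thresholds `H` at `threshold`.
#'
#' @param member_probs numeric matrix (cases x members) or vector (one case)
#'   of member probabilities in `[0, 1]`.
#' @param weights member weights from [compute_weights()].
#' @param threshold decision threshold on the fused score (default 0.5).
#' @return tibble with `score` and `label` per case.
#' @export
weighted_fusion <- function(member_probs, weights, threshold = 0.5) {
  if (is.null(dim(member_probs)))
    member_probs <- matrix(member_probs, nrow = 1)
  abort_if(ncol(member_probs) != length(weights),
           "number of members and weights differ")
  abort_if(any(member_probs < 0 | member_probs > 1),
           "member probabilities must lie in [0, 1]")
  h <- as.numeric(member_probs %*% weights)
  tibble::tibble(score = h, label = as.integer(h >= threshold))
}

#' Classification metrics: AUC, accuracy, sensitivity, specificity
#'
#' AUC uses the rank (Mann-Whitney) formulation with midrank tie
#' correction; accuracy, sensitivity (`TP/(TP+FN)`) and specificity
#' (`TN/(TN+FP)`) come from thresholding the scores.
#'
#' @param scores numeric prediction scores or probabilities.
#' @param labels binary truth (0/1), both classes present.
#' @param threshold decision threshold (default 0.5).
#' @return list with `auc`, `acc`, `sen`, `spe`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  abort_if(length(scores) != length(labels), "scores and labels differ in length")
  labels <- as.integer(labels)
  abort_if(length(unique(labels)) < 2, "both classes must be present")
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  list(auc = auc, acc = (tp + tn) / length(labels),
       sen = tp / (tp + fn), spe = tn / (tn + fp))
}

#' Net reclassification improvement between two models
#'
#' Categorical two-class NRI on predicted labels:
#' `NRI = [P(up|event) - P(down|event)] - [P(up|nonevent) - P(down|nonevent)]`
#' where "up" means the new model reclassifies a case into the higher risk
#' category (predicted positive) relative to the baseline. Positive values
#' favour the new model; the range is `[-2, 2]`.
#'
#' @param baseline_pred,new_pred binary predicted labels of the baseline and
#'   the new model, aligned case-by-case.
#' @param truth binary event status (1 = event), both levels present.
#' @return object of class `nri_result`: list with `nri` and the four
#'   reclassification fractions.
#' @export
nri <- function(baseline_pred, new_pred, truth) {
  abort_if(length(baseline_pred) != length(truth) ||
             length(new_pred) != length(truth),
           "prediction and truth lengths differ")
  truth <- as.integer(truth)
  abort_if(sum(truth == 1) == 0 || sum(truth == 0) == 0,
           "NRI needs both events and non-events")
  up <- new_pred > baseline_pred
  down <- new_pred < baseline_pred
  ev <- truth == 1
  p_up_ev <- mean(up[ev]); p_down_ev <- mean(down[ev])
  p_up_ne <- mean(up[!ev]); p_down_ne <- mean(down[!ev])
  structure(
    list(nri = (p_up_ev - p_down_ev) - (p_up_ne - p_down_ne),
         event_up = p_up_ev, event_down = p_down_ev,
         nonevent_up = p_up_ne, nonevent_down = p_down_ne),
    class = "nri_result")
}

#' @exportS3Method base::print
print.nri_result <- function(x, ...) {
  cat(sprintf("<nri_result> NRI %.3f (events: %.2f up / %.2f down; non-events: %.2f up / %.2f down)\n",
              x$nri, x$event_up, x$event_down, x$nonevent_up, x$nonevent_down))
  invisible(x)
}

#' Pairwise NRI matrix across models
#'
#' Computes the NRI of every model (rows) against every other model
#' (columns); the matrix is antisymmetric by construction.
#'
#' @param pred_labels matrix or data frame of binary predicted labels, one
#'   column per model (named), aligned rows.
#' @param truth binary event status.
#' @return tibble `model_y`, `model_x`, `nri` (long form); the wide matrix is
#'   attached as attribute `"matrix"`.
#' @export
nri_matrix <- function(pred_labels, truth) {
  pred_labels <- as.matrix(pred_labels)
  abort_if(is.null(colnames(pred_labels)), "model columns must be named")
  models <- colnames(pred_labels)
  long <- purrr::map_dfr(models, function(a) {
    purrr::map_dfr(models, function(b) {
      tibble::tibble(model_y = a, model_x = b,
                     nri = if (a == b) 0 else
                       nri(pred_labels[, b], pred_labels[, a], truth)$nri)
    })
  })
  m <- matrix(long$nri, length(models), length(models), byrow = TRUE,
              dimnames = list(models, models))
  attr(long, "matrix") <- m
  long
}

#' Rank-based comparison of metric samples across feature-type groups
#'
#' Omnibus Kruskal-Wallis test across the groups followed by pairwise
#' two-sided rank-sum comparisons with Bonferroni adjustment (raw p times
#' the number of pairs, capped at 1), significance at 0.05.
#'
#' @param data data frame with the metric and grouping columns.
#' @param value name of the metric column.
#' @param group name of the grouping column.
#' @return list with `omnibus_p`, `pairwise` (tibble `group_a`, `group_b`,
#'   `p_raw`, `p_adjusted`, `significant`).
#' @export
feature_group_test <- function(data, value = "mean_auc", group = "phase_combo") {
  v <- data[[value]]; g <- factor(data[[group]])
  abort_if(nlevels(g) < 2, "need at least 2 groups")
  abort_if(any(table(g) < 2), "every group needs at least 2 samples")
  omnibus <- kruskal.test(v, g)$p.value
  pairs <- combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- suppressWarnings(wilcox.test(v[g == a], v[g == b],
                                      exact = FALSE)$p.value)
    tibble::tibble(group_a = a, group_b = b, p_raw = p,
                   p_adjusted = min(1, p * n_pairs))
  })
  pw$significant <- pw$p_adjusted < 0.05
  list(omnibus_p = omnibus, pairwise = pw)
}

#' Fuse the top models and evaluate on the test set
#'
#' Refits each member configuration on the full training/validation set,
#' predicts the test set, and evaluates each member alongside the two fusion
#' rules: plurality voting (PV) over the members' hard labels at their own
#' 0.5 thresholds, and weighted fusion (WF) of the member probabilities with
#' accuracy-proportional weights derived from the members' mean CV
#' validation accuracies.
#'
#' @param members tibble of member configurations as returned by
#'   [top_k_models()] (needs `config_id`, `phase_combo`, `region`,
#'   `selector`, `classifier`, `mean_acc`, and the `cv` list column).
#' @param store long feature store covering train and test cases.
#' @param split list from [chronological_split()].
#' @param k_features features selected per member (on the full training set).
#' @param seed seed for stochastic member refits.
#' @param threshold decision threshold for hard labels.
#' @return object of class `fusion_result`: list with `metrics` (tibble of
#'   member + PV + WF test metrics), `weights`, `predictions` (per-case
#'   member and fused scores/labels), `nri` (pairwise NRI tibble).
#' @export
fuse_top_models <- function(members, store, split, k_features = 10,
                            seed = 1L, threshold = 0.5) {
  abort_if(nrow(members) < 2, "need at least 2 members to fuse")
  combos <- phase_combos()
  train <- split$train; test <- split$test
  member_probs <- purrr::map(seq_len(nrow(members)), function(i) {
    cfg <- members[i, ]
    phases <- combos$phases[[match(cfg$phase_combo, combos$combo)]]
    mtr <- feature_matrix(store, train, phases, cfg$region)
    mte <- feature_matrix(store, test, phases, cfg$region)
    feat_cols <- setdiff(names(mtr), c("case_id", "chrono_index", "mvi_label"))
    sel <- select_features(as.matrix(mtr[, feat_cols]), mtr$mvi_label,
                           cfg$selector, k_features)
    model <- fit_classifier(as.matrix(mtr[, sel]), mtr$mvi_label,
                            cfg$classifier, seed = derive_seed(seed, "refit", i))
    predict_prob(model, as.matrix(mte[, sel, drop = FALSE]))
  })
  probs <- do.call(cbind, member_probs)
  colnames(probs) <- members$config_id
  truth <- dplyr::arrange(test, .data$chrono_index)$mvi_label
  hard <- probs >= threshold
  storage.mode(hard) <- "integer"
  weights <- compute_weights(members$mean_acc)
  pv_label <- apply(hard, 1, plurality_vote)
  wf <- weighted_fusion(probs, weights, threshold)
  metrics <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(ncol(probs)), function(i) {
      m <- classification_metrics(probs[, i], truth, threshold)
      tibble::tibble(model = colnames(probs)[i], kind = "member",
                     auc = m$auc, acc = m$acc, sen = m$sen, spe = m$spe)
    }),
    {
      m <- classification_metrics(pv_label, truth, threshold)
      tibble::tibble(model = "PV", kind = "fusion", auc = m$auc, acc = m$acc,
                     sen = m$sen, spe = m$spe)
    },
    {
      m <- classification_metrics(wf$score, truth, threshold)
      tibble::tibble(model = "WF", kind = "fusion", auc = m$auc, acc = m$acc,
                     sen = m$sen, spe = m$spe)
    })
  all_labels <- cbind(hard, PV = pv_label, WF = wf$label)
  preds <- tibble::tibble(
    case_id = dplyr::arrange(test, .data$chrono_index)$case_id,
    truth = truth,
    tibble::as_tibble(probs), pv_label = pv_label, wf_score = wf$score,
    wf_label = wf$label)
  structure(
    list(metrics = metrics, weights = setNames(weights, members$config_id),
         predictions = preds, nri = nri_matrix(all_labels, truth),
         threshold = threshold),
    class = "fusion_result")
}

#' @exportS3Method base::print
print.fusion_result <- function(x, ...) {
  cat("<fusion_result> test-set metrics:\n")
  print(as.data.frame(x$metrics), digits = 3)
  invisible(x)
}
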