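#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold cross-validation metrics
#'
#' @param x a [tenfold_cv()] result.
#' @param ... unused.
#' @return tibble with one row per fold: `fold`, `n_valid`, `auc`, `acc`,
#'   `sen`, `spe` and the per-fold `selected` feature list.
#' @export
tidy.cv_result <- function(x, ...) {
  x$folds
}

#' One-row cross-validation summary
#'
#' @param x a [tenfold_cv()] result.
#' @param ... unused.
#' @return one-row tibble with the configuration and mean metrics.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(selector = x$selector, classifier = x$classifier,
                 k_features = x$k_features, n_folds = nrow(x$folds),
                 mean_auc = x$mean_auc, mean_acc = x$mean_acc,
                 mean_sen = x$mean_sen, mean_spe = x$mean_spe)
}

#' Tidy fusion test-set metrics
#'
#' @param x a [fuse_top_models()] result.
#' @param ... unused.
#' @return tibble of member and fusion (PV/WF) test metrics.
#' @export
tidy.fusion_result <- function(x, ...) {
  x$metrics
}

#' One-row fusion summary
#'
#' @param x a [fuse_top_models()] result.
#' @param ... unused.
#' @return one-row tibble with the WF and PV test AUC, the best member AUC
#'   and the WF-versus-best-member NRI.
#' @export
glance.fusion_result <- function(x, ...) {
  members <- dplyr::filter(x$metrics, .data$kind == "member")
  wf <- dplyr::filter(x$metrics, .data$model == "WF")
  pv <- dplyr::filter(x$metrics, .data$model == "PV")
  best_member <- members$model[which.max(members$auc)]
  nri_wf <- dplyr::filter(x$nri, .data$model_y == "WF",
                          .data$model_x == best_member)$nri
  tibble::tibble(n_members = nrow(members), wf_auc = wf$auc, pv_auc = pv$auc,
                 best_member_auc = max(members$auc),
                 wf_vs_best_nri = nri_wf)
}

#' Tidy an NRI comparison
#'
#' @param x an [nri()] result.
#' @param ... unused.
#' @return one-row tibble with the NRI and its four reclassification
#'   fractions.
#' @export
tidy.nri_result <- function(x, ...) {
  tibble::tibble(nri = x$nri, event_up = x$event_up,
                 event_down = x$event_down, nonevent_up = x$nonevent_up,
                 nonevent_down = x$nonevent_down)
}
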