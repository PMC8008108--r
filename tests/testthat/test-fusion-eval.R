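test_that("plurality vote takes the majority and breaks ties positive", {
  expect_identical(plurality_vote(c(1, 1, 0)), 1L)
  expect_identical(plurality_vote(c(0, 0, 1)), 0L)
  expect_identical(plurality_vote(c(0, 0, 0, 0)), 0L)
  expect_message(tie <- plurality_vote(c(0, 1)), "tied")
  expect_identical(tie, 1L)
  expect_error(plurality_vote(1), "at least 2")
  expect_error(plurality_vote(c(0, 2)), "binary")
})

test_that("accuracy-proportional weights normalize the member accuracies", {
  accs <- c(0.704, 0.684, 0.70)
  w <- compute_weights(accs)
  expect_equal(sum(w), 1)
  expect_equal(w, accs / sum(accs))
  expect_equal(w[1], 0.704 / 2.088)
  expect_error(compute_weights(0.7), "at least 2")
  expect_error(compute_weights(c(0.7, 0)), "positive")
})

test_that("weighted fusion is the weighted linear combination of probabilities", {
  wf <- weighted_fusion(c(0.6, 0.4, 0.9), rep(1 / 3, 3))
  expect_equal(wf$score, mean(c(0.6, 0.4, 0.9)))
  expect_identical(wf$label, 1L)
  m <- rbind(c(1, 0), c(0.2, 0.4))
  wf2 <- weighted_fusion(m, c(0.75, 0.25))
  expect_equal(wf2$score, c(0.75, 0.25))
  expect_identical(wf2$label, c(1L, 0L))
  expect_error(weighted_fusion(c(0.5, 1.2), c(0.5, 0.5)), "\\[0, 1\\]")
  expect_error(weighted_fusion(c(0.5, 0.5), c(1)), "differ")
})

test_that("classification metrics match hand counts and the pair-count AUC", {
  # 2 positives scored 0.9 / 0.4 against 1 negative scored 0.5:
  # one concordant, one discordant pair
  m <- classification_metrics(c(0.9, 0.4, 0.5), c(1, 1, 0))
  expect_equal(m$auc, 0.5)
  # frozen confusion: TP 9, FN 2, TN 9, FP 3
  scores <- c(rep(0.9, 9), rep(0.1, 2), rep(0.1, 9), rep(0.9, 3))
  labels <- c(rep(1, 11), rep(0, 12))
  m2 <- classification_metrics(scores, labels)
  expect_equal(m2$sen, 9 / 11)
  expect_equal(m2$spe, 9 / 12)
  expect_equal(m2$acc, 18 / 23)
  # ties get the midrank correction
  expect_equal(classification_metrics(rep(0.5, 4), c(0, 1, 0, 1))$auc, 0.5)
  expect_error(classification_metrics(c(1, 0), c(1, 1)), "both classes")
})

test_that("rank AUC agrees with pair counting and pROC on random scores", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # induce ties
      got <- classification_metrics(scores, labels)$auc
      expect_equal(got, oracle_auc(scores, labels))
      if (requireNamespace("pROC", quietly = TRUE)) {
        ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<")))
        expect_equal(got, ref)
      }
    }
  })
})

test_that("NRI reproduces the toy reclassification example", {
  # 10 events: 3 reclassified up, 1 down; 10 non-events: 1 up, 1 down
  truth <- c(rep(1, 10), rep(0, 10))
  baseline <- c(rep(0, 4), rep(1, 6), rep(0, 9), 1)
  new      <- c(rep(1, 3), 0, 0, rep(1, 5), 1, rep(0, 8), 0)
  r <- nri(baseline, new, truth)
  expect_s3_class(r, "nri_result")
  expect_equal(r$event_up, 0.3)
  expect_equal(r$event_down, 0.1)
  expect_equal(r$nonevent_up, 0.1)
  expect_equal(r$nonevent_down, 0.1)
  expect_equal(r$nri, 0.2)
  expect_equal(tidy(r)$nri, 0.2)
  # identical models: zero everywhere
  expect_equal(nri(baseline, baseline, truth)$nri, 0)
  expect_error(nri(baseline, new, rep(1, 20)), "events")
})

test_that("the pairwise NRI matrix is antisymmetric with zero diagonal", {
  withr::with_seed(6, {
    truth <- rbinom(30, 1, 0.5); truth[1:2] <- c(0, 1)
    preds <- cbind(m1 = rbinom(30, 1, 0.4), m2 = rbinom(30, 1, 0.5),
                   m3 = rbinom(30, 1, 0.6))
    long <- nri_matrix(preds, truth)
    expect_equal(nrow(long), 9)
    m <- attr(long, "matrix")
    expect_equal(unname(diag(m)), rep(0, 3))
    expect_equal(m + t(m), matrix(0, 3, 3), ignore_attr = TRUE)
    expect_equal(m["m2", "m1"], nri(preds[, "m1"], preds[, "m2"], truth)$nri)
  })
})

test_that("feature_group_test flags shifted groups and spares null ones", {
  withr::with_seed(44, {
    null_dat <- data.frame(v = rnorm(60), g = rep(c("a", "b", "c"), 20))
    r0 <- feature_group_test(null_dat, "v", "g")
    expect_gt(r0$omnibus_p, 0.05)
    expect_false(any(r0$pairwise$significant))
    shift <- data.frame(v = c(rnorm(30), rnorm(30) + 3),
                        g = rep(c("a", "b"), each = 30))
    r1 <- feature_group_test(shift, "v", "g")
    expect_lt(r1$omnibus_p, 0.05)
    expect_true(all(r1$pairwise$significant))
    expect_true(all(r1$pairwise$p_adjusted >= r1$pairwise$p_raw))
    expect_error(feature_group_test(data.frame(v = 1:3, g = c("a", "a", "a")),
                                    "v", "g"), "2 groups")
  })
})

test_that("fuse_top_models evaluates members, PV and WF on the test set", {
  co <- generate_cohort(cohort_spec(
    n_patients = 14, prevalence = 0.5, volume_shape = c(28, 28, 28),
    tumor_radius_mm = c(3.5, 4.5), noise_sd = 10,
    effect_intensity = 60, effect_heterogeneity = 0, effect_extent_mm = 6,
    seed = 9L))
  store <- extract_cohort(co, phases = "PVP", distances = 6,
                          regions = c("V_tc", "V_pt(6)", "V_tc+V_pt(6)"))
  split <- chronological_split(co$labels, 10)
  cfg <- enumerate_configs("t_score", "lda", "Fpha3",
                           c("V_tc", "V_pt(6)", "V_tc+V_pt(6)"))
  bench <- run_benchmark(store, split$train, cfg, k_features = 5,
                         n_folds = 5, seed = 3L)
  top <- top_k_models(bench, 3)
  fus <- fuse_top_models(top, store, split, k_features = 5, seed = 1L)
  expect_s3_class(fus, "fusion_result")
  expect_equal(nrow(fus$metrics), 5)          # 3 members + PV + WF
  expect_setequal(fus$metrics$model[fus$metrics$kind == "fusion"],
                  c("PV", "WF"))
  expect_equal(sum(fus$weights), 1)
  expect_equal(nrow(fus$predictions), 4)
  # WF score is the weighted combination of the member probabilities
  probs <- as.matrix(fus$predictions[, top$config_id])
  expect_equal(fus$predictions$wf_score,
               as.numeric(probs %*% fus$weights))
  gl <- glance(fus)
  expect_true(all(c("wf_auc", "pv_auc", "best_member_auc",
                    "wf_vs_best_nri") %in% names(gl)))
  # deterministic under the same seed
  fus2 <- fuse_top_models(top, store, split, k_features = 5, seed = 1L)
  expect_identical(fus$metrics, fus2$metrics)
})
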