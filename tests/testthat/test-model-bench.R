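# wide tabular stand-in for a feature matrix: informative + noise columns
make_wide <- function(n = 40, p = 12, shift = 2.5, seed = 13) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * p), n)
    colnames(x) <- sprintf("feat%02d", seq_len(p))
    x[, 1] <- x[, 1] + shift * y
    x[, 2] <- x[, 2] - shift * y
    tibble::tibble(case_id = sprintf("case_%03d", seq_len(n)),
                   chrono_index = seq_len(n), mvi_label = y,
                   tibble::as_tibble(x))
  })
}

test_that("chronological_split respects order and sizes", {
  lb <- tibble::tibble(case_id = sprintf("c%d", 1:10),
                       chrono_index = 10:1, mvi_label = rep(c(0L, 1L), 5))
  sp <- chronological_split(lb, 7)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_identical(sp$train$chrono_index, 1:7)
  expect_identical(sp$test$chrono_index, 8:10)
  expect_length(intersect(sp$train$case_id, sp$test$case_id), 0)
  expect_error(chronological_split(lb, 10), "smaller")
  expect_error(chronological_split(lb, 0), "positive")
})

test_that("stratified folds balance both classes and are seeded", {
  y <- rep(c(0L, 1L), each = 25)
  f1 <- mvibench:::stratified_folds(y, 10, 7L)
  f2 <- mvibench:::stratified_folds(y, 10, 7L)
  f3 <- mvibench:::stratified_folds(y, 10, 8L)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  # each class is dealt round-robin: 25 cases over 10 folds gives per-class
  # fold sizes 2 or 3 for both classes
  expect_true(all(table(f1[y == 1]) %in% c(2, 3)))
  expect_true(all(table(f1[y == 0]) %in% c(2, 3)))
  expect_length(unique(f1), 10)
})

test_that("tenfold_cv separates signal and stays at chance on noise", {
  signal <- make_wide(shift = 3)
  cv_sig <- tenfold_cv(signal, "t_score", "lda", k_features = 4, seed = 2L)
  expect_s3_class(cv_sig, "cv_result")
  expect_equal(nrow(cv_sig$folds), 10)
  expect_gt(cv_sig$mean_auc, 0.8)
  noise <- make_wide(shift = 0, seed = 99)
  cv_noise <- tenfold_cv(noise, "t_score", "lda", k_features = 4, seed = 2L)
  expect_lt(abs(cv_noise$mean_auc - 0.5), 0.35)
  # per-fold selections are recorded with the requested size
  expect_true(all(lengths(cv_sig$folds$selected) == 4))
  expect_identical(
    cv_sig$mean_auc,
    tenfold_cv(signal, "t_score", "lda", k_features = 4, seed = 2L)$mean_auc)
})

test_that("tidy and glance summarize a cv_result", {
  cv <- tenfold_cv(make_wide(), "f_score", "logistic", k_features = 3,
                   seed = 4L)
  td <- tidy(cv)
  expect_true(all(c("fold", "auc", "acc", "selected") %in% names(td)))
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$selector, "f_score")
  expect_identical(gl$mean_auc, cv$mean_auc)
})

test_that("the full benchmark grid counts multiply to 33,750", {
  full <- enumerate_configs()
  expect_equal(nrow(full), 15 * 10 * 15 * 15)
  expect_equal(anyDuplicated(full$config_id), 0)
  sub <- enumerate_configs(selectors = c("t_score", "mim"),
                           classifiers = "lda",
                           combos = c("Fpha1", "Fpha3"),
                           regions = c("V_tc", "V_pt(4)", "V_tc+V_pt(4)"))
  expect_equal(nrow(sub), 2 * 1 * 2 * 3)
})

test_that("rank_models orders by AUC with deterministic tie-breaks", {
  res <- tibble::tibble(
    config_id = c("c", "a", "b", "d"),
    mean_auc = c(0.7, 0.9, 0.7, 0.7),
    mean_acc = c(0.6, 0.8, 0.7, 0.7))
  rk <- rank_models(res)
  expect_identical(rk$config_id, c("a", "b", "d", "c"))
  expect_identical(rk$rank, 1:4)
  expect_identical(top_k_models(res, 2)$config_id, c("a", "b"))
  expect_error(top_k_models(res, 5), "at least")
})

test_that("aggregate_phase_region averages and finds the best setting", {
  res <- tidyr::expand_grid(
    phase_combo = c("Fpha1", "Fpha3"),
    region = c("V_tc", "V_pt(4)", "V_pt(8)", "V_tc+V_pt(4)")) |>
    dplyr::mutate(config_id = paste(phase_combo, region, sep = "|"),
                  mean_auc = c(0.60, 0.55, 0.58, 0.62,
                               0.70, 0.72, 0.80, 0.78),
                  mean_acc = mean_auc)
  agg <- aggregate_phase_region(res)
  expect_s3_class(agg, "benchmark_summary")
  pr <- agg$phase_region
  expect_equal(pr$mean_auc[pr$phase_combo == "Fpha3" &
                             pr$region_class == "V_pt"],
               mean(c(0.72, 0.80)))
  # Fpha3 x V_tc+V_pt has the largest phase/region-class mean (0.78)
  expect_identical(agg$best$phase_combo, "Fpha3")
  expect_identical(agg$best$region_class, "V_tc+V_pt")
  expect_equal(agg$best$mean_auc, 0.78)
  tr <- agg$distance_trend
  # the trend pools phase combos within a region class and distance
  expect_equal(tr$mean_auc[tr$region_class == "V_pt" & tr$distance == 8],
               mean(c(0.58, 0.80)))
})

test_that("run_benchmark wires the store through CV deterministically", {
  co <- generate_cohort(cohort_spec(
    n_patients = 12, prevalence = 0.5, volume_shape = c(28, 28, 28),
    tumor_radius_mm = c(3.5, 4.5), noise_sd = 10, seed = 5L))
  store <- extract_cohort(co, phases = "PVP", distances = 4,
                          regions = c("V_tc", "V_tc+V_pt(4)"))
  cfg <- enumerate_configs("t_score", "lda", "Fpha3",
                           c("V_tc", "V_tc+V_pt(4)"))
  b1 <- run_benchmark(store, co$labels, cfg, k_features = 5, n_folds = 4,
                      seed = 11L)
  expect_equal(nrow(b1), 2)
  expect_true(all(c("config_id", "mean_auc", "mean_acc", "cv") %in% names(b1)))
  b2 <- run_benchmark(store, co$labels, cfg, k_features = 5, n_folds = 4,
                      seed = 11L)
  expect_identical(b1$mean_auc, b2$mean_auc)
})

test_that("top_feature_census percentages sum to 100", {
  cv <- tenfold_cv(make_wide(shift = 3), "t_score", "lda", k_features = 3,
                   seed = 2L)
  res <- tibble::tibble(config_id = "x", mean_auc = cv$mean_auc,
                        mean_acc = cv$mean_acc, cv = list(cv))
  cen <- top_feature_census(res, auc_min = 0.5, top_n = 3)
  expect_equal(sum(cen$percentage), 100)
  expect_true("feat01" %in% cen$feature)
  expect_warning(none <- top_feature_census(res, auc_min = 1),
                 "no configuration")
  expect_equal(nrow(none), 0)
})
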