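#' Configure a full study run
#'
#' Bundles every choice a study depends on: the synthetic cohort, the
#' peritumoral distances, the discretization, the benchmark grid subset and
#' the seeds. A `run_config` plus the package version fully determines a
#' [run_study()] result. The default grid is a reduced subset sized for
#' interactive use; pass the full registries for the complete
#' 33,750-configuration grid.
#'
#' @param spec a [cohort_spec()].
#' @param distances peritumoral distances (mm).
#' @param bin_width discretization bin width.
#' @param selectors,classifiers grid subsets (defaults: 4 selectors x 3
#'   classifiers).
#' @param combos phase-combination labels (default: the 4 single-phase
#'   groups).
#' @param regions region ids (default: core plus combined regions at
#'   `distances`).
#' @param n_train training/validation set size for the chronological split.
#' @param k_features features selected per fold.
#' @param n_folds CV folds.
#' @param seed master seed; every stage derives its own substream from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(),
                       distances = seq(2, 14, by = 2),
                       bin_width = 25,
                       selectors = c("t_score", "f_score", "trace_ratio", "mim"),
                       classifiers = c("lda", "logistic", "random_forest"),
                       combos = c("Fpha1", "Fpha2", "Fpha3", "Fpha4"),
                       regions = c("V_tc", sprintf("V_tc+V_pt(%d)", distances)),
                       n_train = round(0.8 * spec$n_patients),
                       k_features = 10, n_folds = 10, seed = 1L) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  structure(list(spec = spec, distances = distances, bin_width = bin_width,
                 selectors = selectors, classifiers = classifiers,
                 combos = combos, regions = regions, n_train = n_train,
                 k_features = k_features, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Executes the complete workflow: synthetic cohort generation, region
#' construction, feature extraction, chronological split, grid benchmarking
#' by ten-fold CV on the training/validation set, phase/region aggregation,
#' distance trend, top-3 ranking at the best setting, PV/WF fusion with
#' test-set metrics and the pairwise NRI matrix, the top-feature census, and
#' the rank-based comparison across phase groups.
#'
#' @param config a [run_config()].
#' @return list of class `study_result`: `benchmark` (per-config results),
#'   `summary` ([aggregate_phase_region()] output), `top3`, `fusion`
#'   ([fuse_top_models()] output), `census`, `group_test`, `split`, `log`
#'   (config echo with seeds).
#' @export
run_study <- function(config) {
  abort_if(!inherits(config, "run_config"), "`config` must be a run_config")
  cohort <- generate_cohort(config$spec)
  combos <- phase_combos()
  used_phases <- unique(unlist(
    combos$phases[match(config$combos, combos$combo)]))
  store <- extract_cohort(cohort, phases = used_phases,
                          distances = config$distances,
                          regions = config$regions,
                          bin_width = config$bin_width)
  split <- chronological_split(cohort$labels, config$n_train)
  configs <- enumerate_configs(config$selectors, config$classifiers,
                               config$combos, config$regions)
  train_store <- dplyr::filter(store, .data$case_id %in% split$train$case_id)
  bench <- run_benchmark(train_store, split$train, configs,
                         config$k_features, config$n_folds,
                         seed = derive_seed(config$seed, "bench"))
  summ <- aggregate_phase_region(bench)
  # optimal setting: best phase combo, best region class; rank its models
  best_subset <- bench |>
    dplyr::mutate(region_class = region_class(.data$region)) |>
    dplyr::filter(.data$phase_combo == summ$best$phase_combo,
                  .data$region_class == summ$best$region_class)
  if (summ$best$region_class != "V_tc") {
    trend <- dplyr::filter(summ$distance_trend,
                           .data$region_class == summ$best$region_class)
    best_d <- trend$distance[which.max(trend$mean_auc)]
    best_subset <- dplyr::filter(best_subset,
                                 region_distance(.data$region) == best_d)
  }
  top3 <- top_k_models(best_subset, min(3, nrow(best_subset)))
  fusion <- fuse_top_models(top3, store, split, config$k_features,
                            seed = derive_seed(config$seed, "fusion"))
  census <- top_feature_census(bench)
  group_test <- if (length(unique(bench$phase_combo)) >= 2)
    feature_group_test(bench, "mean_auc", "phase_combo") else NULL
  structure(
    list(benchmark = dplyr::select(bench, -"cv"), summary = summ,
         top3 = dplyr::select(top3, -"cv"), fusion = fusion, census = census,
         group_test = group_test, split = split,
         labels = cohort$labels,
         log = list(config = config, seed = config$seed,
                    n_configs = nrow(configs), phases = used_phases)),
    class = "study_result")
}

#' @exportS3Method base::print
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d configs benchmarked; best setting %s / %s\n",
              nrow(x$benchmark), x$summary$best$phase_combo,
              x$summary$best$region_class))
  print(x$fusion)
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Write a phantom case to NIfTI files
#'
#' One image per phase (`<phase>.nii.gz`) and one file per anatomy mask,
#' with the voxel spacing stored in the headers.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ph in names(case$phases)) {
    p <- file.path(dir, paste0(ph, ".nii.gz"))
    im <- RNifti::asNifti(case$phases[[ph]])
    RNifti::pixdim(im) <- case$spacing_mm
    RNifti::writeNifti(im, p)
    paths <- c(paths, p)
  }
  for (mk in c("liver_mask", "tumor_mask", "vessel_mask", "bileduct_mask")) {
    p <- file.path(dir, paste0(mk, ".nii.gz"))
    im <- RNifti::asNifti(array(as.integer(case[[mk]]), dim(case[[mk]])))
    RNifti::pixdim(im) <- case$spacing_mm
    RNifti::writeNifti(im, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a cohort to disk
#'
#' Writes each case's NIfTI files into `dir/<case_id>/` and the label table
#' (with generator parameters) to `dir/cohort.csv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return invisibly, the cohort CSV path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$cases))
    write_phantom_case(cohort$cases[[id]], file.path(dir, id))
  spec <- cohort$spec
  tbl <- cohort$labels |>
    dplyr::mutate(n_patients = spec$n_patients, prevalence = spec$prevalence,
                  effect_intensity = spec$effect_intensity,
                  effect_heterogeneity = spec$effect_heterogeneity,
                  noise_sd = spec$noise_sd, seed = spec$seed)
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Read a case from NIfTI files
#'
#' Loads phase images and masks, validating that all volumes share one shape
#' and voxel spacing (read from the headers).
#'
#' @param image_paths named character vector of phase image paths (names are
#'   phase ids).
#' @param mask_paths named character vector with entries `liver_mask`,
#'   `tumor_mask` and optionally `vessel_mask`, `bileduct_mask`.
#' @return a `phantom_case`-equivalent list usable by [build_region_set()]
#'   and [extract_case()].
#' @export
read_case <- function(image_paths, mask_paths) {
  abort_if(is.null(names(image_paths)) || is.null(names(mask_paths)),
           "image and mask paths must be named")
  imgs <- lapply(image_paths, RNifti::readNifti)
  msks <- lapply(mask_paths, RNifti::readNifti)
  all_vols <- c(imgs, msks)
  ref_dim <- dim(all_vols[[1]])
  ref_pix <- RNifti::pixdim(all_vols[[1]])[1:3]
  for (nm in names(all_vols)) {
    abort_if(!identical(dim(all_vols[[nm]]), ref_dim),
             sprintf("volume `%s` has shape %s, expected %s", nm,
                     paste(dim(all_vols[[nm]]), collapse = "x"),
                     paste(ref_dim, collapse = "x")))
    abort_if(max(abs(RNifti::pixdim(all_vols[[nm]])[1:3] - ref_pix)) > 1e-4,
             sprintf("volume `%s` disagrees on voxel spacing", nm))
  }
  phases <- lapply(imgs, function(v) array(as.numeric(v), ref_dim))
  masks <- lapply(msks, function(v) array(as.numeric(v) != 0, ref_dim))
  out <- c(list(phases = phases), masks,
           list(spacing_mm = as.numeric(ref_pix)))
  if (is.null(out$vessel_mask)) out$vessel_mask <- array(FALSE, ref_dim)
  if (is.null(out$bileduct_mask)) out$bileduct_mask <- array(FALSE, ref_dim)
  structure(out, class = "phantom_case")
}
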