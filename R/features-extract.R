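#' The 94-feature radiomics catalogue
#'
#' Feature names and family tags for the catalogue: 19 first-order, 24 GLCM,
#' 16 GLSZM, 16 GLRLM, 5 NGTDM and 14 GLDM features.
#'
#' @return tibble with columns `feature` and `family` (94 rows).
#' @export
feature_catalogue <- function() {
  img <- array(rep(c(1, 2), 4), c(2, 2, 2))
  msk <- array(TRUE, c(2, 2, 2))
  nm <- c(names(first_order_features(c(1, 2, 3))),
          names(glcm_features(img, msk, 1)),
          names(glszm_features(img, msk, 1)),
          names(glrlm_features(img, msk, 1)),
          names(ngtdm_features(img, msk, 1)),
          names(gldm_features(img, msk, 1)))
  tibble::tibble(feature = nm, family = sub("_.*$", "", nm))
}

#' Extract the full 94-feature vector from one region
#'
#' Computes all six feature families on the intensities of `image` inside
#' `mask`, using one shared fixed-bin-width discretization for the texture
#' matrices.
#'
#' @param image numeric 3D intensity array.
#' @param mask binary 3D mask (>= 2 voxels).
#' @param spacing_mm physical voxel size (mm) for the total-energy feature.
#' @param bin_width discretization bin width (default 25).
#' @return tibble with columns `feature`, `family`, `value` (94 rows).
#' @export
radiomic_features <- function(image, mask, spacing_mm = c(1, 1, 1),
                              bin_width = 25) {
  mask <- as_mask(mask)
  check_same_shape(image, mask, c("image", "mask"))
  abort_if(sum(mask) < 2,
           "degenerate region: radiomic features need at least 2 voxels")
  spacing_mm <- check_spacing(spacing_mm)
  vals <- as.numeric(image[mask])
  v <- c(first_order_features(vals, bin_width, prod(spacing_mm)),
         glcm_features(image, mask, bin_width),
         glszm_features(image, mask, bin_width),
         glrlm_features(image, mask, bin_width),
         ngtdm_features(image, mask, bin_width),
         gldm_features(image, mask, bin_width))
  tibble::tibble(feature = names(v), family = sub("_.*$", "", names(v)),
                 value = unname(v))
}

#' Extract features for one case, phase and region
#'
#' @param case a `phantom_case` (or the list [read_case()] returns).
#' @param regions a [build_region_set()] result for the case.
#' @param phase phase id (`"EAP"`, `"LAP"`, `"PVP"`, `"EP"`).
#' @param region region id (e.g. `"V_tc"`, `"V_pt(12)"`, `"V_tc+V_pt(12)"`).
#' @param bin_width discretization bin width.
#' @return tibble with columns `phase`, `region`, `feature`, `family`,
#'   `value` (94 rows).
#' @export
extract_case <- function(case, regions, phase, region = "V_tc",
                         bin_width = 25) {
  abort_if(!phase %in% names(case$phases),
           sprintf("phase `%s` not present in case", phase))
  mask <- region_mask(regions, region)
  out <- radiomic_features(case$phases[[phase]], mask, case$spacing_mm,
                           bin_width)
  tibble::tibble(phase = phase, region = region, out)
}

#' Enumerate the 15 phase combinations
#'
#' All non-empty subsets of the four phases, labelled `Fpha1` ... `Fpha1;2;3;4`
#' with phases numbered EAP = 1, LAP = 2, PVP = 3, EP = 4: four single-phase
#' groups, six pairs, four triples and one quadruple.
#'
#' @return tibble with columns `combo` (label), `phases` (list column) and
#'   `n_phases`.
#' @export
phase_combos <- function() {
  ph <- ct_phases()
  subsets <- unlist(lapply(seq_along(ph), function(k) {
    asplit(combn(4, k), 2)
  }), recursive = FALSE)
  tibble::tibble(
    combo = vapply(subsets, function(s) paste0("Fpha", paste(s, collapse = ";")),
                   character(1)),
    phases = lapply(subsets, function(s) ph[s]),
    n_phases = lengths(subsets))
}

#' Concatenate per-phase feature vectors into one combined vector
#'
#' Joins the 94-feature vectors of the phases in `combo` into a single
#' phase-prefixed vector of `94 * length(phases)` features; all vectors must
#' come from the same region.
#'
#' @param vectors tibble of per-phase features as returned by
#'   [extract_case()] (long form, possibly several phases stacked).
#' @param combo character vector of phase ids to concatenate.
#' @return tibble with columns `region`, `feature` (phase-prefixed), `value`.
#' @export
concat_phases <- function(vectors, combo) {
  abort_if(!all(combo %in% vectors$phase),
           sprintf("missing phase(s): %s",
                   paste(setdiff(combo, vectors$phase), collapse = ", ")))
  abort_if(length(unique(vectors$region)) != 1,
           "all vectors must share one region tag")
  vectors |>
    dplyr::filter(.data$phase %in% combo) |>
    dplyr::mutate(phase = factor(.data$phase, levels = combo)) |>
    dplyr::arrange(.data$phase) |>
    dplyr::transmute(region = .data$region,
                     feature = paste0(as.character(.data$phase), "_", .data$feature),
                     value = .data$value)
}

#' Extract the cohort-level feature store
#'
#' For every case: builds the barrier mask (large vessels by
#' [vessel_caliber_filter()] plus bile ducts), constructs the region set from
#' the tumor core, and extracts the 94-feature vector for each requested
#' phase and region. This is the long-form store every benchmark matrix is
#' assembled from.
#'
#' @param cohort a [generate_cohort()] result.
#' @param phases phases to extract (default all four).
#' @param distances peritumoral distances for the region sets.
#' @param regions region ids to extract (default all 15 options).
#' @param bin_width discretization bin width.
#' @param min_caliber_mm vessel caliber threshold for the barrier mask.
#' @return tibble with columns `case_id`, `phase`, `region`, `feature`,
#'   `family`, `value`.
#' @export
extract_cohort <- function(cohort, phases = ct_phases(),
                           distances = seq(2, 14, by = 2),
                           regions = region_options(distances),
                           bin_width = 25, min_caliber_mm = 2) {
  abort_if(!inherits(cohort, "phantom_cohort"), "`cohort` must be a phantom_cohort")
  purrr::map_dfr(names(cohort$cases), function(id) {
    case <- cohort$cases[[id]]
    barrier <- vessel_caliber_filter(case$vessel_mask, case$spacing_mm,
                                     min_caliber_mm) | case$bileduct_mask
    rs <- build_region_set(case$tumor_mask, case$liver_mask, barrier,
                           case$spacing_mm, distances)
    purrr::map_dfr(phases, function(ph) {
      purrr::map_dfr(regions, function(rg) {
        extract_case(case, rs, ph, rg, bin_width)
      })
    }) |>
      dplyr::mutate(case_id = id, .before = 1)
  })
}

#' Assemble a wide feature matrix for one phase combination and region
#'
#' Filters the long store to `phases` and `region`, prefixes feature names by
#' phase, pivots to one row per case and joins the label table. Column count
#' is `94 * length(phases)` plus the identifier columns.
#'
#' @param store long feature store from [extract_cohort()].
#' @param labels label tibble (`case_id`, `chrono_index`, `mvi_label`).
#' @param phases character vector of phase ids.
#' @param region single region id.
#' @return wide tibble: `case_id`, `chrono_index`, `mvi_label`, then feature
#'   columns.
#' @export
feature_matrix <- function(store, labels, phases, region) {
  sub <- store |>
    dplyr::filter(.data$phase %in% phases, .data$region == !!region)
  abort_if(nrow(sub) == 0, "no features in store for the requested phases/region")
  abort_if(!all(phases %in% sub$phase),
           sprintf("store lacks phase(s): %s",
                   paste(setdiff(phases, sub$phase), collapse = ", ")))
  wide <- sub |>
    dplyr::mutate(feature = paste0(.data$phase, "_", .data$feature)) |>
    dplyr::select("case_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  labels |>
    dplyr::select("case_id", "chrono_index", "mvi_label") |>
    dplyr::inner_join(wide, by = "case_id") |>
    dplyr::arrange(.data$chrono_index)
}
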