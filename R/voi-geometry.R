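#' Dice similarity coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`, the standard overlap measure for paired
#' delineations of the same structure.
#'
#' @param mask_a,mask_b binary 3D arrays of equal shape; at least one must be
#'   non-empty.
#' @return the Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  mask_a <- as_mask(mask_a, "mask_a")
  mask_b <- as_mask(mask_b, "mask_b")
  check_same_shape(mask_a, mask_b)
  na <- sum(mask_a); nb <- sum(mask_b)
  abort_if(na + nb == 0, "Dice is undefined when both masks are empty")
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Consensus mask from two raters' delineations
#'
#' Pairs whose Dice coefficient exceeds `dice_threshold` are averaged
#' voxelwise and thresholded at 0.5 (tie-inclusive), which for two raters
#' equals their union; an `"intersection"` rule (strict majority) is offered
#' as a config option. Pairs at or below the threshold are surfaced as a
#' disagreement state — the workflow this mirrors resolves those by human
#' discussion, so no mask is returned.
#'
#' @param mask_a,mask_b binary 3D arrays of equal shape.
#' @param dice_threshold concordance threshold (default 0.9).
#' @param rule `"union"` (average >= 0.5) or `"intersection"` (> 0.5).
#' @return an object of class `consensus_result`: list with `agreed`
#'   (logical), `dice`, and `mask` (`NULL` on disagreement).
#' @export
consensus_mask <- function(mask_a, mask_b, dice_threshold = 0.9,
                           rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  mask_a <- as_mask(mask_a, "mask_a")
  mask_b <- as_mask(mask_b, "mask_b")
  d <- dice(mask_a, mask_b)
  if (d > dice_threshold) {
    avg <- (mask_a + mask_b) / 2
    mask <- if (rule == "union") avg >= 0.5 else avg > 0.5
    out <- list(agreed = TRUE, dice = d, mask = array(mask, dim(mask_a)))
  } else {
    out <- list(agreed = FALSE, dice = d, mask = NULL)
  }
  structure(out, class = "consensus_result")
}

#' @exportS3Method base::print
print.consensus_result <- function(x, ...) {
  if (x$agreed)
    cat(sprintf("<consensus_result> agreed (Dice %.3f), %d voxels\n",
                x$dice, sum(x$mask)))
  else
    cat(sprintf("<consensus_result> DISAGREEMENT (Dice %.3f) - resolve manually\n",
                x$dice))
  invisible(x)
}

#' Retain only large vessels by caliber
#'
#' Keeps the 26-connected components of a vessel mask whose caliber — the
#' maximum inscribed-sphere diameter, estimated as twice the largest interior
#' distance to background minus one voxel extent — reaches
#' `min_caliber_mm`. Used to build the barrier mask that stops peritumoral
#' expansion at large vessels.
#'
#' @param vessel_mask binary 3D array.
#' @param spacing_mm physical voxel size (mm), length 3.
#' @param min_caliber_mm minimum vessel caliber retained (default 2 mm).
#' @return binary array containing only the retained components.
#' @export
vessel_caliber_filter <- function(vessel_mask, spacing_mm, min_caliber_mm = 2) {
  vessel_mask <- as_mask(vessel_mask, "vessel_mask")
  spacing_mm <- check_spacing(spacing_mm)
  if (!any(vessel_mask)) return(vessel_mask)
  dims <- dim(vessel_mask)
  labs <- array(cpp_components(as.integer(vessel_mask), dims), dims)
  # interior distance: from each vessel voxel centre to the nearest
  # background voxel centre; caliber = 2*max - one voxel (centre-to-boundary
  # half-voxel correction on each side)
  dist_bg <- sqrt(cpp_sq_edt(as.integer(!vessel_mask), dims, spacing_mm))
  keep <- array(FALSE, dims)
  for (comp in seq_len(max(labs))) {
    sel <- labs == comp
    caliber <- 2 * max(dist_bg[sel]) - min(spacing_mm)
    if (caliber >= min_caliber_mm) keep <- keep | sel
  }
  keep
}

#' Expand a tumor core into a barrier-aware peritumoral ring
#'
#' Returns the voxels outside the core whose physical distance to the core
#' is at most `distance_mm`, restricted to the liver and excluding barrier
#' voxels (large vessels, bile ducts) — so the expansion stops at the liver
#' margin and at barrier structures. Distances are Euclidean between voxel
#' centres with anisotropic spacing; the `"geodesic"` metric instead
#' propagates distance through the permitted region only, so barriers also
#' block the path of the expansion rather than just being excluded from the
#' result.
#'
#' @param core binary tumor-core mask (non-empty, inside `liver_mask`).
#' @param liver_mask binary liver mask.
#' @param barrier_mask binary mask of structures that stop the expansion;
#'   `NULL` for none.
#' @param spacing_mm physical voxel size (mm), length 3.
#' @param distance_mm expansion distance in mm (>= 0).
#' @param metric `"euclidean"` (default) or `"geodesic"`.
#' @return binary ring mask, disjoint from `core`.
#' @export
expand_region <- function(core, liver_mask, barrier_mask = NULL, spacing_mm,
                          distance_mm, metric = c("euclidean", "geodesic")) {
  metric <- match.arg(metric)
  core <- as_mask(core, "core")
  liver_mask <- as_mask(liver_mask, "liver_mask")
  check_same_shape(core, liver_mask, c("core", "liver_mask"))
  if (is.null(barrier_mask)) barrier_mask <- array(FALSE, dim(core))
  barrier_mask <- as_mask(barrier_mask, "barrier_mask")
  check_same_shape(core, barrier_mask, c("core", "barrier_mask"))
  spacing_mm <- check_spacing(spacing_mm)
  abort_if(!any(core), "`core` mask is empty")
  abort_if(any(core & !liver_mask), "`core` must lie inside `liver_mask`")
  abort_if(distance_mm < 0, "`distance_mm` must be non-negative")
  dims <- dim(core)
  if (metric == "euclidean") {
    d <- sqrt(cpp_sq_edt(as.integer(core), dims, spacing_mm))
  } else {
    allowed <- liver_mask & !barrier_mask
    d <- cpp_geodesic_dist(as.integer(allowed), as.integer(core), dims, spacing_mm)
  }
  d <- array(d, dims)
  tol <- 1e-9 * max(1, distance_mm)
  ring <- !core & liver_mask & !barrier_mask & (d <= distance_mm + tol)
  array(ring, dims)
}

#' Build the full region set for one case
#'
#' Constructs the tumor core `V_tc`, the peritumoral rings `V_pt(d)` for
#' each requested distance (cumulative shells from the tumor margin out to
#' `d`), and the combined regions `V_tc + V_pt(d)`.
#'
#' @inheritParams expand_region
#' @param distances expansion distances in mm (default `2, 4, ..., 14`).
#' @return an object of class `region_set`: list with `core`, named lists
#'   `rings` and `combined` keyed by distance, `spacing_mm` and `distances`.
#' @export
build_region_set <- function(core, liver_mask, barrier_mask = NULL, spacing_mm,
                             distances = seq(2, 14, by = 2),
                             metric = c("euclidean", "geodesic")) {
  metric <- match.arg(metric)
  abort_if(length(distances) < 1 || any(distances < 0),
           "`distances` must be non-negative")
  rings <- lapply(distances, function(d) {
    expand_region(core, liver_mask, barrier_mask, spacing_mm, d, metric)
  })
  names(rings) <- as.character(distances)
  combined <- lapply(rings, function(r) r | as_mask(core))
  structure(
    list(core = as_mask(core), rings = rings, combined = combined,
         spacing_mm = check_spacing(spacing_mm),
         distances = as.numeric(distances)),
    class = "region_set")
}

#' @exportS3Method base::print
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> core %d voxels; rings at %s mm: %s voxels\n",
              sum(x$core), paste(x$distances, collapse = ", "),
              paste(vapply(x$rings, sum, numeric(1)), collapse = ", ")))
  invisible(x)
}

# resolve a region identifier ("V_tc", "V_pt(12)", "V_tc+V_pt(12)") to a mask
region_mask <- function(regions, region_id) {
  abort_if(!inherits(regions, "region_set"), "`regions` must be a region_set")
  if (region_id == "V_tc") return(regions$core)
  m <- regmatches(region_id, regexec("^(V_tc\\+)?V_pt\\((\\d+)\\)$", region_id))[[1]]
  abort_if(length(m) == 0, sprintf("unknown region id `%s`", region_id))
  d <- m[3]
  abort_if(!d %in% names(regions$rings),
           sprintf("distance %s mm not present in region set", d))
  if (m[2] == "V_tc+") regions$combined[[d]] else regions$rings[[d]]
}

#' Enumerate the region options of the benchmarking grid
#'
#' The tumor core, the peritumoral ring at each distance, and their union at
#' each distance: `1 + 7 + 7 = 15` options for the default distances.
#'
#' @param distances peritumoral distances in mm.
#' @return character vector of region identifiers.
#' @export
region_options <- function(distances = seq(2, 14, by = 2)) {
  c("V_tc",
    sprintf("V_pt(%d)", distances),
    sprintf("V_tc+V_pt(%d)", distances))
}

# region class of an identifier: V_tc, V_pt or V_tc+V_pt; distance or NA
region_class <- function(region_id) {
  ifelse(region_id == "V_tc", "V_tc",
         ifelse(grepl("^V_tc\\+", region_id), "V_tc+V_pt", "V_pt"))
}

region_distance <- function(region_id) {
  d <- suppressWarnings(as.numeric(sub("^.*V_pt\\((\\d+)\\)$", "\\1", region_id)))
  ifelse(region_id == "V_tc", NA_real_, d)
}
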