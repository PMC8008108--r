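#' Specify a synthetic MVI cohort
#'
#' A `cohort_spec` fixes every parameter of the synthetic four-phase CT
#' cohort generator: cohort size and MVI prevalence, the voxel grid, the
#' tumor geometry, the class effects carried by MVI-positive cases, the
#' noise level and the density of barrier structures (vessels, bile ducts).
#' Together with a seed it fully determines the generated cohort.
#'
#' MVI-positive cases differ from negatives in two ways, both confined by
#' default to the portal-venous-phase (PVP) analog within
#' `effect_extent_mm` of the tumor margin: an additive intensity shift of
#' `effect_intensity` HU-like units on the peritumoral shell, and speckle
#' patches of a second gray-level population controlled by
#' `effect_heterogeneity`, which raise zone-size (GLSZM) heterogeneity.
#'
#' @param n_patients number of cases (>= 2).
#' @param prevalence fraction of MVI-positive cases, strictly in (0, 1).
#' @param volume_shape integer voxel grid, length 3.
#' @param spacing_mm physical voxel size in mm, length 3, all > 0.
#' @param tumor_radius_mm length-2 range the tumor radius is drawn from (mm).
#' @param effect_intensity additive HU-like shift applied to the peritumoral
#'   shell of positives on the effect phase.
#' @param effect_heterogeneity texture-mixing parameter in `[0, 1]`; 0 disables
#'   speckle injection.
#' @param noise_sd Gaussian noise standard deviation (HU-like units).
#' @param barrier_density expected number of vessel structures per volume.
#' @param effect_phase phase carrying the class effect (default `"PVP"`).
#' @param effect_extent_mm peritumoral distance (mm) the class effect covers.
#' @param seed master RNG seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 111,
                        prevalence = 57 / 111,
                        volume_shape = c(64L, 64L, 64L),
                        spacing_mm = c(1, 1, 1),
                        tumor_radius_mm = c(6, 10),
                        effect_intensity = 30,
                        effect_heterogeneity = 0.3,
                        noise_sd = 20,
                        barrier_density = 3,
                        effect_phase = "PVP",
                        effect_extent_mm = 12,
                        seed = 1L) {
  abort_if(n_patients < 2, "`n_patients` must be at least 2")
  abort_if(prevalence <= 0 || prevalence >= 1,
           "`prevalence` must be strictly between 0 and 1")
  abort_if(length(volume_shape) != 3L || any(volume_shape < 8),
           "`volume_shape` must be three dimensions of at least 8 voxels")
  spacing_mm <- check_spacing(spacing_mm)
  abort_if(length(tumor_radius_mm) != 2L || any(tumor_radius_mm <= 0) ||
             diff(tumor_radius_mm) < 0,
           "`tumor_radius_mm` must be an increasing positive range")
  abort_if(effect_heterogeneity < 0 || effect_heterogeneity > 1,
           "`effect_heterogeneity` must lie in [0, 1]")
  abort_if(noise_sd < 0, "`noise_sd` must be non-negative")
  abort_if(!effect_phase %in% ct_phases(),
           "`effect_phase` must be one of EAP, LAP, PVP, EP")
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         volume_shape = as.integer(volume_shape), spacing_mm = spacing_mm,
         tumor_radius_mm = as.numeric(tumor_radius_mm),
         effect_intensity = effect_intensity,
         effect_heterogeneity = effect_heterogeneity,
         noise_sd = noise_sd, barrier_density = barrier_density,
         effect_phase = effect_phase, effect_extent_mm = effect_extent_mm,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' The four dynamic contrast phases
#'
#' Phase identifiers in acquisition order: early arterial (EAP), late
#' arterial (LAP), portal venous (PVP) and equilibrium (EP).
#' @return character vector of the four phase ids.
#' @export
ct_phases <- function() c("EAP", "LAP", "PVP", "EP")

# per-tissue HU-like offsets for each phase; rows tissue, columns phase.
# HCC analog: arterial enhancement of the tumor, washout on PVP/EP.
tissue_contrast <- function() {
  m <- rbind(
    background = c(-150, -150, -150, -150),
    liver      = c(  60,   90,  110,   85),
    tumor      = c( 120,  140,   60,   50),
    vessel     = c( 200,  250,  180,  120),
    bileduct   = c(  10,   10,   10,   10))
  colnames(m) <- ct_phases()
  m
}

# mark voxels within `radius_mm` of the polyline `pts` (n x 3, physical mm)
rasterize_tube <- function(shape, spacing, pts, radius_mm) {
  mask <- array(FALSE, shape)
  nseg <- nrow(pts) - 1L
  for (s in seq_len(nseg)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    lo <- pmin(a, b) - radius_mm
    hi <- pmax(a, b) + radius_mm
    i0 <- pmax(1L, floor(lo / spacing) + 1L)
    i1 <- pmin(shape, ceiling(hi / spacing) + 1L)
    if (any(i0 > i1)) next
    xs <- (seq(i0[1], i1[1]) - 1) * spacing[1]
    ys <- (seq(i0[2], i1[2]) - 1) * spacing[2]
    zs <- (seq(i0[3], i1[3]) - 1) * spacing[3]
    g <- expand.grid(x = xs, y = ys, z = zs)
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (g$x - a[1])^2 + (g$y - a[2])^2 + (g$z - a[3])^2
    } else {
      t <- ((g$x - a[1]) * ab[1] + (g$y - a[2]) * ab[2] + (g$z - a[3]) * ab[3]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (g$x - (a[1] + t * ab[1]))^2 +
            (g$y - (a[2] + t * ab[2]))^2 +
            (g$z - (a[3] + t * ab[3]))^2
    }
    inside <- d2 <= radius_mm^2
    if (!any(inside)) next
    ix <- as.matrix(expand.grid(seq(i0[1], i1[1]), seq(i0[2], i1[2]),
                                seq(i0[3], i1[3])))[inside, , drop = FALSE]
    mask[ix] <- TRUE
  }
  mask
}

random_walk_tube <- function(start, extent, n_steps = 14L, step_mm = 3) {
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(NA_real_, n_steps + 1L, 3L)
  pts[1, ] <- start
  for (i in seq_len(n_steps)) {
    dir <- dir + rnorm(3, sd = 0.35)
    dir <- dir / sqrt(sum(dir^2))
    nxt <- pts[i, ] + dir * step_mm
    nxt <- pmin(pmax(nxt, 0), extent)
    pts[i + 1L, ] <- nxt
  }
  pts
}

#' Generate a single synthetic four-phase liver phantom
#'
#' Builds one case: a liver ellipsoid containing a boundary-perturbed
#' spheroidal tumor, random-walk vessel tubes of mixed caliber, thin bile
#' ducts, and four co-registered phase volumes that share anatomy but differ
#' by per-tissue contrast offsets. When `label == 1`, the phase named in
#' `spec$effect_phase` carries the MVI class effect on the peritumoral shell
#' within `spec$effect_extent_mm` of the tumor margin: an additive intensity
#' shift plus, when `effect_heterogeneity > 0`, speckle patches of a second
#' gray-level population.
#'
#' Output is deterministic given `(spec, case_seed, label)`; the anatomy and
#' the noise field do not depend on the label, so a matched pair generated
#' with the two labels differs only through the injected class effect.
#'
#' @param spec a [cohort_spec()].
#' @param case_seed integer per-case seed.
#' @param label MVI label, 0 or 1.
#' @return an object of class `phantom_case`: named list of the four phase
#'   volumes, binary anatomy masks (`liver_mask`, `tumor_mask`,
#'   `vessel_mask`, `bileduct_mask`), `spacing_mm`, `mvi_label` and
#'   provenance fields.
#' @export
generate_phantom <- function(spec, case_seed, label) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  abort_if(!label %in% c(0, 1), "`label` must be 0 or 1")
  shape <- spec$volume_shape
  spacing <- spec$spacing_mm
  extent <- (shape - 1) * spacing
  with_seed(case_seed, {
    # --- geometry (label-independent) ------------------------------------
    liver_center <- extent / 2
    liver_semi <- extent * 0.46
    r0 <- runif(1, spec$tumor_radius_mm[1], spec$tumor_radius_mm[2])
    abort_if(r0 >= min(liver_semi),
             sprintf("tumor radius %.1f mm does not fit inside the liver (semi-axis %.1f mm)",
                     r0, min(liver_semi)))
    # place the tumor so that, where geometrically possible, a full 14 mm
    # peritumoral margin of parenchyma surrounds it
    slack <- min(liver_semi) - (r0 * 1.1 + 14)
    offset <- if (slack > 0) runif(3, -1, 1) * min(slack, 4) else c(0, 0, 0)
    tumor_center <- liver_center + offset

    g <- coord_grid(shape, spacing)
    lx <- (g$x - liver_center[1]) / liver_semi[1]
    ly <- (g$y - liver_center[2]) / liver_semi[2]
    lz <- (g$z - liver_center[3]) / liver_semi[3]
    liver_mask <- (lx^2 + ly^2 + lz^2) <= 1

    dx <- g$x - tumor_center[1]
    dy <- g$y - tumor_center[2]
    dz <- g$z - tumor_center[3]
    rho <- sqrt(dx^2 + dy^2 + dz^2)
    theta <- acos(ifelse(rho > 0, dz / pmax(rho, 1e-12), 1))
    phi <- atan2(dy, dx)
    ph <- runif(4, 0, 2 * pi)
    amp <- runif(3, 0.04, 0.09)
    rloc <- r0 * (1 + amp[1] * sin(2 * theta + ph[1]) +
                      amp[2] * cos(3 * phi + ph[2]) * sin(theta) +
                      amp[3] * sin(2 * phi + ph[3]) * sin(theta))
    tumor_mask <- (rho <= rloc) & liver_mask
    abort_if(sum(tumor_mask) < 8, "degenerate tumor rasterization")

    n_vessels <- max(1L, rpois(1, spec$barrier_density))
    vessel_mask <- array(FALSE, shape)
    for (v in seq_len(n_vessels)) {
      start <- liver_center + runif(3, -0.5, 0.5) * liver_semi
      # mix of calibers: some >= 2 mm diameter, some below
      radius <- if (v %% 2 == 1) runif(1, 1.1, 2.2) else runif(1, 0.3, 0.8)
      vessel_mask <- vessel_mask |
        rasterize_tube(shape, spacing, random_walk_tube(start, extent), radius)
    }
    bileduct_mask <- array(FALSE, shape)
    for (b in seq_len(2L)) {
      start <- liver_center + runif(3, -0.4, 0.4) * liver_semi
      bileduct_mask <- bileduct_mask |
        rasterize_tube(shape, spacing, random_walk_tube(start, extent, 10L, 3), 0.45)
    }
    vessel_mask <- vessel_mask & liver_mask & !tumor_mask
    bileduct_mask <- bileduct_mask & liver_mask & !tumor_mask & !vessel_mask

    # --- intensities ------------------------------------------------------
    contrast <- tissue_contrast()
    tissue <- array(1L, shape)                       # background
    tissue[liver_mask] <- 2L
    tissue[tumor_mask] <- 3L
    tissue[vessel_mask] <- 4L
    tissue[bileduct_mask] <- 5L
    noise <- lapply(ct_phases(), function(p) rnorm(prod(shape), sd = spec$noise_sd))
    names(noise) <- ct_phases()

    # peritumoral shell for the class effect (label-independent geometry)
    sqd <- cpp_sq_edt(as.integer(tumor_mask), shape, spacing)
    shell <- array(sqrt(sqd) <= spec$effect_extent_mm, shape) &
      liver_mask & !tumor_mask & !vessel_mask & !bileduct_mask

    speckle <- array(FALSE, shape)
    if (label == 1 && spec$effect_heterogeneity > 0) {
      set.seed(derive_seed(case_seed, "speckle"))
      shell_idx <- which(shell)
      n_sp <- max(1L, round(spec$effect_heterogeneity * length(shell_idx) / 150))
      seeds <- sample(shell_idx, min(n_sp, length(shell_idx)))
      sm <- array(FALSE, shape)
      sm[seeds] <- TRUE
      blob_d <- cpp_sq_edt(as.integer(sm), shape, spacing)
      speckle <- array(sqrt(blob_d) <= 2, shape) & shell
    }

    phases <- lapply(ct_phases(), function(p) {
      vol <- matrix(contrast[, p], ncol = 1)[tissue]
      vol <- array(vol, shape)
      if (label == 1 && p == spec$effect_phase) {
        vol[shell] <- vol[shell] + spec$effect_intensity
        vol[speckle] <- vol[speckle] + 80
      }
      vol <- vol + array(noise[[p]], shape)
      array(as.integer(round(pmin(pmax(vol, -200), 400))), shape)
    })
    names(phases) <- ct_phases()

    structure(
      list(phases = phases, liver_mask = liver_mask, tumor_mask = tumor_mask,
           vessel_mask = vessel_mask, bileduct_mask = bileduct_mask,
           spacing_mm = spacing, mvi_label = as.integer(label),
           case_seed = as.integer(case_seed), spec = spec),
      class = "phantom_case")
  })
}

#' Generate a synthetic cohort with a chronological label table
#'
#' Draws exactly `round(n_patients * prevalence)` MVI-positive cases, assigns
#' each case a chronological index (the order a chronological
#' train/validation versus test split uses), and generates every phantom from
#' a per-case seed derived from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `phantom_cohort` with elements `cases` (list of
#'   [generate_phantom()] results) and `labels` (tibble with `case_id`,
#'   `chrono_index`, `mvi_label`, `case_seed`).
#' @export
generate_cohort <- function(spec) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  n <- spec$n_patients
  n_pos <- round(n * spec$prevalence)
  abort_if(n_pos == 0 || n_pos == n,
           "`prevalence` must yield at least one positive and one negative case")
  labels <- with_seed(derive_seed(spec$seed, "labels"), {
    sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  })
  case_seeds <- vapply(seq_len(n), function(i) derive_seed(spec$seed, "case", i),
                       integer(1))
  cases <- purrr::map(seq_len(n), function(i) {
    generate_phantom(spec, case_seeds[i], labels[i])
  })
  tbl <- tibble::tibble(
    case_id = sprintf("case_%03d", seq_len(n)),
    chrono_index = seq_len(n),
    mvi_label = labels,
    case_seed = case_seeds)
  names(cases) <- tbl$case_id
  structure(list(cases = cases, labels = tbl, spec = spec),
            class = "phantom_cohort")
}

#' @exportS3Method base::print
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels @ %s mm, MVI %d, tumor %d voxels\n",
              paste(dim(x$tumor_mask), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              x$mvi_label, sum(x$tumor_mask)))
  invisible(x)
}

#' @exportS3Method base::print
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases (%d MVI+, %d MVI-)\n",
              nrow(x$labels), sum(x$labels$mvi_label),
              sum(1 - x$labels$mvi_label)))
  invisible(x)
}
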