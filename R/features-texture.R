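# Texture-matrix feature families. The raw matrices (co-occurrences, zones,
# runs, neighbourhood differences, dependences) are accumulated in C++ over
# the 26-neighbourhood / 13 unique 3D directions; the feature formulas are
# evaluated here from the matrices.

# masked gray-level array: levels >= 1 inside mask, 0 outside
masked_levels <- function(image, mask, bin_width) {
  vals <- image[mask]
  lv <- array(0L, dim(image))
  lv[mask] <- discretize(vals, bin_width)
  lv
}

glcm_features_from_counts <- function(counts, ng) {
  feats <- matrix(NA_real_, 24, 0)
  acc <- NULL
  for (d in seq_len(dim(counts)[3])) {
    C <- counts[, , d, drop = TRUE]
    C <- matrix(C, ng, ng)
    s <- sum(C)
    if (s == 0) next
    P <- C / s
    i <- row(P); j <- col(P)
    px <- rowSums(P); py <- colSums(P)
    mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
    sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
    sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
    # diagonal / cross-diagonal marginals
    k_sum <- 2:(2 * ng)
    p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
    k_diff <- 0:(ng - 1)
    p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
    lg <- function(x) ifelse(x > 0, log2(x), 0)
    hxy <- -sum(P * lg(P))
    pxy_prod <- outer(px, py)
    hxy1 <- -sum(P * lg(pxy_prod))
    hxy2 <- -sum(pxy_prod * lg(pxy_prod))
    hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
    da <- sum(k_diff * p_diff)
    # MCC: second largest eigenvalue of Q over the present gray levels
    pres <- which(px > 0)
    if (length(pres) < 2) {
      mcc <- 1
    } else {
      Pp <- P[pres, pres, drop = FALSE]
      pxp <- px[pres]; pyp <- py[pres]
      Q <- matrix(0, length(pres), length(pres))
      for (a in seq_along(pres))
        for (b in seq_along(pres))
          Q[a, b] <- sum(Pp[a, ] * Pp[b, ] / (pxp[a] * pyp))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      mcc <- sqrt(max(ev[2], 0))
    }
    corr <- if (sigx * sigy > 0)
      (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
    imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
    imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
    f <- c(
      Autocorrelation = sum(i * j * P),
      JointAverage = mux,
      ClusterProminence = sum((i + j - mux - muy)^4 * P),
      ClusterShade = sum((i + j - mux - muy)^3 * P),
      ClusterTendency = sum((i + j - mux - muy)^2 * P),
      Contrast = sum((i - j)^2 * P),
      Correlation = corr,
      DifferenceAverage = da,
      DifferenceEntropy = -sum(p_diff * lg(p_diff)),
      DifferenceVariance = sum((k_diff - da)^2 * p_diff),
      JointEnergy = sum(P^2),
      JointEntropy = hxy,
      Imc1 = imc1,
      Imc2 = imc2,
      Idm = sum(P / (1 + (i - j)^2)),
      Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
      Id = sum(P / (1 + abs(i - j))),
      Idn = sum(P / (1 + abs(i - j) / ng)),
      InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
      MaximumProbability = max(P),
      SumAverage = sum(k_sum * p_sum),
      SumEntropy = -sum(p_sum * lg(p_sum)),
      SumSquares = sum((i - mux)^2 * P),
      MCC = mcc)
    acc <- if (is.null(acc)) f else acc + f
    feats <- cbind(feats, f)
  }
  abort_if(is.null(acc), "GLCM undefined: no voxel pairs in any direction")
  out <- acc / ncol(feats)
  names(out) <- paste0("glcm_", names(out))
  out
}

#' Gray level co-occurrence matrix features (24)
#'
#' Symmetric co-occurrences over the 13 unique 3D directions at offset 1,
#' normalized per direction; each feature is the average of its per-direction
#' values.
#'
#' @param image numeric 3D intensity array.
#' @param mask binary 3D mask with at least 2 voxels.
#' @param bin_width discretization bin width.
#' @return named numeric vector of 24 features (`glcm_*`).
#' @export
glcm_features <- function(image, mask, bin_width = 25) {
  mask <- as_mask(mask)
  abort_if(sum(mask) < 2, "GLCM needs at least 2 voxels in the mask")
  lv <- masked_levels(image, mask, bin_width)
  ng <- max(lv)
  counts <- array(cpp_glcm(as.vector(lv), dim(lv), ng), c(ng, ng, 13))
  glcm_features_from_counts(counts, ng)
}

glszm_features_from_zones <- function(zones, ng, n_voxels) {
  nz <- nrow(zones)
  abort_if(nz == 0, "GLSZM undefined: no zones")
  sizes <- sort(unique(zones[, 2]))
  P <- unclass(table(factor(zones[, 1], levels = seq_len(ng)),
                     factor(zones[, 2], levels = sizes)))
  P <- matrix(as.numeric(P), ng, length(sizes))
  iv <- seq_len(ng)
  jv <- sizes
  gi <- rowSums(P)      # zones per gray level
  sj <- colSums(P)      # zones per size
  p <- P / nz
  pi_m <- gi / nz
  pj_m <- sj / nz
  mu_i <- sum(iv * pi_m); mu_j <- sum(jv * pj_m)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  out <- c(
    SmallAreaEmphasis = sum(sweep(P, 2, jv^2, "/")) / nz,
    LargeAreaEmphasis = sum(sweep(P, 2, jv^2, "*")) / nz,
    GrayLevelNonUniformity = sum(gi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nz^2,
    SizeZoneNonUniformity = sum(sj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sj^2) / nz^2,
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = sum((iv - mu_i)^2 * pi_m),
    ZoneVariance = sum((jv - mu_j)^2 * pj_m),
    ZoneEntropy = -sum(p * lg(p)),
    LowGrayLevelZoneEmphasis = sum(sweep(P, 1, iv^2, "/")) / nz,
    HighGrayLevelZoneEmphasis = sum(sweep(P, 1, iv^2, "*")) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / outer(iv^2, jv^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * outer(iv^2, 1 / jv^2)) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * outer(1 / iv^2, jv^2)) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * outer(iv^2, jv^2)) / nz)
  names(out) <- paste0("glszm_", names(out))
  out
}

#' Gray level size zone matrix features (16)
#'
#' Zones are 26-connected components of constant gray level; `P(i, j)` counts
#' zones of level `i` and size `j` voxels.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (`glszm_*`).
#' @export
glszm_features <- function(image, mask, bin_width = 25) {
  mask <- as_mask(mask)
  abort_if(!any(mask), "GLSZM needs a non-empty mask")
  lv <- masked_levels(image, mask, bin_width)
  ng <- max(lv)
  zones <- cpp_zones(as.vector(lv), dim(lv))
  glszm_features_from_zones(zones, ng, sum(mask))
}

glrlm_features_from_counts <- function(counts, ng, maxrun, n_voxels) {
  acc <- NULL
  ndir <- 0L
  for (d in seq_len(dim(counts)[3])) {
    P <- matrix(counts[, , d], ng, maxrun)
    nr <- sum(P)
    if (nr == 0) next
    iv <- seq_len(ng); jv <- seq_len(maxrun)
    gi <- rowSums(P); rj <- colSums(P)
    p <- P / nr
    pi_m <- gi / nr; pj_m <- rj / nr
    mu_i <- sum(iv * pi_m); mu_j <- sum(jv * pj_m)
    lg <- function(x) ifelse(x > 0, log2(x), 0)
    f <- c(
      ShortRunEmphasis = sum(sweep(P, 2, jv^2, "/")) / nr,
      LongRunEmphasis = sum(sweep(P, 2, jv^2, "*")) / nr,
      GrayLevelNonUniformity = sum(gi^2) / nr,
      GrayLevelNonUniformityNormalized = sum(gi^2) / nr^2,
      RunLengthNonUniformity = sum(rj^2) / nr,
      RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
      RunPercentage = nr / n_voxels,
      GrayLevelVariance = sum((iv - mu_i)^2 * pi_m),
      RunVariance = sum((jv - mu_j)^2 * pj_m),
      RunEntropy = -sum(p * lg(p)),
      LowGrayLevelRunEmphasis = sum(sweep(P, 1, iv^2, "/")) / nr,
      HighGrayLevelRunEmphasis = sum(sweep(P, 1, iv^2, "*")) / nr,
      ShortRunLowGrayLevelEmphasis = sum(P / outer(iv^2, jv^2)) / nr,
      ShortRunHighGrayLevelEmphasis = sum(P * outer(iv^2, 1 / jv^2)) / nr,
      LongRunLowGrayLevelEmphasis = sum(P * outer(1 / iv^2, jv^2)) / nr,
      LongRunHighGrayLevelEmphasis = sum(P * outer(iv^2, jv^2)) / nr)
    acc <- if (is.null(acc)) f else acc + f
    ndir <- ndir + 1L
  }
  abort_if(ndir == 0L, "GLRLM undefined: empty mask")
  out <- acc / ndir
  names(out) <- paste0("glrlm_", names(out))
  out
}

#' Gray level run length matrix features (16)
#'
#' Runs are maximal same-level straight segments along each of the 13 unique
#' 3D directions; features are averaged over directions.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (`glrlm_*`).
#' @export
glrlm_features <- function(image, mask, bin_width = 25) {
  mask <- as_mask(mask)
  abort_if(!any(mask), "GLRLM needs a non-empty mask")
  lv <- masked_levels(image, mask, bin_width)
  ng <- max(lv)
  maxrun <- max(dim(lv))
  counts <- array(cpp_glrlm(as.vector(lv), dim(lv), ng), c(ng, maxrun, 13))
  glrlm_features_from_counts(counts, ng, maxrun, sum(mask))
}

ngtdm_features_from_acc <- function(acc, ng) {
  n_i <- acc[, 1]; s_i <- acc[, 2]
  nvp <- sum(n_i)
  abort_if(nvp == 0, "NGTDM undefined: no voxel has an in-mask neighbour")
  p_i <- n_i / nvp
  pres <- which(p_i > 0)
  iv <- seq_len(ng)
  ngp <- length(pres)
  sum_ps <- sum(p_i * s_i)
  # degenerate conventions: features whose defining ratio is 0/0 return 0
  coarseness <- if (sum_ps > 0) 1 / sum_ps else 0
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[pres], p_i[pres]) * outer(iv[pres], iv[pres], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s_i) / nvp)
  } else 0
  den_bus <- sum(abs(outer(iv[pres] * p_i[pres], iv[pres] * p_i[pres], "-")))
  busyness <- if (den_bus > 0) sum_ps / den_bus else 0
  complexity <- if (ngp > 0) {
    pi_p <- p_i[pres]; si_p <- s_i[pres]; ii <- iv[pres]
    num <- outer(pi_p * si_p, pi_p * si_p, "+")
    den <- outer(pi_p, pi_p, "+")
    sum(abs(outer(ii, ii, "-")) * num / den) / nvp
  } else 0
  strength <- if (sum(s_i) > 0) {
    pi_p <- p_i[pres]; ii <- iv[pres]
    sum(outer(pi_p, pi_p, "+") * outer(ii, ii, "-")^2) / sum(s_i)
  } else 0
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

#' Neighbouring gray tone difference matrix features (5)
#'
#' For each gray level the mean absolute difference between voxels of that
#' level and the average of their in-mask 26-neighbourhoods.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features (`ngtdm_*`).
#' @export
ngtdm_features <- function(image, mask, bin_width = 25) {
  mask <- as_mask(mask)
  abort_if(!any(mask), "NGTDM needs a non-empty mask")
  lv <- masked_levels(image, mask, bin_width)
  ng <- max(lv)
  acc <- cpp_ngtdm(as.vector(lv), dim(lv), ng)
  ngtdm_features_from_acc(acc, ng)
}

gldm_features_from_counts <- function(P, ng) {
  nz <- sum(P)
  abort_if(nz == 0, "GLDM undefined: empty mask")
  jv <- seq_len(ncol(P))     # dependence size = dependent neighbours + 1
  iv <- seq_len(ng)
  gi <- rowSums(P); dj <- colSums(P)
  p <- P / nz
  pi_m <- gi / nz; pj_m <- dj / nz
  mu_i <- sum(iv * pi_m); mu_j <- sum(jv * pj_m)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  out <- c(
    SmallDependenceEmphasis = sum(sweep(P, 2, jv^2, "/")) / nz,
    LargeDependenceEmphasis = sum(sweep(P, 2, jv^2, "*")) / nz,
    GrayLevelNonUniformity = sum(gi^2) / nz,
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    GrayLevelVariance = sum((iv - mu_i)^2 * pi_m),
    DependenceVariance = sum((jv - mu_j)^2 * pj_m),
    DependenceEntropy = -sum(p * lg(p)),
    LowGrayLevelEmphasis = sum(sweep(P, 1, iv^2, "/")) / nz,
    HighGrayLevelEmphasis = sum(sweep(P, 1, iv^2, "*")) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / outer(iv^2, jv^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * outer(iv^2, 1 / jv^2)) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / iv^2, jv^2)) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * outer(iv^2, jv^2)) / nz)
  names(out) <- paste0("gldm_", names(out))
  out
}

#' Gray level dependence matrix features (14)
#'
#' A 26-neighbour is dependent on the centre when its gray level equals the
#' centre's (tolerance `alpha = 0`); `P(i, j)` counts voxels of level `i`
#' with dependence size `j` (dependent neighbours + 1).
#'
#' @inheritParams glcm_features
#' @param alpha gray-level tolerance for dependence (default 0).
#' @return named numeric vector of 14 features (`gldm_*`).
#' @export
gldm_features <- function(image, mask, bin_width = 25, alpha = 0) {
  mask <- as_mask(mask)
  abort_if(!any(mask), "GLDM needs a non-empty mask")
  lv <- masked_levels(image, mask, bin_width)
  ng <- max(lv)
  P <- cpp_gldm(as.vector(lv), dim(lv), ng, as.integer(alpha))
  gldm_features_from_counts(P, ng)
}
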