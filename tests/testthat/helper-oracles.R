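# Brute-force reference ("oracle") implementations used to verify the fast
# accumulators. These are written directly from the definitions of the
# texture matrices and of the physical distance expansion, independently of
# the package internals: matrices are built from explicit voxel-pair /
# neighbourhood enumeration, and the ring oracle measures the distance of
# every candidate voxel to every core voxel.

# The canonical 13 unique 3D directions at offset 1 (one representative per
# +/- pair). This set is part of the definition of the direction-averaged
# texture families, not of the implementation under test.
oracle_dirs13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

oracle_dirs26 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(d[rowSums(abs(d)) > 0, , drop = FALSE])
}

# linear index of coordinate rows (column-major), NA when out of bounds
oracle_lin <- function(co, dims) {
  ok <- co[, 1] >= 1 & co[, 1] <= dims[1] &
        co[, 2] >= 1 & co[, 2] <= dims[2] &
        co[, 3] >= 1 & co[, 3] <= dims[3]
  out <- rep(NA_integer_, nrow(co))
  out[ok] <- co[ok, 1] + (co[ok, 2] - 1L) * dims[1] +
    (co[ok, 3] - 1L) * dims[1] * dims[2]
  out
}

# symmetric co-occurrence counts, ng x ng x 13, by enumerating every in-mask
# voxel pair at each offset
oracle_glcm <- function(lv, ng) {
  dims <- dim(lv)
  dirs <- oracle_dirs13()
  co <- which(lv > 0, arr.ind = TRUE)
  out <- array(0, c(ng, ng, 13))
  for (d in seq_len(13)) {
    q <- sweep(co, 2, dirs[d, ], "+")
    qi <- oracle_lin(q, dims)
    ok <- !is.na(qi)
    li <- lv[co[ok, , drop = FALSE]]
    lj <- lv[qi[ok]]
    keep <- lj > 0
    if (!any(keep)) next
    tab <- table(factor(li[keep], levels = seq_len(ng)),
                 factor(lj[keep], levels = seq_len(ng)))
    m <- matrix(as.numeric(tab), ng, ng)
    out[, , d] <- m + t(m)
  }
  out
}

# run-length counts, ng x maxrun x 13, by walking every complete grid line
# in each direction and run-length-encoding its level sequence
oracle_glrlm <- function(lv, ng, maxrun) {
  dims <- dim(lv)
  dirs <- oracle_dirs13()
  out <- array(0, c(ng, maxrun, 13))
  all_co <- which(array(TRUE, dims), arr.ind = TRUE)
  for (d in seq_len(13)) {
    off <- dirs[d, ]
    # line starts: voxels whose predecessor along -off is outside the grid
    prev <- sweep(all_co, 2, off, "-")
    starts <- all_co[is.na(oracle_lin(prev, dims)), , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      p <- starts[s, ]
      seqlv <- integer(0)
      while (!is.na(oracle_lin(matrix(p, 1), dims))) {
        seqlv <- c(seqlv, lv[p[1], p[2], p[3]])
        p <- p + off
      }
      r <- rle(seqlv)
      for (k in seq_along(r$values)) {
        if (r$values[k] > 0)
          out[r$values[k], r$lengths[k], d] <-
            out[r$values[k], r$lengths[k], d] + 1
      }
    }
  }
  out
}

# zones of constant level under 26-connectivity by iterative label-minimum
# propagation; returns a (level, size) matrix, one row per zone
oracle_zone_table <- function(lv) {
  dims <- dim(lv)
  n <- prod(dims)
  all_co <- which(array(TRUE, dims), arr.ind = TRUE)
  dirs <- oracle_dirs26()
  # per-offset neighbour pairs restricted to equal in-mask levels
  pairs <- lapply(seq_len(nrow(dirs)), function(d) {
    qi <- oracle_lin(sweep(all_co, 2, dirs[d, ], "+"), dims)
    p <- which(!is.na(qi) & lv > 0)
    q <- qi[p]
    keep <- lv[q] == lv[p]
    list(p = p[keep], q = q[keep])
  })
  lab <- ifelse(as.vector(lv) > 0, seq_len(n), 0L)
  repeat {
    changed <- FALSE
    for (pr in pairs) {
      if (!length(pr$p)) next
      new <- pmin(lab[pr$p], lab[pr$q])
      if (any(new < lab[pr$p])) {
        lab[pr$p] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  idx <- which(lab > 0)
  sizes <- table(lab[idx])
  levels_of <- as.vector(lv)[as.integer(names(sizes))]
  cbind(level = levels_of, size = as.integer(sizes))
}

# NGTDM accumulators (n_i, s_i) from explicit neighbourhood means
oracle_ngtdm <- function(lv, ng) {
  dims <- dim(lv)
  n <- prod(dims)
  all_co <- which(array(TRUE, dims), arr.ind = TRUE)
  nb_sum <- numeric(n)
  nb_cnt <- integer(n)
  for (d in seq_len(26)) {
    qi <- oracle_lin(sweep(all_co, 2, oracle_dirs26()[d, ], "+"), dims)
    p <- which(!is.na(qi))
    q <- qi[p]
    keep <- lv[q] > 0
    nb_sum[p[keep]] <- nb_sum[p[keep]] + lv[q[keep]]
    nb_cnt[p[keep]] <- nb_cnt[p[keep]] + 1L
  }
  out <- matrix(0, ng, 2)
  idx <- which(as.vector(lv) > 0 & nb_cnt > 0)
  for (i in idx) {
    li <- as.vector(lv)[i]
    out[li, 1] <- out[li, 1] + 1
    out[li, 2] <- out[li, 2] + abs(li - nb_sum[i] / nb_cnt[i])
  }
  out
}

# GLDM counts P(i, j), j = dependent 26-neighbours + 1, columns 1..27
oracle_gldm <- function(lv, ng, alpha = 0) {
  dims <- dim(lv)
  n <- prod(dims)
  all_co <- which(array(TRUE, dims), arr.ind = TRUE)
  dep <- integer(n)
  for (d in seq_len(26)) {
    qi <- oracle_lin(sweep(all_co, 2, oracle_dirs26()[d, ], "+"), dims)
    p <- which(!is.na(qi))
    q <- qi[p]
    keep <- lv[q] > 0 & abs(lv[q] - lv[p]) <= alpha
    dep[p[keep]] <- dep[p[keep]] + 1L
  }
  idx <- which(as.vector(lv) > 0)
  tab <- table(factor(as.vector(lv)[idx], levels = seq_len(ng)),
               factor(dep[idx] + 1L, levels = 1:27))
  matrix(as.numeric(tab), ng, 27)
}

# peritumoral ring by all-pairs physical voxel-centre distances
oracle_ring <- function(core, liver, barrier, spacing, distance_mm) {
  dims <- dim(core)
  co <- which(array(TRUE, dims), arr.ind = TRUE)
  phys <- sweep(co - 1, 2, spacing, "*")
  cp <- phys[which(core), , drop = FALSE]
  cand <- which(!core & liver & !barrier)
  ring <- logical(prod(dims))
  tol <- 1e-9 * max(1, distance_mm)
  for (i in cand) {
    d2 <- (phys[i, 1] - cp[, 1])^2 + (phys[i, 2] - cp[, 2])^2 +
      (phys[i, 3] - cp[, 3])^2
    ring[i] <- sqrt(min(d2)) <= distance_mm + tol
  }
  array(ring, dims)
}

# Mann-Whitney AUC by explicit pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random discretized crop: levels >= 1 inside a random mask, 0 outside.
# Patterns cover constant, binary, few-level and many-level regions and
# mask densities from sparse to full.
oracle_random_crop <- function(max_dim = 16) {
  dims <- sample(4:max_dim, 3, replace = TRUE)
  n <- prod(dims)
  density <- sample(c(0.3, 0.6, 0.9, 1), 1)
  mask <- array(runif(n) <= density, dims)
  if (sum(mask) < 2) mask[seq_len(2)] <- TRUE
  ng <- sample(c(1, 2, 3, 6, 12), 1)
  lv <- array(0L, dims)
  lv[mask] <- sample.int(ng, sum(mask), replace = TRUE)
  lv[which(mask)[1]] <- 1L   # level 1 always present, as after discretization
  ng_eff <- max(lv)
  list(lv = lv, ng = ng_eff, dims = dims, mask = mask)
}
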