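# Feature-selection registry: 15 deterministic selectors over a numeric
# feature matrix and a binary label. Score-based selectors rank by a
# per-feature statistic; the conditional-MI family ranks by greedy forward
# selection on discretized features. Ties always break lexicographically on
# the feature name so rankings are invariant to column order.

#' Available feature-selection methods
#' @return character vector of the 15 selector identifiers.
#' @export
selector_registry <- function() {
  c("t_score", "f_score", "trace_ratio", "chi_square", "gini", "relieff",
    "lasso", "mim", "mifs", "mrmr", "cife", "cmim", "jmi", "disr", "icap")
}

class_stats <- function(x, y) {
  x1 <- x[y == 1, , drop = FALSE]
  x0 <- x[y == 0, , drop = FALSE]
  list(n1 = nrow(x1), n0 = nrow(x0),
       m1 = colMeans(x1), m0 = colMeans(x0),
       v1 = apply(x1, 2, var), v0 = apply(x0, 2, var),
       m = colMeans(x), v = apply(x, 2, var))
}

score_t <- function(x, y) {
  s <- class_stats(x, y)
  den <- sqrt(s$v1 / s$n1 + s$v0 / s$n0)
  ifelse(den > 0, abs(s$m1 - s$m0) / den,
         ifelse(s$m1 != s$m0, Inf, 0))
}

# Fisher score: between-class scatter over within-class scatter, per feature
score_fisher <- function(x, y) {
  s <- class_stats(x, y)
  sb <- s$n1 * (s$m1 - s$m)^2 + s$n0 * (s$m0 - s$m)^2
  sw <- s$n1 * s$v1 * (s$n1 - 1) / s$n1 + s$n0 * s$v0 * (s$n0 - 1) / s$n0
  ifelse(sw > 0, sb / sw, ifelse(sb > 0, Inf, 0))
}

# iterative trace-ratio selection (Nie et al. style): maximize
# tr(selected between-scatter) / tr(selected within-scatter)
rank_trace_ratio <- function(x, y, k) {
  s <- class_stats(x, y)
  b <- s$n1 * (s$m1 - s$m)^2 + s$n0 * (s$m0 - s$m)^2
  w <- s$n1 * s$v1 * (s$n1 - 1) / s$n1 + s$n0 * s$v0 * (s$n0 - 1) / s$n0
  w <- pmax(w, 1e-12)
  nm <- colnames(x)
  sel <- nm[order_scores(b / w, nm)][seq_len(k)]
  for (iter in 1:50) {
    lambda <- sum(b[sel]) / sum(w[sel])
    score <- b - lambda * w
    new_sel <- nm[order_scores(score, nm)][seq_len(k)]
    if (identical(sort(new_sel), sort(sel))) { sel <- new_sel; break }
    sel <- new_sel
  }
  # return the selected k first (by final score), then the rest
  lambda <- sum(b[sel]) / sum(w[sel])
  score <- b - lambda * w
  nm[order_scores(score, nm)]
}

score_chisq <- function(x, y) {
  apply(x, 2, function(v) {
    br <- unique(quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
    g <- cut(v, breaks = c(-Inf, br, Inf), labels = FALSE)
    if (length(unique(g)) < 2) return(0)
    suppressWarnings(unname(stats::chisq.test(table(g, y))$statistic))
  })
}

# largest Gini impurity decrease over candidate single splits
score_gini <- function(x, y) {
  n <- length(y)
  p_root <- mean(y)
  g_root <- 2 * p_root * (1 - p_root)
  apply(x, 2, function(v) {
    cand <- unique(quantile(v, seq(0.1, 0.9, by = 0.1), names = FALSE))
    best <- 0
    for (thr in cand) {
      left <- v <= thr
      nl <- sum(left); nr <- n - nl
      if (nl == 0 || nr == 0) next
      pl <- mean(y[left]); pr <- mean(y[!left])
      dec <- g_root - (nl / n) * 2 * pl * (1 - pl) - (nr / n) * 2 * pr * (1 - pr)
      if (dec > best) best <- dec
    }
    best
  })
}

score_relieff <- function(x, y, k_neighbors = 5) {
  rng <- apply(x, 2, function(v) max(v) - min(v))
  rng[rng == 0] <- 1
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  d <- as.matrix(stats::dist(xs))
  n <- nrow(x)
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(diff))
    if (kh == 0 || km == 0) next
    hits <- same[order(d[i, same])][seq_len(kh)]
    misses <- diff[order(d[i, diff])][seq_len(km)]
    w <- w - colMeans(abs(xs[hits, , drop = FALSE] -
                            matrix(xs[i, ], kh, ncol(x), byrow = TRUE))) / n +
             colMeans(abs(xs[misses, , drop = FALSE] -
                            matrix(xs[i, ], km, ncol(x), byrow = TRUE))) / n
  }
  w
}

# rank by order of entry into the lasso regularization path
rank_lasso <- function(x, y) {
  nm <- colnames(x)
  fit <- glmnet::glmnet(as.matrix(x), y, family = "binomial",
                        standardize = TRUE, nlambda = 100)
  beta <- as.matrix(fit$beta)
  entry <- apply(beta, 1, function(b) {
    nz <- which(b != 0)
    if (length(nz)) nz[1] else Inf
  })
  final <- abs(beta[, ncol(beta)])
  nm[order(entry, -final, nm)]
}

# --- discretized mutual-information machinery -------------------------------

mi_bin <- function(v, bins = 4L) {
  r <- rank(v, ties.method = "average")
  as.integer(ceiling(r / length(v) * bins))
}

entropy_tab <- function(tab) {
  p <- tab / sum(tab)
  p <- p[p > 0]
  -sum(p * log(p))
}

mutual_info <- function(a, b) {
  entropy_tab(table(a)) + entropy_tab(table(b)) - entropy_tab(table(a, b))
}

cond_mutual_info <- function(a, b, z) {
  # I(A;B|Z) = H(A,Z) + H(B,Z) - H(A,B,Z) - H(Z)
  entropy_tab(table(a, z)) + entropy_tab(table(b, z)) -
    entropy_tab(table(a, b, z)) - entropy_tab(table(z))
}

# greedy forward selection for the conditional-MI criteria
rank_mi_family <- function(x, y, k, criterion, bins = 4L) {
  nm <- colnames(x)
  xb <- apply(x, 2, mi_bin, bins = bins)
  rel <- vapply(seq_len(ncol(xb)), function(j) mutual_info(xb[, j], y), numeric(1))
  names(rel) <- nm
  if (criterion == "mim") return(nm[order_scores(rel, nm)])
  selected <- character(0)
  remaining <- nm
  while (length(selected) < min(k, ncol(x)) && length(remaining) > 0) {
    score <- vapply(remaining, function(f) {
      j <- match(f, nm)
      if (length(selected) == 0) return(rel[f])
      red <- vapply(selected, function(s) {
        sj <- match(s, nm)
        mi_xs <- mutual_info(xb[, j], xb[, sj])
        cmi <- cond_mutual_info(xb[, j], xb[, sj], y)
        switch(criterion,
          mifs = mi_xs,
          mrmr = mi_xs,
          cife = mi_xs - cmi,
          icap = max(0, mi_xs - cmi),
          jmi  = mi_xs - cmi,
          cmim = NA_real_,
          disr = NA_real_)
      }, numeric(1))
      switch(criterion,
        mifs = rel[f] - sum(red),
        mrmr = rel[f] - mean(red),
        cife = rel[f] - sum(red),
        icap = rel[f] - sum(red),
        jmi  = rel[f] - mean(red),
        cmim = min(vapply(selected, function(s) {
          sj <- match(s, nm)
          cond_mutual_info(xb[, j], y, xb[, sj])
        }, numeric(1))),
        disr = sum(vapply(selected, function(s) {
          sj <- match(s, nm)
          joint <- interaction(xb[, j], xb[, sj], drop = TRUE)
          ji <- mutual_info(joint, y)
          hj <- entropy_tab(table(joint, y))
          if (hj > 0) ji / hj else 0
        }, numeric(1))))
    }, numeric(1))
    pick <- remaining[order_scores(score, remaining)][1]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  c(selected, remaining[order_scores(rel[remaining], remaining)])
}

order_scores <- function(score, nm) {
  score[is.na(score)] <- -Inf
  score[score == Inf] <- .Machine$double.xmax
  order(-score, nm)
}

#' Rank and select features
#'
#' Applies one of the 15 registered selection methods and returns the `k`
#' top-ranked feature names. All methods are deterministic; rankings are
#' invariant to feature column order (ties break on the feature name).
#'
#' @param x numeric feature matrix or data frame (columns named).
#' @param y binary labels (0/1), both classes present.
#' @param selector one of [selector_registry()].
#' @param k number of features to return.
#' @return character vector of `k` feature names, ranked best first.
#' @export
select_features <- function(x, y, selector = "t_score", k = 10) {
  selector <- match.arg(selector, selector_registry())
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  abort_if(is.null(colnames(x)), "`x` must have column names")
  y <- as.integer(y)
  abort_if(length(unique(y)) < 2, "both classes must be present in `y`")
  abort_if(k > ncol(x), "`k` exceeds the number of features")
  nm <- colnames(x)
  ranked <- switch(selector,
    t_score = nm[order_scores(score_t(x, y), nm)],
    f_score = nm[order_scores(score_fisher(x, y), nm)],
    trace_ratio = rank_trace_ratio(x, y, k),
    chi_square = nm[order_scores(score_chisq(x, y), nm)],
    gini = nm[order_scores(score_gini(x, y), nm)],
    relieff = nm[order_scores(score_relieff(x, y), nm)],
    lasso = rank_lasso(x, y),
    rank_mi_family(x, y, k, selector))
  ranked[seq_len(k)]
}
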