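# Independent oracles, deliberately written without calling the package's
# implementation paths.

# PCA by eigendecomposition of the covariance matrix of the centered data
eigen_pca_oracle <- function(x) {
  x <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  list(scores = x %*% ev$vectors, values = ev$values, vectors = ev$vectors)
}

# exhaustive Ward.D2 agglomeration: at each step merge the pair minimizing
# d(A, B) = sqrt(2 |A| |B| / (|A| + |B|)) * ||mean_A - mean_B||
ward_bruteforce <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  active <- seq_along(clusters)
  merges <- list()
  cluster_id <- -seq_len(nrow(x))   # hclust convention: leaves negative
  repeat {
    if (length(active) < 2) break
    best <- NULL
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        ia <- clusters[[active[a]]]; ib <- clusters[[active[b]]]
        ma <- colMeans(x[ia, , drop = FALSE])
        mb <- colMeans(x[ib, , drop = FALSE])
        d <- sqrt(2 * length(ia) * length(ib) / (length(ia) + length(ib))) *
          sqrt(sum((ma - mb)^2))
        if (is.null(best) || d < best$d) best <- list(a = a, b = b, d = d)
      }
    }
    ia <- active[best$a]; ib <- active[best$b]
    merges[[length(merges) + 1L]] <- list(
      members = sort(c(clusters[[ia]], clusters[[ib]])), height = best$d)
    clusters[[ia]] <- c(clusters[[ia]], clusters[[ib]])
    active <- setdiff(active, ib)
  }
  merges
}

# members of every internal node of an hclust tree, in merge order
hclust_merge_members <- function(hc) {
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(j) if (j < 0) -j else out[[j]]
    out[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  out
}

# brute-force confusion counts by explicit pixel loop
confusion_loop_oracle <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i] && !truth[i]) fp <- fp + 1L
    else if (!pred[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# sort-based percentile with linear interpolation (type-7 convention),
# written out explicitly
percentile_sort_oracle <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
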