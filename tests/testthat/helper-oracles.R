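# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops and closed forms only.

# per-pixel RGB mean by explicit loops
gray_ref <- function(rgb) {
  s <- dim(rgb)[1]
  out <- matrix(0, s, s)
  for (i in seq_len(s)) for (j in seq_len(s))
    out[i, j] <- (rgb[i, j, 1] + rgb[i, j, 2] + rgb[i, j, 3]) / 3
  out
}

# direct bilinear formula at each output pixel center (center-aligned grids,
# border replication)
bilinear_resize_ref <- function(px, new_side) {
  s <- nrow(px)
  out <- matrix(0, new_side, new_side)
  for (i in seq_len(new_side)) for (j in seq_len(new_side)) {
    sr <- (i - 0.5) * s / new_side - 0.5
    sc <- (j - 0.5) * s / new_side - 0.5
    sr <- min(max(sr, 0), s - 1); sc <- min(max(sc, 0), s - 1)
    i0 <- floor(sr); j0 <- floor(sc)
    fr <- sr - i0; fc <- sc - j0
    g <- function(a, b) px[min(a, s - 1) + 1, min(b, s - 1) + 1]
    out[i, j] <- (1 - fr) * ((1 - fc) * g(i0, j0) + fc * g(i0, j0 + 1)) +
      fr * ((1 - fc) * g(i0 + 1, j0) + fc * g(i0 + 1, j0 + 1))
  }
  out
}

# exact 90-degree counterclockwise rotation as an index permutation
rot90_ccw_ref <- function(px) {
  s <- nrow(px)
  out <- matrix(0, s, s)
  for (i in seq_len(s)) for (j in seq_len(s))
    out[s + 1 - j, i] <- px[i, j]
  out
}

# brute-force incircle pixel count (half-integer centers, dist < r + 0.5)
incircle_count_ref <- function(side, r) {
  n <- 0L
  for (i in seq_len(side)) for (j in seq_len(side)) {
    d <- sqrt((i - 0.5 - side / 2)^2 + (j - 0.5 - side / 2)^2)
    if (d < r + 0.5) n <- n + 1L
  }
  n
}

# direct evaluation of the driven leaky state update
eq1_ref <- function(x, u, W, Win, alpha) {
  (1 - alpha) * x + alpha * tanh(Win %*% matrix(c(1, u)) + W %*% matrix(x))[, 1]
}

# direct evaluation of the generative leaky update (no input, no bias)
eq2_ref <- function(x, W, alpha) {
  (1 - alpha) * x + alpha * tanh(W %*% matrix(x))[, 1]
}

# closed-form ridge solution with an explicit matrix inverse
ridge_ref <- function(X, Y, beta) {
  A <- X %*% t(X) + beta * diag(nrow(X))
  Y %*% t(X) %*% solve(A)
}

# textbook one-vs-rest metrics from a K x K count matrix
metrics_ref <- function(counts) {
  K <- nrow(counts); n <- sum(counts)
  out <- data.frame(PRC = numeric(K), REC = numeric(K), SPC = numeric(K),
                    F1 = numeric(K))
  for (c in seq_len(K)) {
    tp <- counts[c, c]
    fp <- sum(counts[, c]) - tp
    fn <- sum(counts[c, ]) - tp
    tn <- n - tp - fp - fn
    out$PRC[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    out$REC[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    out$SPC[c] <- if (tn + fp == 0) 0 else tn / (tn + fp)
    out$F1[c] <- if (out$PRC[c] + out$REC[c] == 0) 0 else
      2 * out$PRC[c] * out$REC[c] / (out$PRC[c] + out$REC[c])
  }
  out$ACC <- sum(diag(counts)) / n
  out
}

# Gini impurity decrease recomputed from scratch for auditing split search
gini_decrease_ref <- function(labels, left, K) {
  g <- function(l) {
    p <- tabulate(l, K) / length(l)
    1 - sum(p^2)
  }
  if (sum(left) == 0 || sum(!left) == 0) return(-Inf)
  g(labels) - (sum(left) * g(labels[left]) +
                 sum(!left) * g(labels[!left])) / length(labels)
}

# independent recursive tree walk
route_ref <- function(tree, v) {
  if (tree$leaf) return(tree$prob)
  if (v[tree$p1] - v[tree$p2] <= tree$theta) route_ref(tree$left, v)
  else route_ref(tree$right, v)
}

# nearest-centroid classifier on raw pixels
centroid_classify_ref <- function(train_X, train_y, test_X) {
  classes <- sort(unique(train_y))
  centroids <- t(vapply(classes, function(cl)
    colMeans(train_X[train_y == cl, , drop = FALSE]),
    numeric(ncol(train_X))))
  apply(test_X, 1, function(v)
    classes[which.min(colSums((t(centroids) - v)^2))])
}

# a smooth reproducible test patch: two gaussian blobs on a gradient
smooth_patch <- function(side = 20, range = "unit") {
  g <- expand.grid(row = seq_len(side) - 0.5, col = seq_len(side) - 0.5)
  c0 <- side / 2
  v <- 0.5 + 0.25 * exp(-((g$row - c0)^2 + (g$col - c0)^2) / (0.1 * side^2)) -
    0.2 * exp(-((g$row - 0.7 * side)^2 + (g$col - 0.35 * side)^2) /
                (0.05 * side^2)) +
    0.1 * (g$col - c0) / side
  px <- matrix(pmin(pmax(v, 0), 1), side, side)
  if (range == "signed") px <- 2 * px - 1
  gray_patch(px, label = 1L, patch_id = "smooth", range = range)
}

# small cached synthetic dataset resized to the working side
tiny_dataset <- local({
  cache <- new.env()
  function(counts = c(10L, 10L, 10L), delta = 1.5, seed = 42L, side = 20L,
           background = TRUE, n_folds = 3L) {
    key <- paste(c(counts, delta, seed, side, background, n_folds),
                 collapse = "_")
    if (is.null(cache[[key]])) {
      ds <- generate_dataset(counts = counts, delta = delta, seed = seed,
                             background = background, n_folds = n_folds)
      ds$patches <- lapply(ds$patches, resize_patch, new_side = side)
      ds$side <- side
      cache[[key]] <- ds
    }
    cache[[key]]
  }
})
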