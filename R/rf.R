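#' Gini impurity of a class histogram
#'
#' `1 - sum(p_c^2)` with `p_c` the class proportions; zero iff the node is
#' pure, at most `1 - 1/K` for a uniform K-class mixture.
#'
#' @param histogram nonnegative class counts (not all zero).
#' @return Impurity in `[0, 1 - 1/K]`.
#' @export
gini_impurity <- function(histogram) {
  if (any(histogram < 0) || sum(histogram) == 0)
    stop("histogram must be nonnegative with positive total", call. = FALSE)
  p <- histogram / sum(histogram)
  1 - sum(p^2)
}

#' Random-forest hyper-parameters
#'
#' Defaults follow the bespoke patch-classification forest: at every internal
#' node 100 random pixel pairs are each tested against 20 random thresholds
#' (2000 candidate tests per node), each candidate is scored on a random
#' subsample of at most 200 node samples, trees grow to `max_depth` or until
#' fewer than 100 samples reach a node, and every tree sees all training
#' samples (no bagging).
#'
#' @param forest_size number of trees.
#' @param max_depth maximum tree depth (root at depth 0).
#' @param n_split_functions random pixel pairs per node.
#' @param n_thresholds random thresholds per pixel pair.
#' @param n_eval_samples subsample size for scoring candidates.
#' @param min_node_size below this node size a leaf is made.
#' @return An object of class `rf_hyper`.
#' @export
rf_hyper <- function(forest_size = 16L, max_depth = 8L,
                     n_split_functions = 100L, n_thresholds = 20L,
                     n_eval_samples = 200L, min_node_size = 100L) {
  stopifnot(forest_size >= 1, max_depth >= 0, n_split_functions >= 1,
            n_thresholds >= 1, n_eval_samples >= 1, min_node_size >= 1)
  structure(list(forest_size = as.integer(forest_size),
                 max_depth = as.integer(max_depth),
                 n_split_functions = as.integer(n_split_functions),
                 n_thresholds = as.integer(n_thresholds),
                 n_eval_samples = as.integer(n_eval_samples),
                 min_node_size = as.integer(min_node_size)),
            class = "rf_hyper")
}

#' Sample candidate pixel-pair split functions
#'
#' Each split function compares the intensity difference of two distinct
#' pixel locations to a threshold: `I(p1) - I(p2) <= theta` routes a sample
#' left. Thresholds are drawn uniformly between the minimum and maximum
#' difference observed on the evaluation subsample, so every pair yields
#' candidates that can actually separate it.
#'
#' @param n_features number of pixels per patch (`side^2`).
#' @param eval_data numeric matrix (subsample rows x features) used to bound
#'   the thresholds.
#' @param n_split_functions,n_thresholds candidate counts (their product is
#'   the number of tests per node).
#' @return A data.frame with columns `p1`, `p2` (linear pixel indices) and
#'   `theta`, one row per candidate, in sampling order.
#' @export
sample_candidate_splits <- function(n_features, eval_data,
                                    n_split_functions = 100L,
                                    n_thresholds = 20L) {
  stopifnot(nrow(eval_data) >= 1, n_features >= 2)
  pairs <- t(vapply(seq_len(n_split_functions),
                    function(i) sample.int(n_features, 2L), integer(2)))
  out <- vector("list", n_split_functions)
  for (j in seq_len(n_split_functions)) {
    d <- eval_data[, pairs[j, 1]] - eval_data[, pairs[j, 2]]
    out[[j]] <- data.frame(p1 = pairs[j, 1], p2 = pairs[j, 2],
                           theta = stats::runif(n_thresholds, min(d), max(d)))
  }
  do.call(rbind, out)
}

# Gini impurity decrease of a candidate on labels split by `left`.
.gini_decrease <- function(labels, left, K) {
  nl <- sum(left); nr <- length(left) - nl
  if (nl == 0 || nr == 0) return(-Inf)
  n <- length(left)
  gl <- gini_impurity(tabulate(labels[left], K))
  gr <- gini_impurity(tabulate(labels[!left], K))
  gini_impurity(tabulate(labels, K)) - (nl * gl + nr * gr) / n
}

#' Select the best candidate split at a node
#'
#' Candidates are scored by Gini-impurity decrease on a random subsample of
#' at most `n_eval_samples` node samples; the maximizing candidate (ties to
#' the first in sampling order) is then applied to the full node data. When
#' no candidate separates the subsample, `NULL` is returned and the node
#' becomes a leaf.
#'
#' @param data node feature matrix (rows = samples).
#' @param labels integer class labels (1..K) of the node samples.
#' @param K number of classes.
#' @param hyper an [rf_hyper()].
#' @param detail also return every candidate with its subsample score and
#'   the evaluation subsample indices (for auditing the search).
#' @return `NULL`, or a list with `p1`, `p2`, `theta`, `decrease` and the
#'   logical full-data routing `left` (plus `candidates` and `eval_idx` when
#'   `detail = TRUE`).
#' @export
best_split <- function(data, labels, K, hyper, detail = FALSE) {
  n <- nrow(data)
  eval_idx <- if (n > hyper$n_eval_samples)
    sample.int(n, hyper$n_eval_samples) else seq_len(n)
  eval_data <- data[eval_idx, , drop = FALSE]
  eval_labels <- labels[eval_idx]
  cand <- sample_candidate_splits(ncol(data), eval_data,
                                  hyper$n_split_functions, hyper$n_thresholds)
  dec <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    d <- eval_data[, cand$p1[i]] - eval_data[, cand$p2[i]]
    dec[i] <- .gini_decrease(eval_labels, d <= cand$theta[i], K)
  }
  if (!any(dec > 0)) return(NULL)
  i <- which.max(dec)   # ties resolved to the first candidate in order
  left <- (data[, cand$p1[i]] - data[, cand$p2[i]]) <= cand$theta[i]
  if (all(left) || !any(left)) return(NULL)  # degenerate on the full node
  out <- list(p1 = cand$p1[i], p2 = cand$p2[i], theta = cand$theta[i],
              decrease = dec[i], left = left)
  if (detail) {
    cand$decrease <- dec
    out$candidates <- cand
    out$eval_idx <- eval_idx
  }
  out
}

#' Grow a single decision tree
#'
#' Recursive growth with two stopping rules: a leaf is made when the maximum
#' depth is reached or when fewer than `min_node_size` samples arrive at the
#' node (or when no candidate split separates the node). Leaves store the
#' normalized class histogram of the arriving samples.
#'
#' @inheritParams best_split
#' @param depth current depth (root = 0); internal.
#' @return A nested list: `list(leaf = TRUE, prob = ...)` or
#'   `list(leaf = FALSE, p1, p2, theta, left, right)`.
#' @export
grow_tree <- function(data, labels, K, hyper, depth = 0L) {
  stopifnot(nrow(data) >= 1)
  make_leaf <- function() {
    h <- tabulate(labels, K)
    list(leaf = TRUE, prob = h / sum(h), n = nrow(data))
  }
  if (depth >= hyper$max_depth || nrow(data) < hyper$min_node_size)
    return(make_leaf())
  sp <- best_split(data, labels, K, hyper)
  if (is.null(sp)) return(make_leaf())
  list(leaf = FALSE, p1 = sp$p1, p2 = sp$p2, theta = sp$theta,
       left = grow_tree(data[sp$left, , drop = FALSE], labels[sp$left],
                        K, hyper, depth + 1L),
       right = grow_tree(data[!sp$left, , drop = FALSE], labels[!sp$left],
                         K, hyper, depth + 1L))
}

#' Train a classification forest of pixel-pair trees
#'
#' Every tree is trained on all available samples (no bagging); the only
#' randomness is in the per-node candidate sampling, so trees decorrelate
#' through the split search alone.
#'
#' @param data feature matrix (rows = samples, columns = pixels in
#'   column-major patch order) or a list of `"unit"`-range [gray_patch()]
#'   objects (features are then the flattened pixels).
#' @param labels integer labels in `1..K`; taken from the patches when
#'   `data` is a patch list.
#' @param K number of classes (default `max(labels)`).
#' @param hyper an [rf_hyper()].
#' @param seed RNG seed for the split sampling.
#' @return An object of class `rf_forest`.
#' @export
train_forest <- function(data, labels = NULL, K = NULL, hyper = rf_hyper(),
                         seed = 1L) {
  if (is.list(data) && inherits(data[[1]], "gray_patch")) {
    labels <- vapply(data, `[[`, 0L, "label")
    data <- t(vapply(data, function(p) as.numeric(p$pixels),
                     numeric(data[[1]]$side^2)))
  }
  stopifnot(is.matrix(data), length(labels) == nrow(data), !anyNA(labels))
  if (is.null(K)) K <- max(labels)
  trees <- withr::with_seed(seed, {
    lapply(seq_len(hyper$forest_size), function(i)
      grow_tree(data, labels, K, hyper))
  })
  structure(list(trees = trees, K = K, n_features = ncol(data),
                 hyper = hyper, seed = seed),
            class = "rf_forest")
}

#' @export
print.rf_forest <- function(x, ...) {
  cat(sprintf("<rf_forest> %d trees, max depth %d, %d classes, %d features\n",
              length(x$trees), x$hyper$max_depth, x$K, x$n_features))
  invisible(x)
}

.route <- function(tree, v) {
  while (!tree$leaf)
    tree <- if (v[tree$p1] - v[tree$p2] <= tree$theta) tree$left else tree$right
  tree$prob
}

#' Forest prediction by averaged leaf histograms
#'
#' Each patch is routed through every tree; the per-tree leaf histograms are
#' averaged into a class probability distribution and the winner is the
#' argmax (ties to the smallest class index).
#'
#' @param forest a trained [train_forest()].
#' @param patch a `"unit"`-range [gray_patch()], a feature vector, or a
#'   feature matrix (rows = samples).
#' @return A list with `prob` (distribution, or `n x K` matrix) and `class`
#'   (winner id(s)).
#' @export
predict_forest <- function(forest, patch) {
  stopifnot(inherits(forest, "rf_forest"))
  if (length(forest$trees) == 0) stop("forest is untrained", call. = FALSE)
  if (inherits(patch, "gray_patch")) patch <- as.numeric(patch$pixels)
  if (is.matrix(patch)) {
    res <- t(apply(patch, 1, function(v)
      rowMeans(vapply(forest$trees, .route, numeric(forest$K), v = v))))
    return(list(prob = res, class = apply(res, 1, which.max)))
  }
  if (length(patch) != forest$n_features)
    stop("patch has ", length(patch), " features, forest expects ",
         forest$n_features, call. = FALSE)
  prob <- rowMeans(vapply(forest$trees, .route, numeric(forest$K), v = patch))
  list(prob = prob, class = which.max(prob))
}

#' Rotation augmentation for conventional (non-temporal) classifiers
#'
#' Replicates each patch at rotation angles `k * max(delta_phi, 1)` for
#' `k = 0 .. floor(360 / max(delta_phi, 1)) - 1`, each rotation an
#' independently labeled training sample. This is the conventional way to
#' give a static classifier approximate rotation invariance, matched in
#' budget to the temporal rotation stream.
#'
#' @param patches list of `"unit"`-range [gray_patch()] objects.
#' @param delta_phi skip parameter; `0` yields all 360 one-degree rotations.
#' @return List of rotated `gray_patch` copies (originals first).
#' @export
augment_rotations <- function(patches, delta_phi = 0L) {
  if (inherits(patches, "gray_patch")) patches <- list(patches)
  step <- max(delta_phi, 1L)
  angles <- seq(0L, by = step, length.out = floor(360 / step))
  out <- vector("list", length(patches) * length(angles))
  k <- 0L
  for (a in angles) for (p in patches) {
    k <- k + 1L
    out[[k]] <- rotate_patch(p, a)
  }
  out
}
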