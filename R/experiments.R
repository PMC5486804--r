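#' Cross-validated evaluation of an ESN or RF configuration
#'
#' Runs `n_repeats` independent `n_folds`-fold cross-validations on the
#' training split of a dataset. Per repeat the fold assignment is freshly
#' randomized (stratified by class and source patch) and per fold the
#' classifier is retrained from scratch — for the ESN with a fresh reservoir
#' seeded deterministically from `(seed, repeat, fold)`. The summary is the
#' mean and standard deviation of the weighted accuracy across repeats.
#'
#' @param dataset a [generate_dataset()] result (or any `cell_dataset`).
#' @param classifier `"esn"` or `"rf"`.
#' @param config configuration list. ESN keys: `N`, `rho`, `alpha`,
#'   `delta_phi`, `connectivity`, `input_scale`, `beta`, `steps_per_image`,
#'   `trim_fraction`, `gap_range` (missing keys fall back to [esn_defaults()]
#'   and standard values). RF keys: `forest_size`, `max_depth`, `delta_phi`
#'   (rotation-augmentation of the training folds) plus [rf_hyper()] fields.
#' @param side working patch side (native patches are resized to it).
#' @param n_folds,n_repeats cross-validation shape.
#' @param seed master seed.
#' @param use_split which manifest split to cross-validate (`"train"` by
#'   default; `"all"` uses every patch).
#' @return An object of class `run_record`: `config`, `per_fold`
#'   (data.frame `repeat_`, `fold`, `n_test`, `acc`), `per_repeat` (weighted
#'   accuracy per repeat), `mean_acc`, `sd_acc`, `metrics` (pooled
#'   [class_metrics()] over all held-out predictions of the last repeat).
#' @export
run_cv <- function(dataset, classifier = c("esn", "rf"), config = list(),
                   side = 20L, n_folds = 10L, n_repeats = 5L, seed = 1L,
                   use_split = c("train", "all")) {
  classifier <- match.arg(classifier)
  use_split <- match.arg(use_split)
  man <- dataset$manifest
  keep <- if (use_split == "all") seq_len(nrow(man)) else
    which(man$split == "train")
  if (length(keep) < n_folds) stop("too few patches for ", n_folds, " folds",
                                   call. = FALSE)
  patches <- lapply(dataset$patches[keep], resize_patch, new_side = side)
  labels <- man$label[keep]
  source_id <- man$source_id[keep]
  classes <- sort(unique(labels))
  K <- max(classes)

  per_fold <- NULL; per_repeat <- numeric(n_repeats); last_rep <- NULL
  for (r in seq_len(n_repeats)) {
    fold <- withr::with_seed(.derive_seed(seed, r, 0L),
                             .stratified_folds(labels, source_id, n_folds))
    truth <- integer(0); pred <- integer(0)
    for (f in seq_len(n_folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      fseed <- .derive_seed(seed, r, f)
      p <- .fit_predict(classifier, config, patches[tr], patches[te],
                        K, fseed)
      present <- sort(unique(labels[te]))
      if (!setequal(present, classes))
        warning("fold ", f, " (repeat ", r, ") is missing class(es) ",
                paste(setdiff(classes, present), collapse = ", "),
                call. = FALSE)
      acc <- mean(p == labels[te])
      per_fold <- rbind(per_fold,
                        data.frame(repeat_ = r, fold = f,
                                   n_test = length(te), acc = acc))
      truth <- c(truth, labels[te]); pred <- c(pred, p)
    }
    per_repeat[r] <- mean(pred == truth)   # weighted ACC over all held-out
    last_rep <- list(truth = truth, pred = pred)
  }
  structure(
    list(classifier = classifier, config = config,
         per_fold = per_fold, per_repeat = per_repeat,
         mean_acc = mean(per_repeat),
         sd_acc = if (n_repeats > 1) stats::sd(per_repeat) else NA_real_,
         metrics = class_metrics(confusion(last_rep$truth, last_rep$pred, K)),
         n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s, %d-fold CV x %d: ACC = %.4f (SD %.4f)\n",
              x$classifier, x$n_folds, x$n_repeats, x$mean_acc, x$sd_acc))
  invisible(x)
}

.derive_seed <- function(master, r, f) {
  (as.integer(master) * 10007L + r * 101L + f) %% 2147483647L
}

# stratified fold assignment; variants of one source patch share a fold
.stratified_folds <- function(labels, source_id, n_folds) {
  src <- unique(source_id)
  src_label <- labels[match(src, source_id)]
  src_fold <- stats::setNames(integer(length(src)), src)
  for (cl in unique(src_label)) {
    s <- sample(src[src_label == cl])
    src_fold[s] <- rep_len(sample(n_folds), length(s))
  }
  unname(src_fold[source_id])
}

.fit_predict <- function(classifier, config, train_patches, test_patches,
                         K, seed) {
  cfg <- function(key, default) if (!is.null(config[[key]])) config[[key]]
  else default
  if (classifier == "esn") {
    delta_phi <- cfg("delta_phi", 0L)
    def <- esn_defaults(delta_phi)
    params <- reservoir_params(
      N = cfg("N", 200L), rho = cfg("rho", def$rho),
      alpha = cfg("alpha", def$alpha),
      connectivity = cfg("connectivity", 0.3),
      input_scale = cfg("input_scale", 1), seed = seed)
    model <- esn_fit(train_patches, params, delta_phi = delta_phi,
                     steps_per_image = cfg("steps_per_image", 360L),
                     beta = cfg("beta", 1e-2),
                     trim_fraction = cfg("trim_fraction", 0.05),
                     gap_range = cfg("gap_range", c(50L, 100L)),
                     seed = seed)
    predict(model, test_patches)
  } else {
    delta_phi <- cfg("delta_phi", 0L)
    hyper <- rf_hyper(forest_size = cfg("forest_size", 16L),
                      max_depth = cfg("max_depth", 8L),
                      n_split_functions = cfg("n_split_functions", 100L),
                      n_thresholds = cfg("n_thresholds", 20L),
                      n_eval_samples = cfg("n_eval_samples", 200L),
                      min_node_size = cfg("min_node_size", 100L))
    aug <- withr::with_seed(seed, augment_rotations(train_patches, delta_phi))
    forest <- train_forest(aug, K = K, hyper = hyper, seed = seed)
    vapply(test_patches, function(p) predict_forest(forest, p)$class, 0L)
  }
}

#' Grid search over forest size and tree depth
#'
#' Evaluates every `(forest_size, max_depth)` cell under the same
#' cross-validation protocol and returns the grid table plus the per-cell
#' run records.
#'
#' @inheritParams run_cv
#' @param sizes,depths grid values (defaults give the 16-cell reference grid).
#' @param config shared RF configuration (e.g. `delta_phi`,
#'   `min_node_size`); `forest_size`/`max_depth` are overridden per cell.
#' @return List with `grid` (data.frame `forest_size`, `max_depth`,
#'   `mean_acc`, `sd_acc`) and `records` (list of [run_cv()] results).
#' @export
run_rf_grid <- function(dataset, sizes = c(4L, 16L, 64L, 128L),
                        depths = c(2L, 4L, 8L, 12L), config = list(),
                        side = 20L, n_folds = 10L, n_repeats = 5L,
                        seed = 1L, use_split = "train") {
  cells <- expand.grid(forest_size = sizes, max_depth = depths)
  records <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$forest_size <- cells$forest_size[i]
    cfg$max_depth <- cells$max_depth[i]
    records[[i]] <- run_cv(dataset, "rf", cfg, side = side,
                           n_folds = n_folds, n_repeats = n_repeats,
                           seed = seed, use_split = use_split)
  }
  cells$mean_acc <- vapply(records, `[[`, 0, "mean_acc")
  cells$sd_acc <- vapply(records, `[[`, 0, "sd_acc")
  list(grid = cells, records = records)
}

#' Rotation-robustness of a trained classifier
#'
#' Classifies every test patch twice — once at starting angle zero and once
#' at a uniformly random integer starting angle in \[0, 359\] (which may fall
#' inside a skipped-angle period) — and reports the fraction of patches that
#' receive the same label both times, together with the per-patch report.
#' For the ESN the starting angle shifts the rotation schedule; for the RF
#' the patch itself is rotated before prediction.
#'
#' @param model an [esn_fit()] `esn_classifier` or a [train_forest()]
#'   `rf_forest`.
#' @param patches list of `"unit"`-range test patches (already at the
#'   model's working side).
#' @param seed seed for the random starting angles.
#' @return List with `consistency` (fraction identical), `report`
#'   (data.frame `patch_id`, `label`, `phi0`, `pred_0`, `pred_random`,
#'   `agree`).
#' @export
eval_rotation_robustness <- function(model, patches, seed = 1L) {
  stopifnot(length(patches) >= 1)
  phi <- withr::with_seed(seed, sample(0:359, length(patches),
                                       replace = TRUE))
  if (inherits(model, "esn_classifier")) {
    pred0 <- predict(model, patches, phi0 = 0L)
    predr <- predict(model, patches, phi0 = phi)
  } else if (inherits(model, "rf_forest")) {
    pred0 <- vapply(patches, function(p) predict_forest(model, p)$class, 0L)
    predr <- vapply(seq_along(patches), function(i)
      predict_forest(model, rotate_patch(patches[[i]], phi[i]))$class, 0L)
  } else stop("unsupported model class", call. = FALSE)
  report <- data.frame(
    patch_id = vapply(patches, `[[`, "", "patch_id"),
    label = vapply(patches, `[[`, 0L, "label"),
    phi0 = phi, pred_0 = pred0, pred_random = predr,
    agree = pred0 == predr)
  list(consistency = mean(report$agree), report = report)
}
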