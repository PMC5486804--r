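#' Synthetic class specifications for bone-marrow-like cell patches
#'
#' Emulates the statistical structure of single-cell bone-marrow patches:
#' each foreground class is a centered, hematoxylin-dark nucleus drawn as a
#' noisy (possibly lobed) ellipse at a uniformly random orientation with
#' chromatin-like speckle, surrounded by lighter cytoplasm on a bright
#' textured background; the background class carries texture and off-center
#' clutter but no centered object. Consecutive classes mimic a maturation
#' progression (round, then indented, then band-shaped nuclei) whose
#' parameter means are separated by the inter-class-distance knob `delta`:
#' `delta = 0` makes all foreground classes identically distributed, larger
#' `delta` makes them increasingly separable.
#'
#' @param K_fg number of foreground classes.
#' @param delta nonnegative inter-class-distance knob.
#' @param background also append a background class spec (id `K_fg + 1`).
#' @return List of class specs (lists with geometry, texture and intensity
#'   parameters).
#' @export
class_specs <- function(K_fg = 4L, delta = 1, background = TRUE) {
  stopifnot(K_fg >= 1, delta >= 0)
  specs <- lapply(seq_len(K_fg), function(c) {
    prog <- delta * (c - 1)
    radius <- 6.0 * (1 + 0.10 * prog)       # mean nucleus radius, px
    elong <- 1 + 0.18 * prog                # semi-axis ratio a/b
    list(id = c, kind = "foreground",
         radius_range = radius * c(0.94, 1.06),
         elongation = elong,
         lobes = if (c == 1) 0L else 2L,
         indent = min(0.10 * prog, 0.45),
         boundary_noise = 0.04,
         nucleus_int = max(0.42 - 0.05 * prog, 0.08) + c(-0.03, 0.03),
         cyto_int = 0.65, bg_int = 0.82,
         speckle_density = 0.18, speckle_contrast = 0.10)
  })
  if (background)
    specs <- c(specs, list(list(
      id = as.integer(K_fg) + 1L, kind = "background",
      bg_int = 0.82, clutter_int = 0.55,
      speckle_density = 0.06, speckle_contrast = 0.08)))
  specs
}

# 3x3 box blur with replicated borders; softens mask edges like optics would.
.box_blur <- function(m) {
  n <- nrow(m)
  pad <- rbind(m[1, ], m, m[n, ])
  pad <- cbind(pad[, 1], pad, pad[, n])
  out <- matrix(0, n, n)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[(1:n) + di, (1:n) + dj]
  out / 9
}

#' Generate one synthetic cell patch
#'
#' Draws geometry and texture from the class spec using the current RNG
#' state (wrap in [withr::with_seed()] or set `seed` for reproducibility).
#'
#' @param spec one element of [class_specs()].
#' @param side native patch side in pixels (33 by default, resize to the
#'   working size with [resize_patch()]).
#' @param patch_id identifier for the patch.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param return_mask also return the nucleus mask.
#' @return A `"unit"`-range [gray_patch()] labeled `spec$id` (with
#'   `return_mask = TRUE`, a list `patch`, `mask`).
#' @export
generate_patch <- function(spec, side = 33L, patch_id = NA_character_,
                           seed = NULL, return_mask = FALSE) {
  gen <- function() .generate_patch_impl(spec, side, patch_id, return_mask)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.generate_patch_impl <- function(spec, side, patch_id, return_mask) {
  ctr <- side / 2
  gx <- matrix(rep(seq_len(side) - 0.5 - ctr, each = side), side)   # x right
  gy <- matrix(rep(ctr - (seq_len(side) - 0.5), side), side)        # y up
  canvas <- spec$bg_int + matrix(stats::rnorm(side^2, 0, 0.035), side)
  spk <- stats::runif(side^2) < spec$speckle_density
  canvas[spk] <- canvas[spk] - spec$speckle_contrast * stats::runif(sum(spk))

  mask <- matrix(FALSE, side, side)
  if (spec$kind == "foreground") {
    theta0 <- stats::runif(1, 0, 2 * pi)
    r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    a <- r0 * sqrt(spec$elongation)
    b <- r0 / sqrt(spec$elongation)
    xr <- cos(theta0) * gx + sin(theta0) * gy
    yr <- -sin(theta0) * gx + cos(theta0) * gy
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    psi <- atan2(yr, xr)
    phase <- stats::runif(3, 0, 2 * pi)
    wobble <- spec$boundary_noise *
      (cos(2 * psi + phase[2]) + 0.6 * cos(3 * psi + phase[3]))
    edge <- 1 + spec$indent * cos(spec$lobes * (psi - phase[1])) + wobble
    cyto <- rho <= 1.4 * edge
    mask <- rho <= edge
    canvas[cyto] <- spec$cyto_int + stats::rnorm(sum(cyto), 0, 0.03)
    nuc_int <- stats::runif(1, spec$nucleus_int[1], spec$nucleus_int[2])
    canvas[mask] <- nuc_int + stats::rnorm(sum(mask), 0, 0.03)
    chroma <- mask & (matrix(stats::runif(side^2), side) < spec$speckle_density)
    canvas[chroma] <- canvas[chroma] -
      spec$speckle_contrast * stats::runif(sum(chroma), 0.5, 1)
  } else {
    # off-center clutter fragments, kept away from the patch center
    for (k in seq_len(sample(1:3, 1))) {
      ang <- stats::runif(1, 0, 2 * pi)
      d0 <- stats::runif(1, 9, ctr + 2)
      cx <- d0 * cos(ang); cy <- d0 * sin(ang)
      rad <- stats::runif(1, 1.5, 3.5)
      blob <- sqrt((gx - cx)^2 + (gy - cy)^2) <= rad
      canvas[blob] <- spec$clutter_int + stats::rnorm(sum(blob), 0, 0.04)
    }
  }
  canvas <- .box_blur(canvas)
  patch <- gray_patch(matrix(pmin(pmax(canvas, 0), 1), side, side),
                      label = spec$id, patch_id = patch_id)
  if (return_mask) list(patch = patch, mask = mask) else patch
}

#' Swirl (circular) distortion of a patch
#'
#' Center-anchored nonlinear warp: the sampling angle offset decays linearly
#' from `peak_deg` at the center to zero at the incircle edge, so the patch
#' border stays fixed while the cell body is twisted.
#'
#' @param patch a [gray_patch()].
#' @param peak_deg peak angular displacement in degrees (sign sets the
#'   direction).
#' @return The distorted `gray_patch`.
#' @export
swirl_patch <- function(patch, peak_deg) {
  stopifnot(inherits(patch, "gray_patch"))
  s <- patch$side; c0 <- s / 2
  grid <- expand.grid(row = seq_len(s) - 0.5, col = seq_len(s) - 0.5)
  dx <- grid$col - c0; dy <- c0 - grid$row
  rho <- sqrt(dx^2 + dy^2)
  off <- peak_deg * pmax(1 - rho / c0, 0) * pi / 180
  co <- cos(off); si <- sin(off)
  sx <- co * dx + si * dy
  sy <- -si * dx + co * dy
  v <- .bilinear_sample(patch$pixels, c0 - sy - 0.5, sx + c0 - 0.5,
                        edge = "clamp")
  lo <- if (patch$range == "unit") 0 else -1
  gray_patch(matrix(pmin(pmax(v, lo), 1), s, s), label = patch$label,
             patch_id = patch$patch_id, range = patch$range)
}

#' Six-fold warp-and-flip augmentation
#'
#' Expands one patch into six: the original, its horizontal flip, circular
#' distortions at the extreme magnitudes (+35 and -35 degrees) and two
#' intermediate magnitudes combined with flips. All six carry the original
#' label and are pairwise distinct in pixel content.
#'
#' @param patch a [gray_patch()].
#' @param peak_deg extreme distortion magnitude in degrees.
#' @return List of six `gray_patch` objects (`patch_id` suffixed `_a1`..`_a6`).
#' @export
augment_patch <- function(patch, peak_deg = 35) {
  stopifnot(inherits(patch, "gray_patch"))
  out <- list(patch,
              flip_patch(patch),
              swirl_patch(patch, peak_deg),
              swirl_patch(patch, -peak_deg),
              flip_patch(swirl_patch(patch, peak_deg / 2)),
              flip_patch(swirl_patch(patch, -peak_deg / 2)))
  for (k in seq_along(out))
    out[[k]]$patch_id <- paste0(patch$patch_id, "_a", k)
  out
}

#' Generate a labeled synthetic patch dataset with train/test split and folds
#'
#' Default class counts follow the reference test-set proportions
#' 69 : 56 : 61 : 65 (foreground) : 70 (background), scaled by `scale`.
#' 66% of each class is assigned to training and 34% held out; the training
#' part carries stratified cross-validation fold labels. Folds stratify by
#' class and by source patch, so augmented variants of one source never
#' straddle folds.
#'
#' @param counts patches per class (last class is the background when
#'   `background = TRUE`).
#' @param delta inter-class-distance knob, see [class_specs()].
#' @param seed dataset seed (full reproducibility).
#' @param scale multiplier applied to `counts` (result rounded, minimum 1).
#' @param side native patch side.
#' @param n_folds cross-validation folds on the training part.
#' @param background whether the last count is a textured background class.
#' @param train_fraction fraction assigned to training.
#' @return An object of class `cell_dataset`: `patches` (list of
#'   [gray_patch()]), `manifest` (data.frame `patch_id`, `label`,
#'   `source_id`, `split`, `fold`), `specs`, `delta`, `side`, `seed`.
#' @export
generate_dataset <- function(counts = c(69L, 56L, 61L, 65L, 70L), delta = 1,
                             seed = 1L, scale = 1, side = 33L, n_folds = 10L,
                             background = TRUE, train_fraction = 0.66) {
  counts <- pmax(1L, round(counts * scale))
  K_fg <- length(counts) - as.integer(background)
  stopifnot(K_fg >= 1)
  specs <- class_specs(K_fg = K_fg, delta = delta, background = background)
  withr::with_seed(seed, {
    patches <- list(); lab <- integer(0)
    for (cl in seq_along(counts)) {
      for (i in seq_len(counts[cl])) {
        pid <- sprintf("c%d_%04d", cl, i)
        patches[[length(patches) + 1L]] <-
          generate_patch(specs[[cl]], side = side, patch_id = pid)
        lab <- c(lab, specs[[cl]]$id)
      }
    }
    pid <- vapply(patches, `[[`, "", "patch_id")
    split <- rep("test", length(patches))
    fold <- rep(NA_integer_, length(patches))
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      n_tr <- round(train_fraction * length(idx))
      tr <- sample(idx, n_tr)
      split[tr] <- "train"
      fold[tr] <- rep_len(sample(n_folds), length(tr))[sample(length(tr))]
    }
  })
  structure(
    list(patches = patches,
         manifest = data.frame(patch_id = pid, label = lab, source_id = pid,
                               split = split, fold = fold,
                               stringsAsFactors = FALSE),
         specs = specs, delta = delta, side = side, seed = as.integer(seed)),
    class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %d patches (%dx%d px), delta = %g, seed = %d\n",
              length(x$patches), x$side, x$side, x$delta, x$seed))
  print(table(label = x$manifest$label, split = x$manifest$split))
  invisible(x)
}
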