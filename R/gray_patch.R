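#' Construct a gray-scale cell patch
#'
#' A `gray_patch` is the unit of classification: a square matrix of pixel
#' intensities together with an optional class label and identifier. Two
#' intensity conventions are used in the pipeline: `"unit"` intensities in
#' \[0, 1\] (as read from image files, and as consumed by the random-forest
#' baseline) and `"signed"` intensities in \[-1, 1\] (as fed to the reservoir,
#' see [normalize_intensity()]).
#'
#' @param pixels numeric square matrix of intensities.
#' @param label integer class id (`NA` for unlabeled patches).
#' @param patch_id character identifier.
#' @param range `"unit"` for \[0, 1\] intensities, `"signed"` for \[-1, 1\].
#' @return An object of class `gray_patch` with fields `pixels`, `side`,
#'   `label`, `patch_id` and `range`.
#' @export
gray_patch <- function(pixels, label = NA_integer_, patch_id = NA_character_,
                       range = c("unit", "signed")) {
  range <- match.arg(range)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) != ncol(pixels))
    stop("patch must be square, got ", nrow(pixels), "x", ncol(pixels),
         call. = FALSE)
  if (nrow(pixels) < 2)
    stop("patch side must be at least 2 pixels to admit an incircle",
         call. = FALSE)
  lo <- if (range == "unit") 0 else -1
  if (anyNA(pixels) || min(pixels) < lo - 1e-12 || max(pixels) > 1 + 1e-12)
    stop("pixel intensities must lie in [", lo, ", 1]", call. = FALSE)
  structure(
    list(pixels = pixels, side = nrow(pixels),
         label = as.integer(label), patch_id = as.character(patch_id),
         range = range),
    class = "gray_patch")
}

#' @export
print.gray_patch <- function(x, ...) {
  cat(sprintf("<gray_patch %s> %dx%d px, label %s, range %s [%.3f, %.3f]\n",
              x$patch_id, x$side, x$side,
              ifelse(is.na(x$label), "?", x$label), x$range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Convert an RGB patch to gray-scale by channel averaging
#'
#' The gray value of each pixel is the arithmetic mean of its red, green and
#' blue intensities.
#'
#' @param rgb_patch numeric `side x side x 3` array with values in \[0, 1\].
#' @param label,patch_id passed through to [gray_patch()].
#' @return A `gray_patch` with `"unit"` range.
#' @export
to_grayscale <- function(rgb_patch, label = NA_integer_,
                         patch_id = NA_character_) {
  if (!is.array(rgb_patch) || length(dim(rgb_patch)) != 3 ||
      dim(rgb_patch)[3] != 3)
    stop("`rgb_patch` must be a side x side x 3 array", call. = FALSE)
  d <- dim(rgb_patch)
  if (d[1] != d[2])
    stop("RGB patch must be square, got ", d[1], "x", d[2], call. = FALSE)
  if (anyNA(rgb_patch) || min(rgb_patch) < 0 || max(rgb_patch) > 1)
    stop("RGB intensities must lie in [0, 1]", call. = FALSE)
  gray <- (rgb_patch[, , 1] + rgb_patch[, , 2] + rgb_patch[, , 3]) / 3
  gray_patch(gray, label = label, patch_id = patch_id)
}

# Vectorized bilinear sampler on fractional (row, col) positions, 0-based
# continuous pixel indices (pixel i covers [i, i+1), center at i + 0.5).
# `edge = "fill"` returns `fill` outside the grid; `edge = "clamp"` replicates
# the border (used by resizing, where samples may fall marginally outside).
.bilinear_sample <- function(pixels, row, col, edge = c("fill", "clamp"),
                             fill = 0) {
  edge <- match.arg(edge)
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (edge == "clamp") {
    row <- pmin(pmax(row, 0), nr - 1)
    col <- pmin(pmax(col, 0), nc - 1)
  }
  i0 <- floor(row); j0 <- floor(col)
  fr <- row - i0;   fc <- col - j0
  val_at <- function(i, j) {
    ok <- i >= 0 & i <= nr - 1 & j >= 0 & j <= nc - 1
    out <- rep(fill, length(i))
    out[ok] <- pixels[cbind(i[ok] + 1, j[ok] + 1)]
    out
  }
  v00 <- val_at(i0,     j0)
  v01 <- val_at(i0,     j0 + 1)
  v10 <- val_at(i0 + 1, j0)
  v11 <- val_at(i0 + 1, j0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Resize a patch by bilinear interpolation
#'
#' Pixel centers are aligned between grids: output center `k + 0.5` maps to
#' input coordinate `(k + 0.5) * side / new_side - 0.5`; samples beyond the
#' border replicate the edge pixel. Values are clipped back to the patch's
#' intensity range.
#'
#' @param patch a [gray_patch()].
#' @param new_side target side length in pixels (at least 2).
#' @return A `gray_patch` of side `new_side`.
#' @export
resize_patch <- function(patch, new_side) {
  stopifnot(inherits(patch, "gray_patch"))
  if (new_side < 2) stop("`new_side` must be at least 2", call. = FALSE)
  if (new_side == patch$side) return(patch)
  s <- patch$side / new_side
  ctr <- (seq_len(new_side) - 0.5) * s - 0.5
  grid <- expand.grid(row = ctr, col = ctr)
  v <- .bilinear_sample(patch$pixels, grid$row, grid$col, edge = "clamp")
  lo <- if (patch$range == "unit") 0 else -1
  px <- matrix(pmin(pmax(v, lo), 1), new_side, new_side)
  gray_patch(px, label = patch$label, patch_id = patch$patch_id,
             range = patch$range)
}

#' Rescale intensities from \[0, 1\] to \[-1, 1\]
#'
#' The reservoir units use a tanh activation; mapping `x -> 2x - 1` centers
#' the input on zero so that both saturating branches of the nonlinearity are
#' exercised.
#'
#' @param patch a `gray_patch` with `"unit"` range.
#' @return The same patch with `"signed"` range.
#' @export
normalize_intensity <- function(patch) {
  stopifnot(inherits(patch, "gray_patch"))
  if (patch$range == "signed") return(patch)
  gray_patch(2 * patch$pixels - 1, label = patch$label,
             patch_id = patch$patch_id, range = "signed")
}

#' @rdname normalize_intensity
#' @export
denormalize_intensity <- function(patch) {
  stopifnot(inherits(patch, "gray_patch"))
  if (patch$range == "unit") return(patch)
  gray_patch((patch$pixels + 1) / 2, label = patch$label,
             patch_id = patch$patch_id, range = "unit")
}

#' Rotate a patch counterclockwise about its center
#'
#' Bilinear resampling on the half-integer pixel-center grid; counterclockwise
#' is with respect to the usual display orientation (row 1 on top). Samples
#' falling outside the source grid are set to `fill`; they lie outside the
#' incircle and are never read by the receptive field.
#'
#' @param patch a [gray_patch()].
#' @param phi rotation angle in degrees (any real; counterclockwise positive).
#' @param fill value for samples outside the source grid.
#' @return The rotated `gray_patch`.
#' @export
rotate_patch <- function(patch, phi, fill = 0) {
  stopifnot(inherits(patch, "gray_patch"))
  if (phi %% 360 == 0) return(patch)
  s <- patch$side
  c0 <- s / 2
  rad <- phi * pi / 180
  co <- cos(rad); si <- sin(rad)
  grid <- expand.grid(row = seq_len(s) - 0.5, col = seq_len(s) - 0.5)
  dx <- grid$col - c0          # x to the right
  dy <- c0 - grid$row          # y upwards
  # output position q samples the source at R(-phi) q
  sx <- co * dx + si * dy
  sy <- -si * dx + co * dy
  src_col <- sx + c0 - 0.5
  src_row <- c0 - sy - 0.5
  v <- .bilinear_sample(patch$pixels, src_row, src_col,
                        edge = "fill", fill = fill)
  lo <- if (patch$range == "unit") 0 else -1
  px <- matrix(pmin(pmax(v, lo), 1), s, s)
  gray_patch(px, label = patch$label, patch_id = patch$patch_id,
             range = patch$range)
}

#' Mirror a patch horizontally
#'
#' @param patch a [gray_patch()].
#' @return The left-right flipped `gray_patch`.
#' @export
flip_patch <- function(patch) {
  stopifnot(inherits(patch, "gray_patch"))
  gray_patch(patch$pixels[, rev(seq_len(patch$side))], label = patch$label,
             patch_id = patch$patch_id, range = patch$range)
}
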