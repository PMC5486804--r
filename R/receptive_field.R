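#' Build the incircle receptive field of a square patch
#'
#' The receptive field forwards only the pixels inside the incircle of the
#' patch into the network, so that in-plane rotations are
#' information-preserving: every rotation of the patch presents exactly the
#' same set of pixel positions. With pixel centers on the half-integer grid,
#' a pixel belongs to the field when the rounded distance from its center to
#' the patch center is at most `r` (equivalently, distance < r + 0.5). For
#' `side = 20`, `r = 10` this yields `L = 332` inputs.
#'
#' @param side patch side length in pixels.
#' @param r incircle radius in pixels; requires `2 * r <= side`.
#' @return An object of class `receptive_field` with fields `side`, `r`,
#'   `pixels` (an `L x 2` matrix of 1-based (row, col) coordinates in
#'   deterministic row-major order), `lin` (the corresponding linear indices
#'   into the patch matrix) and `L`.
#' @export
receptive_field <- function(side, r) {
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  ctr <- side / 2
  # row-major ordering over included pixels
  grid <- expand.grid(col = seq_len(side), row = seq_len(side))[, c("row", "col")]
  d <- sqrt((grid$row - 0.5 - ctr)^2 + (grid$col - 0.5 - ctr)^2)
  keep <- d < r + 0.5
  px <- as.matrix(grid[keep, , drop = FALSE])
  dimnames(px) <- list(NULL, c("row", "col"))
  structure(
    list(side = side, r = r, pixels = px,
         lin = (px[, "col"] - 1L) * side + px[, "row"],
         L = nrow(px)),
    class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> side %d, r %g, L = %d incircle pixels\n",
              x$side, x$r, x$L))
  invisible(x)
}

#' Read the receptive-field pixels of a patch
#'
#' @param field a [receptive_field()].
#' @param patch a [gray_patch()] of matching side.
#' @return Numeric vector of length `field$L` in the field's pixel order.
#' @export
field_values <- function(field, patch) {
  stopifnot(inherits(field, "receptive_field"), inherits(patch, "gray_patch"))
  if (patch$side != field$side)
    stop("patch side (", patch$side, ") does not match field side (",
         field$side, ")", call. = FALSE)
  patch$pixels[field$lin]
}
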