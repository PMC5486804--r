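#' Rotation schedule for temporal patch encoding
#'
#' A static patch is presented to the reservoir as a stream of in-plane
#' rotations. The rotation angle advances one degree per recorded time step;
#' an external input (the receptive-field pixels of the rotated patch) is
#' presented every `delta_phi + 1` steps, and on the `delta_phi` steps in
#' between the reservoir runs in generative mode (no input). With
#' `delta_phi = 5` the first recorded steps t = 0..12 therefore carry exactly
#' three external inputs, at rotation angles 0, 6 and 12 degrees.
#'
#' @param phi0 starting rotation angle, integer degrees in \[0, 360).
#' @param delta_phi number of skipped rotation angles per period
#'   (non-negative integer).
#' @param steps_per_image recorded time steps per patch (default 360, one
#'   full revolution at one degree per step).
#' @return An object of class `rotation_schedule`.
#' @export
rotation_schedule <- function(phi0 = 0L, delta_phi = 0L,
                              steps_per_image = 360L) {
  stopifnot(delta_phi >= 0, steps_per_image >= 1)
  phi0 <- as.integer(phi0) %% 360L
  structure(
    list(phi0 = phi0, delta_phi = as.integer(delta_phi),
         period = as.integer(delta_phi) + 1L,
         steps_per_image = as.integer(steps_per_image)),
    class = "rotation_schedule")
}

#' Encode a patch as a rotation input stream
#'
#' Recorded step `t` (0-based, `t = 0 .. steps_per_image - 1`) is an external
#' input when `t mod (delta_phi + 1) == 0`, carrying the receptive-field
#' pixels of the patch rotated counterclockwise by `(phi0 + t) mod 360`
#' degrees; all other recorded steps are generative (the reservoir runs on
#' its own activity).
#'
#' @param patch a [gray_patch()] with `"signed"` range (see
#'   [normalize_intensity()]), already resized to the field side.
#' @param field a [receptive_field()].
#' @param schedule a [rotation_schedule()].
#' @return An object of class `input_stream`; see [concatenate_streams()] for
#'   the multi-image form. Fields: `L`, `n_steps`, `kind` (per-step
#'   `"external"`, `"generative"` or `"gap"`), `angle` (degrees, `NA` when no
#'   input), `label` and `image_id` per step, `U_ext` (an `L x n_external`
#'   matrix of external inputs in step order), `ext_step` (step index of each
#'   column of `U_ext`), `recorded` (logical; gap steps are not recorded),
#'   `patch_ids`, `labels` (one per image) and `schedule`.
#' @export
build_input_stream <- function(patch, field, schedule) {
  stopifnot(inherits(patch, "gray_patch"), inherits(field, "receptive_field"),
            inherits(schedule, "rotation_schedule"))
  if (patch$side != field$side)
    stop("patch side (", patch$side, ") does not match field side (",
         field$side, ")", call. = FALSE)
  if (patch$range != "signed")
    stop("patch must be intensity-normalized to [-1, 1] first", call. = FALSE)
  S <- schedule$steps_per_image
  t <- 0:(S - 1)
  ext <- t %% schedule$period == 0L
  angles <- (schedule$phi0 + t) %% 360L
  U_ext <- vapply(angles[ext], function(a)
    field_values(field, rotate_patch(patch, a)), numeric(field$L))
  U_ext <- matrix(U_ext, nrow = field$L)
  structure(
    list(L = field$L, n_steps = S,
         kind = ifelse(ext, "external", "generative"),
         angle = ifelse(ext, angles, NA_real_),
         label = rep(patch$label, S),
         image_id = rep(1L, S),
         U_ext = U_ext,
         ext_step = which(ext),
         recorded = rep(TRUE, S),
         patch_ids = patch$patch_id,
         labels = patch$label,
         schedule = schedule),
    class = "input_stream")
}

#' @export
print.input_stream <- function(x, ...) {
  cat(sprintf(
    "<input_stream> %d image(s), %d steps (%d external, %d generative, %d gap), L = %d\n",
    length(x$labels), x$n_steps, sum(x$kind == "external"),
    sum(x$kind == "generative"), sum(x$kind == "gap"), x$L))
  invisible(x)
}

#' Draw a zero-input gap length
#'
#' Gap lengths are uniform integers in \[50, 100\] (inclusive) by default:
#' long enough for reservoir activity to decay to rest between images, short
#' enough not to dominate training time. Uses the current RNG state.
#'
#' @param range integer vector of length 2, inclusive bounds.
#' @return A single integer gap length.
#' @export
sample_gap_length <- function(range = c(50L, 100L)) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  sample(range[1]:range[2], 1L)
}

#' Concatenate per-image streams with zero-input gaps
#'
#' Joins single-image streams (optionally in shuffled order, so the readout
#' cannot learn the class sequence) and inserts a zero-input gap of random
#' length between consecutive images. Gap steps drive the reservoir with a
#' zero input vector but are excluded from the recorded state matrix, so each
#' image contributes exactly `steps_per_image` recorded steps.
#'
#' @param streams list of single-image [build_input_stream()] results sharing
#'   `L` and schedule.
#' @param shuffle randomize image order (uses the current RNG state).
#' @param gap_range inclusive bounds for [sample_gap_length()].
#' @return A multi-image `input_stream`.
#' @export
concatenate_streams <- function(streams, shuffle = TRUE,
                                gap_range = c(50L, 100L)) {
  if (length(streams) == 0) stop("no streams to concatenate", call. = FALSE)
  stopifnot(all(vapply(streams, inherits, TRUE, "input_stream")))
  L <- streams[[1]]$L
  if (any(vapply(streams, `[[`, 0L, "L") != L))
    stop("streams disagree on input dimension L", call. = FALSE)
  if (length(streams) == 1 && !shuffle) return(streams[[1]])
  ord <- if (shuffle) sample(length(streams)) else seq_along(streams)
  kind <- character(0); angle <- numeric(0); label <- integer(0)
  image_id <- integer(0); ext_step <- integer(0)
  U <- vector("list", length(streams))
  offset <- 0L
  for (k in seq_along(ord)) {
    s <- streams[[ord[k]]]
    if (k > 1) {
      g <- sample_gap_length(gap_range)
      kind <- c(kind, rep("gap", g))
      angle <- c(angle, rep(NA_real_, g))
      label <- c(label, rep(NA_integer_, g))
      image_id <- c(image_id, rep(NA_integer_, g))
      offset <- offset + g
    }
    kind <- c(kind, s$kind)
    angle <- c(angle, s$angle)
    label <- c(label, s$label)
    image_id <- c(image_id, rep(k, s$n_steps))
    ext_step <- c(ext_step, s$ext_step + offset)
    U[[k]] <- s$U_ext
    offset <- offset + s$n_steps
  }
  structure(
    list(L = L, n_steps = offset,
         kind = kind, angle = angle, label = label, image_id = image_id,
         U_ext = do.call(cbind, U),
         ext_step = ext_step,
         recorded = kind != "gap",
         patch_ids = vapply(streams[ord], `[[`, "", "patch_ids"),
         labels = vapply(streams[ord], `[[`, 0L, "labels"),
         schedule = streams[[1]]$schedule),
    class = "input_stream")
}
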