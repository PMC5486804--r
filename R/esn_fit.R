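#' Train a rotation-invariant ESN classifier on labeled patches
#'
#' End-to-end training pipeline: each `"unit"`-range patch is intensity
#' normalized to \[-1, 1\] and encoded as a rotation stream at `phi0 = 0`;
#' the per-image streams are concatenated in shuffled order with zero-input
#' gaps; reservoir states are harvested from rest; and one ridge readout per
#' class is trained on the recorded state matrix.
#'
#' @param patches list of [gray_patch()] objects (all the same side, `"unit"`
#'   range) with labels set.
#' @param params a [reservoir_params()]; its `N`, `rho`, `alpha` govern the
#'   reservoir, its `seed` the weights.
#' @param delta_phi skipped rotation angles per period.
#' @param r receptive-field radius (default `side / 2`).
#' @param steps_per_image recorded steps per patch.
#' @param beta ridge coefficient.
#' @param trim_fraction inference-window trim.
#' @param gap_range inclusive bounds for the zero-input gap length.
#' @param seed seed for stream order and gap lengths.
#' @return An object of class `esn_classifier` holding the reservoir, the
#'   readouts, the receptive field, the schedule and the class ids.
#' @export
esn_fit <- function(patches, params, delta_phi = 0L, r = NULL,
                    steps_per_image = 360L, beta = 1e-2,
                    trim_fraction = 0.05, gap_range = c(50L, 100L),
                    seed = params$seed) {
  stopifnot(length(patches) >= 1,
            all(vapply(patches, inherits, TRUE, "gray_patch")))
  side <- patches[[1]]$side
  if (any(vapply(patches, `[[`, 0L, "side") != side))
    stop("all training patches must share the same side", call. = FALSE)
  labels <- vapply(patches, `[[`, 0L, "label")
  if (anyNA(labels)) stop("all training patches must be labeled", call. = FALSE)
  classes <- sort(unique(labels))
  if (is.null(r)) r <- side / 2
  field <- receptive_field(side, r)
  schedule <- rotation_schedule(phi0 = 0L, delta_phi = delta_phi,
                                steps_per_image = steps_per_image)
  esn <- init_reservoir(params, field$L)
  streams <- lapply(patches, function(p)
    build_input_stream(normalize_intensity(p), field, schedule))
  withr::with_seed(seed, {
    train_stream <- concatenate_streams(streams, shuffle = TRUE,
                                        gap_range = gap_range)
  })
  sm <- harvest_states(train_stream, esn)
  Y <- make_targets(sm$labels, classes)
  readouts <- train_readouts(sm, Y, beta = beta)
  structure(
    list(esn = esn, readouts = readouts, field = field, schedule = schedule,
         classes = classes, beta = beta, trim_fraction = trim_fraction,
         gap_range = gap_range, seed = seed),
    class = "esn_classifier")
}

#' @export
print.esn_classifier <- function(x, ...) {
  cat(sprintf(
    "<esn_classifier> N = %d, L = %d, delta_phi = %d, %d classes (%s)\n",
    x$esn$params$N, x$field$L, x$schedule$delta_phi, length(x$classes),
    paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict class labels for patches with a trained ESN classifier
#'
#' Each patch is encoded as a fresh rotation stream starting at `phi0` (the
#' reservoir starts from rest per patch) and scored over the trimmed
#' inference window.
#'
#' @param object an [esn_fit()] result.
#' @param patches list of `"unit"`-range [gray_patch()] objects of the
#'   training side. A single patch may be passed directly.
#' @param phi0 starting rotation angle in degrees; scalar or one per patch.
#' @param scores also return the `n x K` matrix of mean class scores.
#' @param ... unused.
#' @return Integer vector of predicted class ids, or (with `scores = TRUE`)
#'   a list with `class` and `scores`.
#' @export
predict.esn_classifier <- function(object, patches, phi0 = 0L,
                                   scores = FALSE, ...) {
  if (inherits(patches, "gray_patch")) patches <- list(patches)
  phi0 <- rep_len(as.integer(phi0), length(patches))
  sc <- matrix(NA_real_, length(patches), length(object$classes),
               dimnames = list(NULL, as.character(object$classes)))
  winner <- integer(length(patches))
  for (i in seq_along(patches)) {
    schedule <- rotation_schedule(
      phi0 = phi0[i], delta_phi = object$schedule$delta_phi,
      steps_per_image = object$schedule$steps_per_image)
    stream <- build_input_stream(normalize_intensity(patches[[i]]),
                                 object$field, schedule)
    pred <- esn_predict_stream(stream, object$esn, object$readouts,
                               trim_fraction = object$trim_fraction)
    sc[i, ] <- pred$scores
    winner[i] <- pred$winner
  }
  if (scores) list(class = winner, scores = sc) else winner
}
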