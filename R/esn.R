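#' Reservoir hyper-parameters
#'
#' @param N number of reservoir units.
#' @param rho target spectral radius of the recurrent weights, in (0, 1);
#'   controls how slowly reservoir activity decays (the echo-state property
#'   requires rho < 1).
#' @param alpha leaking rate in (0, 1\]; mixes the previous state into the new
#'   tanh activation and thereby smooths temporal features.
#' @param connectivity fraction of nonzero recurrent weights (0.3 by default;
#'   input weights are dense).
#' @param input_scale magnitude bound of the uniform input weights.
#' @param seed integer seed making the reservoir fully reproducible.
#' @return An object of class `reservoir_params`.
#' @export
reservoir_params <- function(N, rho = 0.6, alpha = 0.85, connectivity = 0.3,
                             input_scale = 1, seed = 1L) {
  stopifnot(N >= 1, rho > 0, rho < 1, alpha > 0, alpha <= 1,
            connectivity > 0, connectivity <= 1, input_scale > 0)
  structure(
    list(N = as.integer(N), rho = rho, alpha = alpha,
         connectivity = connectivity, input_scale = input_scale,
         seed = as.integer(seed)),
    class = "reservoir_params")
}

#' Paper-style default (delta_phi, rho, alpha) tuples
#'
#' The spectral radius is matched to the length of the generative period: the
#' longer the reservoir must run without input, the slower its activity may
#' decay. Defaults: `(0, 0.6, 0.85)`, `(5, 0.8, 0.85)`, `(10, 0.95, 0.85)`.
#'
#' @param delta_phi skipped rotation angles per period (0, 5 or 10; other
#'   values fall back to the nearest listed setting).
#' @return List with `rho` and `alpha`.
#' @export
esn_defaults <- function(delta_phi) {
  tab <- data.frame(delta_phi = c(0, 5, 10), rho = c(0.6, 0.8, 0.95),
                    alpha = c(0.85, 0.85, 0.85))
  i <- which.min(abs(tab$delta_phi - delta_phi))
  list(rho = tab$rho[i], alpha = tab$alpha[i])
}

#' Initialize a fixed random reservoir
#'
#' The recurrent matrix `W` has exactly `round(connectivity * N^2)` nonzero
#' entries (at least one) at uniformly chosen positions with values uniform on
#' \[-1, 1\], rescaled so that its spectral radius equals `rho`. Input weights
#' `Win` are dense uniform on \[-input_scale, input_scale\]; column 1 feeds
#' the constant bias. Both matrices stay fixed; only readouts are trained.
#'
#' @param params a [reservoir_params()].
#' @param L input dimension (receptive-field size).
#' @return An object of class `echo_state_network` with fields `W`, `Win`,
#'   `params`, `L`.
#' @export
init_reservoir <- function(params, L) {
  stopifnot(inherits(params, "reservoir_params"), L >= 1)
  N <- params$N
  withr::with_seed(params$seed, {
    W <- .sample_recurrent(N, params$connectivity, params$rho)
    Win <- matrix(stats::runif(N * (1 + L), -params$input_scale,
                               params$input_scale), N, 1 + L)
  })
  structure(list(W = W, Win = Win, params = params, L = as.integer(L)),
            class = "echo_state_network")
}

.sample_recurrent <- function(N, connectivity, rho, max_tries = 10L) {
  nnz <- max(1L, round(connectivity * N^2))
  for (try in seq_len(max_tries)) {
    W <- matrix(0, N, N)
    W[sample.int(N^2, nnz)] <- stats::runif(nnz, -1, 1)
    sr <- max(abs(eigen(W, only.values = TRUE)$values))
    if (sr > 1e-12) return(W * (rho / sr))
    message("degenerate recurrent sample (zero spectral radius); resampling")
  }
  stop("could not sample a recurrent matrix with nonzero spectral radius",
       call. = FALSE)
}

#' @export
print.echo_state_network <- function(x, ...) {
  cat(sprintf(
    "<echo_state_network> N = %d, L = %d, rho = %g, alpha = %g, density = %.3f\n",
    x$params$N, x$L, x$params$rho, x$params$alpha,
    mean(x$W != 0)))
  invisible(x)
}

#' Leaky-integrator state update (driven)
#'
#' `x(t+1) = (1 - alpha) x(t) + alpha tanh(Win [1; u(t)] + W x(t))`. A
#' zero-input (gap) step passes the zero vector as `u`, which still drives
#' the reservoir through the bias column.
#'
#' @param x state vector of length `N`.
#' @param u input vector of length `L` (zero vector for gap steps).
#' @param esn an [init_reservoir()] result.
#' @param alpha leaking rate; defaults to the reservoir's own.
#' @return The updated state vector.
#' @export
update_state <- function(x, u, esn, alpha = esn$params$alpha) {
  if (length(u) != esn$L)
    stop("input length ", length(u), " does not match L = ", esn$L,
         call. = FALSE)
  if (length(x) != esn$params$N)
    stop("state length does not match N", call. = FALSE)
  (1 - alpha) * x + alpha * tanh(drop(esn$Win %*% c(1, u) + esn$W %*% x))
}

#' Generative-mode state update (input switched off)
#'
#' `x(t+1) = (1 - alpha) x(t) + alpha tanh(W x(t))`: the update runs on the
#' remaining reservoir activity alone, with neither input nor bias. With
#' spectral radius below one the activity decays toward the resting state.
#'
#' @inheritParams update_state
#' @return The updated state vector.
#' @export
update_state_generative <- function(x, esn, alpha = esn$params$alpha) {
  (1 - alpha) * x + alpha * tanh(drop(esn$W %*% x))
}

#' Harvest reservoir states along an input stream
#'
#' Iterates the stream from state `x0`: external steps apply the driven
#' update with the rotated-patch input, gap steps apply the driven update
#' with `u = 0` (bias active) and are not recorded, generative steps apply
#' the generative update and are recorded with zero input rows. Each recorded
#' column is `[1; u(t); x(t)]`, so the readout sees bias, raw input and
#' reservoir features side by side.
#'
#' @param stream an [build_input_stream()] / [concatenate_streams()] result.
#' @param esn an [init_reservoir()] result with matching `L`.
#' @param x0 initial state (zero vector by default; between images the state
#'   carries over through the gaps, there is no hard reset).
#' @return An object of class `state_matrix`: `X` is `(1 + L + N) x Psi`,
#'   `labels` and `image_id` give the per-column class and source image,
#'   `kind` the per-column step type, `x_final` the last reservoir state.
#' @export
harvest_states <- function(stream, esn, x0 = NULL) {
  stopifnot(inherits(stream, "input_stream"),
            inherits(esn, "echo_state_network"))
  if (stream$L != esn$L)
    stop("stream L (", stream$L, ") does not match reservoir L (", esn$L, ")",
         call. = FALSE)
  N <- esn$params$N; L <- esn$L; alpha <- esn$params$alpha
  x <- if (is.null(x0)) numeric(N) else x0
  stopifnot(length(x) == N)

  Psi <- sum(stream$recorded)
  X <- matrix(0, 1 + L + N, Psi)
  X[1, ] <- 1
  u0 <- numeric(L)
  ext_col <- cumsum(stream$kind == "external") # column of U_ext a step uses
  rec_col <- cumsum(stream$recorded)
  state_rows <- (2 + L):(1 + L + N)
  for (t in seq_len(stream$n_steps)) {
    k <- stream$kind[t]
    if (k == "external") {
      u <- stream$U_ext[, ext_col[t]]
      x <- update_state(x, u, esn, alpha)
      j <- rec_col[t]
      X[2:(1 + L), j] <- u
      X[state_rows, j] <- x
    } else if (k == "generative") {
      x <- update_state_generative(x, esn, alpha)
      X[state_rows, rec_col[t]] <- x
    } else { # gap: driven update with u = 0 (bias active), not recorded
      x <- update_state(x, u0, esn, alpha)
    }
  }
  structure(
    list(X = X, Psi = Psi,
         labels = stream$label[stream$recorded],
         image_id = stream$image_id[stream$recorded],
         kind = stream$kind[stream$recorded],
         x_final = x),
    class = "state_matrix")
}

#' One-hot target matrix over recorded steps
#'
#' Every recorded column of an image — external and generative alike —
#' carries that image's label, giving a piece-wise constant target function
#' per class.
#'
#' @param labels integer class label per recorded column.
#' @param classes integer vector of all class ids (readout order).
#' @return A `K x Psi` binary matrix with rows named by class.
#' @export
make_targets <- function(labels, classes) {
  if (anyNA(labels) || !all(labels %in% classes))
    stop("labels contain values outside the declared classes", call. = FALSE)
  Y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  Y <- t(Y)
  rownames(Y) <- as.character(classes)
  Y
}

#' Ridge-regression readout training
#'
#' Solves the Tikhonov-regularized least squares problem in the
#' `(1 + L + N)`-dimensional feature space:
#' `Wout = Y X' (X X' + beta I)^{-1}`, computed by a stable symmetric solve
#' rather than explicit inversion. One readout (row) per class.
#'
#' @param X a [harvest_states()] result or a bare feature-by-step matrix.
#' @param Y `K x Psi` target matrix (see [make_targets()]).
#' @param beta ridge coefficient (default `1e-2`).
#' @return An object of class `readout_weights` with fields `Wout`
#'   (`K x (1 + L + N)`) and `beta`.
#' @export
train_readouts <- function(X, Y, beta = 1e-2) {
  if (inherits(X, "state_matrix")) X <- X$X
  stopifnot(beta > 0, ncol(X) == ncol(Y))
  if (!all(is.finite(X))) stop("state matrix contains non-finite values",
                               call. = FALSE)
  A <- tcrossprod(X)
  diag(A) <- diag(A) + beta
  Wout <- t(solve(A, tcrossprod(X, Y)))
  rownames(Wout) <- rownames(Y)
  structure(list(Wout = Wout, beta = beta), class = "readout_weights")
}

#' Windowed multi-class inference on a single-image stream
#'
#' Harvests the stream from rest, computes per-step readout outputs
#' `y_c(t) = Wout_c [1; u(t); x(t)]`, averages them over the trimmed
#' inference window (by default dropping the first and last 5% of the
#' recorded steps, where readout activity is dominated by onset/offset
#' transients) and declares the class with the maximal mean score the winner.
#' Ties go to the smallest class index.
#'
#' @param stream a single-image input stream.
#' @param esn the reservoir used at training time.
#' @param readouts a [train_readouts()] result.
#' @param trim_fraction fraction of recorded steps trimmed at each end
#'   (floor applied on both sides).
#' @return An object of class `esn_prediction`: `scores` (named mean score
#'   per class), `winner` (class id), `window` (1-based first/last recorded
#'   index used), `outputs` (`K x S` per-step outputs).
#' @export
esn_predict_stream <- function(stream, esn, readouts, trim_fraction = 0.05) {
  stopifnot(inherits(readouts, "readout_weights"))
  if (length(stream$labels) != 1)
    stop("inference expects a single-image stream", call. = FALSE)
  sm <- harvest_states(stream, esn)
  outputs <- readouts$Wout %*% sm$X
  S <- ncol(outputs)
  m <- as.integer(floor(trim_fraction * S))
  window <- c(m + 1L, S - m)
  ybar <- rowMeans(outputs[, window[1]:window[2], drop = FALSE])
  classes <- as.integer(rownames(readouts$Wout))
  structure(
    list(scores = stats::setNames(ybar, rownames(readouts$Wout)),
         winner = classes[which.max(ybar)],
         window = window, outputs = outputs),
    class = "esn_prediction")
}

#' @export
print.esn_prediction <- function(x, ...) {
  cat(sprintf("<esn_prediction> winner class %d; window [%d, %d]\n",
              x$winner, x$window[1], x$window[2]))
  print(round(x$scores, 4))
  invisible(x)
}
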