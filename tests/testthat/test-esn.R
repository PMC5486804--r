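# a small reservoir for structural checks
params_small <- reservoir_params(N = 40, rho = 0.7, alpha = 0.85,
                                 connectivity = 0.5, seed = 3)

test_that("reservoir initialization honors radius, density and seed", {
  esn1 <- init_reservoir(reservoir_params(1, rho = 0.5, connectivity = 1,
                                          seed = 2), L = 3)
  expect_equal(abs(esn1$W[1, 1]), 0.5, tolerance = 1e-12)

  esn <- init_reservoir(reservoir_params(200, rho = 0.8, connectivity = 0.3,
                                         seed = 5), L = 10)
  density <- mean(esn$W != 0)
  expect_gte(density, 0.28); expect_lte(density, 0.32)
  # independent eigenvalue oracle
  sr <- max(abs(eigen(esn$W, only.values = TRUE)$values))
  expect_lt(abs(sr - 0.8), 1e-9)
  expect_identical(dim(esn$Win), c(200L, 11L))
  expect_true(all(abs(esn$Win) <= 1))

  again <- init_reservoir(reservoir_params(200, rho = 0.8, connectivity = 0.3,
                                           seed = 5), L = 10)
  expect_identical(esn$W, again$W)
  expect_identical(esn$Win, again$Win)
})

test_that("driven update matches a direct evaluation of the leaky equation", {
  set.seed(21)
  for (i in 1:100) {
    N <- sample(2:10, 1); L <- sample(1:6, 1)
    esn <- list(W = matrix(rnorm(N * N), N),
                Win = matrix(rnorm(N * (1 + L)), N),
                params = list(N = N, alpha = runif(1, 0.05, 1)), L = L)
    class(esn) <- "echo_state_network"
    x <- runif(N, -1, 1); u <- runif(L, -1, 1)
    expect_lt(max(abs(update_state(x, u, esn) -
                        eq1_ref(x, u, esn$W, esn$Win, esn$params$alpha))),
              1e-12)
    expect_lt(max(abs(update_state_generative(x, esn) -
                        eq2_ref(x, esn$W, esn$params$alpha))), 1e-12)
  }
})

test_that("limiting cases of the state update behave as the equation says", {
  esn <- init_reservoir(params_small, L = 5)
  x <- runif(40, -1, 1); u <- runif(5, -1, 1)
  # alpha -> 0: the state freezes
  expect_equal(update_state(x, u, esn, alpha = 0), x)
  # alpha = 1, W = 0, u = 0: only the bias column drives
  esn0 <- esn; esn0$W[] <- 0
  expect_equal(update_state(x, numeric(5), esn0, alpha = 1),
               tanh(esn$Win[, 1]))
  # the zero state is a fixed point of the generative update
  expect_identical(update_state_generative(numeric(40), esn), numeric(40))
  expect_error(update_state(x, runif(3), esn), "does not match")
})

test_that("generative activity decays to rest under the echo-state property", {
  run_down <- function(rho, n_steps, seed) {
    esn <- init_reservoir(reservoir_params(100, rho = rho, alpha = 0.85,
                                           seed = seed), L = 4)
    x <- withr::with_seed(seed, runif(100, -1, 1))
    norms <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      x <- update_state_generative(x, esn)
      norms[t] <- sqrt(sum(x^2))
    }
    norms
  }
  # asymptotic decay rate is 1 - alpha (1 - rho): fast for small radii,
  # ~0.96 per step at rho = 0.95 (a few hundred steps to numerical rest)
  expect_lt(min(run_down(0.6, 100, 1)), 1e-6)
  expect_lt(min(run_down(0.8, 200, 2)), 1e-6)
  n95 <- run_down(0.95, 500, 3)
  expect_lt(min(n95), 1e-6)
  tail_part <- n95[100:300]
  expect_true(all(diff(tail_part) < 0))  # eventually monotone decreasing
})

test_that("harvesting records 360 columns per image with the right step mix", {
  field <- receptive_field(8, 4)
  p <- normalize_intensity(smooth_patch(8))
  esn <- init_reservoir(params_small, L = field$L)

  st0 <- build_input_stream(p, field, rotation_schedule(delta_phi = 0))
  sm0 <- harvest_states(st0, esn)
  expect_identical(sm0$Psi, 360L)
  expect_identical(ncol(sm0$X), 360L)
  expect_true(all(sm0$X[1, ] == 1))

  st5 <- build_input_stream(p, field, rotation_schedule(delta_phi = 5))
  sm5 <- harvest_states(st5, esn)
  expect_identical(sum(sm5$kind == "external"), 60L)
  expect_identical(sum(sm5$kind == "generative"), 300L)
  # input rows are zero on generative columns
  gen <- sm5$kind == "generative"
  expect_true(all(sm5$X[2:(1 + field$L), gen] == 0))
  expect_true(any(sm5$X[2:(1 + field$L), !gen] != 0))
})

test_that("harvesting a continuous stream equals stepwise driven updates", {
  field <- receptive_field(6, 3)
  p <- normalize_intensity(smooth_patch(6))
  esn <- init_reservoir(reservoir_params(15, rho = 0.6, seed = 8), field$L)
  st <- build_input_stream(p, field, rotation_schedule(delta_phi = 0,
                                                       steps_per_image = 50))
  sm <- harvest_states(st, esn)
  x <- numeric(15)
  for (t in 1:50) {
    x <- update_state(x, st$U_ext[, t], esn)
    expect_identical(sm$X[(2 + field$L):(1 + field$L + 15), t], x)
  }
})

test_that("gap steps drive the reservoir but are excluded from the record", {
  field <- receptive_field(6, 3)
  mk <- function(id, label) {
    p <- smooth_patch(6, range = "signed"); p$patch_id <- id
    p$label <- label
    build_input_stream(p, field, rotation_schedule(delta_phi = 2,
                                                   steps_per_image = 30))
  }
  set.seed(4)
  cs <- concatenate_streams(list(mk("a", 1L), mk("b", 3L)), shuffle = FALSE)
  esn <- init_reservoir(reservoir_params(10, seed = 1), field$L)
  sm <- harvest_states(cs, esn)
  expect_identical(sm$Psi, 60L)
  expect_identical(as.integer(table(sm$labels)), c(30L, 30L))
  # targets: every recorded column of an image carries its label
  Y <- make_targets(sm$labels, classes = c(1L, 3L))
  expect_identical(unname(rowSums(Y)), c(30, 30))
  expect_true(all(colSums(Y) == 1))
})

test_that("one-hot targets reject unknown labels", {
  expect_error(make_targets(c(1L, 2L, 7L), classes = 1:5), "outside")
  Y <- make_targets(rep(2L, 8), classes = 1:5)
  expect_identical(dim(Y), c(5L, 8L))
  expect_true(all(Y[2, ] == 1) && sum(Y) == 8)
})

test_that("ridge readouts solve the regularized normal equations", {
  set.seed(13)
  X <- matrix(rnorm(10 * 50), 10, 50)
  Y <- matrix(rbinom(3 * 50, 1, 0.4), 3, 50)
  ro <- train_readouts(X, Y, beta = 1e-2)
  expect_identical(dim(ro$Wout), c(3L, 10L))
  expect_lt(max(abs(ro$Wout - ridge_ref(X, Y, 1e-2))), 1e-9)
  # normal equations residual, relative
  res <- ro$Wout %*% (X %*% t(X) + 1e-2 * diag(10)) - Y %*% t(X)
  expect_lt(max(abs(res)) / max(abs(Y %*% t(X))), 1e-8)

  # exact interpolation in the beta -> 0 limit for a single unit column
  w <- train_readouts(matrix(1, 1, 1), matrix(1, 1, 1), beta = 1e-10)$Wout
  expect_equal(w[1, 1], 1, tolerance = 1e-9)

  # invariance under permutation of recorded steps
  perm <- sample(50)
  ro2 <- train_readouts(X[, perm], Y[, perm], beta = 1e-2)
  expect_lt(max(abs(ro$Wout - ro2$Wout)), 1e-9)

  expect_error(train_readouts(matrix(c(1, NA), 1, 2), matrix(0, 1, 2)),
               "non-finite")

  # five target rows give five readout vectors
  Y5 <- make_targets(sample(1:5, 50, replace = TRUE), 1:5)
  expect_identical(nrow(train_readouts(X, Y5)$Wout), 5L)
})

test_that("windowed inference trims 5% per side and breaks ties downward", {
  field <- receptive_field(6, 3)
  p <- normalize_intensity(smooth_patch(6))
  esn <- init_reservoir(reservoir_params(12, seed = 2), field$L)
  st <- build_input_stream(p, field, rotation_schedule(delta_phi = 0))

  # constant per-class outputs: only the bias weight is nonzero
  Wout <- matrix(0, 3, 1 + field$L + 12,
                 dimnames = list(1:3, NULL))
  Wout[, 1] <- c(0.2, 0.9, 0.4)
  ro <- structure(list(Wout = Wout, beta = 1e-2), class = "readout_weights")
  pred <- esn_predict_stream(st, esn, ro)
  expect_identical(pred$window, c(19L, 342L))           # floor(0.05*360) = 18
  expect_identical(diff(pred$window) + 1L, 324L)
  expect_equal(unname(pred$scores), c(0.2, 0.9, 0.4))
  expect_identical(pred$winner, 2L)

  # exact tie between classes 1 and 3: smallest class index wins
  Wout[, 1] <- c(0.7, 0.1, 0.7)
  ro <- structure(list(Wout = Wout, beta = 1e-2), class = "readout_weights")
  expect_identical(esn_predict_stream(st, esn, ro)$winner, 1L)
})

test_that("the full classifier is deterministic given seeds", {
  ds <- tiny_dataset()
  tr <- which(ds$manifest$split == "train")[1:9]
  te <- which(ds$manifest$split == "test")[1:4]
  fit_once <- function() {
    m <- esn_fit(ds$patches[tr],
                 reservoir_params(30, rho = 0.6, seed = 11),
                 delta_phi = 5L, steps_per_image = 60L, seed = 11)
    predict(m, ds$patches[te], scores = TRUE)
  }
  a <- fit_once(); b <- fit_once()
  expect_identical(a$class, b$class)
  expect_identical(a$scores, b$scores)
})
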