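test_that("extraction matches a brute-force covariance eigendecomposition", {
  set.seed(31)
  for (i in 1:100) {
    X <- matrix(rnorm(5 * 200, sd = runif(1, 0.5, 3)), 5, 200)
    rownames(X) <- c("SH_x", "SH_y", "SH_z", "FA_x", "FA_y")
    dec <- extract_synergies(X, n_components = 5)
    Xc <- X - rowMeans(X)
    covm <- (Xc %*% t(Xc)) / (ncol(X) - 1)
    eig <- eigen(covm, symmetric = TRUE)
    V <- eig$vectors
    for (k in 1:5) if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
    expect_lt(max(abs(dec$loadings - V)), 1e-8)
    expect_lt(max(abs(dec$variance_fraction - eig$values / sum(eig$values))),
              1e-8)
  }
})

test_that("full-rank reconstruction is the identity; low-rank sources are exact", {
  set.seed(5)
  X <- matrix(rnorm(5 * 80), 5, 80)
  dec <- extract_synergies(X, n_components = 5)
  expect_lt(reconstruction_error(X, reconstruct(dec)), 1e-9)
  # noiseless rank-2 source: first two components carry all the variance
  B <- generate_basis(5, 2, seed = 2)
  C <- rbind(sin(seq(0, 6, length.out = 120)), cos(seq(0, 9, length.out = 120)))
  X2 <- B %*% C
  d2 <- extract_synergies(X2)
  expect_equal(sum(d2$variance_fraction[1:2]), 1, tolerance = 1e-9)
  expect_lt(reconstruction_error(X2, reconstruct(d2, n = 2)), 1e-8)
  expect_error(extract_synergies(X[, 1, drop = FALSE]), "rank error")
  expect_error(extract_synergies(X, n_components = 6), "rank error")
})

test_that("component count selection uses a strict cumulative threshold", {
  expect_identical(select_components(c(0.75, 0.16, 0.05, 0.03, 0.01), 0.85), 2L)
  expect_identical(select_components(c(1, 0, 0, 0, 0), 0.85), 1L)
  expect_identical(select_components(rep(0.2, 5), 1.0), 5L)
  # strict inequality: exactly 85% after one component is not enough
  expect_identical(select_components(c(0.85, 0.15), 0.85), 2L)
  expect_error(select_components(c(0.9, 0.1), 0), "threshold")
})

test_that("the Frobenius error matches a naive double loop", {
  X <- matrix(0, 5, 4)
  expect_identical(reconstruction_error(X, X), 0)
  expect_equal(reconstruction_error(matrix(1, 5, 4), matrix(0, 5, 4)),
               sqrt(20))
  set.seed(8)
  A <- matrix(rnorm(30), 5); Bm <- matrix(rnorm(30), 5)
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + (A[i, j] - Bm[i, j])^2
  expect_equal(reconstruction_error(A, Bm), sqrt(acc), tolerance = 1e-12)
  expect_error(reconstruction_error(A, matrix(0, 2, 2)), "shape mismatch")
})

test_that("projection is the least-squares inverse of reconstruction", {
  set.seed(13)
  X <- matrix(rnorm(5 * 60), 5, 60)
  rownames(X) <- c("SH_x", "SH_y", "SH_z", "FA_x", "FA_y")
  dec <- extract_synergies(X, n_components = 3)
  expect_lt(max(abs(project(dec, X, n = 5) - dec$activations)), 1e-9)
  means_rep <- matrix(dec$channel_means, 5, 10,
                      dimnames = list(rownames(X), NULL))
  expect_lt(max(abs(project(dec, means_rep, n = 3))), 1e-12)
  # a signal already in span(W[, 1:3]) survives project -> reconstruct
  insp <- dec$channel_means + dec$loadings[, 1:3] %*% matrix(rnorm(3 * 7), 3)
  rownames(insp) <- rownames(X)
  back <- reconstruct(dec, project(dec, insp, n = 3), n = 3)
  expect_lt(max(abs(back - insp)), 1e-9)
  expect_error(project(dec, X[1:3, ]), "dimension mismatch")
})

test_that("the truncation beats random rank-N factorizations (Eckart-Young)", {
  set.seed(21)
  X <- matrix(rnorm(5 * 100), 5, 100)
  dec <- extract_synergies(X, n_components = 2)
  best <- reconstruction_error(X, reconstruct(dec, n = 2))
  Xc <- X - rowMeans(X)
  for (i in 1:100) {
    W <- matrix(rnorm(10), 5, 2)
    Cr <- qr.solve(W, Xc)    # least-squares C for that W
    expect_gte(reconstruction_error(Xc, W %*% Cr), best - 1e-9)
  }
  # variance fractions equal the activation row-variance shares
  rv <- apply(dec$activations, 1, var)
  expect_lt(max(abs(dec$variance_fraction - rv / sum(rv))), 1e-9)
})

test_that("the forearm-only decomposition obeys the same contracts with j = 2", {
  set.seed(2)
  X <- matrix(rnorm(2 * 150), 2, 150, dimnames = list(c("FA_x", "FA_y"), NULL))
  dec <- extract_synergies(X, n_components = 2)
  expect_lt(max(abs(crossprod(dec$loadings) - diag(2))), 1e-9)
  expect_lt(reconstruction_error(X, reconstruct(dec)), 1e-9)
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-9)
  expect_lt(max(abs(project(dec, X, n = 2) - dec$activations)), 1e-9)
})

test_that("recovered synergy subspaces degrade monotonically with noise", {
  angle_at <- function(noise, seed) {
    coh <- generate_cohort(quick_config(noise_sd = noise, seed = seed,
                                        n_targets = 3,
                                        n_train_trials_per_target = 4,
                                        n_validation_movements = 1))
    sdat <- prepare_subject(coh[[1]]$training)
    max(principal_angles(loadings_in_degrees(sdat$decomp_full, sdat$norm_angles, 2),
                         coh[[1]]$subject$true_basis))
  }
  angles <- vapply(c(0, 0.5, 1.5), function(ns)
    mean(vapply(1:10, function(s) angle_at(ns, 100 + s), numeric(1))),
    numeric(1))
  expect_lt(angles[1], 0.5)          # noise-free: essentially exact
  expect_true(all(diff(angles) > 0)) # and grows with the noise level
})
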