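test_that("input combos map to the documented channel sets", {
  expect_identical(select_inputs(2), c("SH_y", "SH_z"))
  expect_identical(select_inputs(3), c("SH_x", "SH_y", "SH_z"))
  expect_identical(select_inputs(4), c("SH_y", "SH_z", "dSH_y", "dSH_z"))
  expect_identical(select_inputs(6),
                   c("SH_x", "SH_y", "SH_z", "dSH_x", "dSH_y", "dSH_z"))
  # the channel added from 2 to 3 inputs is internal-external rotation
  expect_identical(setdiff(select_inputs(3), select_inputs(2)), "SH_x")
  expect_error(select_inputs(5), "input_combo")
  expect_equal(nrow(scenario_grid()), 36L)
})

test_that("windowing yields T - w + 1 examples and never crosses movements", {
  f10 <- matrix(rnorm(10 * 2), 10, 2)
  ds1 <- build_windows(f10, matrix(0, 10, 1), window = 10)
  expect_equal(dim(ds1$inputs), c(10, 2, 1))
  f150 <- matrix(rnorm(150 * 3), 150, 3)
  expect_equal(dim(build_windows(f150, matrix(0, 150, 2), 10)$inputs)[3], 141)
  # brute-force enumeration over two concatenated movements
  m1 <- matrix(seq_len(24), 12, 2); m2 <- matrix(100 + seq_len(30), 15, 2)
  ds <- build_windows(list(m1, m2), list(m1[, 1, drop = FALSE],
                                         m2[, 1, drop = FALSE]), 5)
  oracle <- list()
  for (mv in list(m1, m2))
    for (i in seq_len(nrow(mv) - 4))
      oracle[[length(oracle) + 1L]] <- mv[i:(i + 4), ]
  expect_equal(dim(ds$inputs)[3], length(oracle))
  for (k in seq_along(oracle))
    expect_equal(ds$inputs[, , k], oracle[[k]])
  # a window mixing both movements never appears
  for (k in seq_len(dim(ds$inputs)[3]))
    expect_true(all(ds$inputs[, 1, k] < 100) || all(ds$inputs[, 1, k] > 100))
  expect_error(build_windows(matrix(0, 4, 2), matrix(0, 4, 1), 10),
               "empty-dataset")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(1)
  Xarr <- array(rnorm(5 * 3 * 4), dim = c(5, 3, 4))
  Y <- matrix(rnorm(4 * 2), 4, 2)
  w <- synspace:::cpp_lstm_init(3L, 4L, 2L, 2L, seed = 9L)
  g <- synspace:::cpp_lstm_grad(w, Xarr, Y, 2L, 4L)
  eps <- 1e-6
  for (nm in names(w)) {
    wm <- w[[nm]]
    probe <- sample(length(wm), min(6, length(wm)))
    for (j in probe) {
      wp <- w; wp[[nm]][j] <- wp[[nm]][j] + eps
      wm2 <- w; wm2[[nm]][j] <- wm2[[nm]][j] - eps
      num <- (synspace:::cpp_lstm_loss(wp, Xarr, Y, 2L, 4L) -
              synspace:::cpp_lstm_loss(wm2, Xarr, Y, 2L, 4L)) / (2 * eps)
      expect_equal(g$grad[[nm]][j], num, tolerance = 1e-5)
    }
  }
})

test_that("training is seeded-deterministic and fits the zero function", {
  set.seed(3)
  Xarr <- array(rnorm(10 * 2 * 120), dim = c(10, 2, 120))
  Y0 <- matrix(0, 120, 2)
  fit1 <- synspace:::cpp_lstm_train(Xarr, Y0, 1L, 8L, 0.1, 30L, 32L, 0.01,
                                    seed = 4L, val_fraction = 0, patience = 5L)
  fit2 <- synspace:::cpp_lstm_train(Xarr, Y0, 1L, 8L, 0.1, 30L, 32L, 0.01,
                                    seed = 4L, val_fraction = 0, patience = 5L)
  expect_identical(fit1$weights, fit2$weights)
  expect_equal(fit1$final_train_loss, fit2$final_train_loss, tolerance = 1e-6)
  pred <- synspace:::cpp_lstm_predict(fit1$weights, Xarr, 1L, 8L)
  expect_lt(mean(pred^2), 1e-4)
  # inference is deterministic
  expect_identical(pred, synspace:::cpp_lstm_predict(fit1$weights, Xarr, 1L, 8L))
})

test_that("an overfit run predicts its own training data near the loss floor", {
  set.seed(6)
  f <- matrix(rnorm(80 * 2), 80, 2)
  y <- matrix(cumsum(rnorm(80, sd = 0.05)), 80, 1)
  ds <- build_windows(f, y, 10)
  fit <- synspace:::cpp_lstm_train(ds$inputs, ds$targets, 1L, 16L, 0.0, 120L,
                                   16L, 0.01, seed = 2L, val_fraction = 0,
                                   patience = 10L)
  pred <- synspace:::cpp_lstm_predict(fit$weights, ds$inputs, 1L, 16L)
  expect_lt(mean((pred - ds$targets)^2), 5 * fit$final_train_loss + 1e-8)
  # smoothed loss curve is non-increasing overall
  tl <- fit$train_loss
  expect_lt(mean(tail(tl, 10)), mean(head(tl, 10)))
})

test_that("methodologies train the documented output dimensions", {
  sdat <- shared_subject()
  for (m in c("two_synergy", "one_synergy", "direct")) {
    dec <- fit_decoder(sdat, quick_scenario(m))
    expect_equal(nrow(dec$weights$Wy),
                 if (m == "one_synergy") 1L else 2L)
    preds <- predict(dec, sdat)
    expect_true(all(vapply(preds, nrow, integer(1)) == 2L))
    expect_identical(rownames(preds[[1]]), c("FA_x", "FA_y"))
    # one output vector per window position
    Tlen <- ncol(sdat$validation$trials[[1]]$angles)
    expect_equal(ncol(preds[[1]]), Tlen - dec$scenario$window + 1L)
  }
  expect_error(fit_decoder(sdat, "not a scenario"))
})

test_that("perfect activation signals reconstruct the forearm channels", {
  sdat <- shared_clean_subject()
  tr <- sdat$trials[[1]]
  ang <- apply_normalization(tr$angles, sdat$norm_angles)
  # two-synergy path with the true (projected) activations
  C2 <- project(sdat$decomp_full, ang, n = 2)
  rec <- reconstruct(sdat$decomp_full, C2, n = 2, channels = c("FA_x", "FA_y"))
  back <- invert_normalization(rec, sdat$norm_angles)
  # noise-free data are rank 2 around the channel means, so the
  # 2-component truncation is numerically exact
  expect_lt(rmse(tr$angles[c("FA_x", "FA_y"), ], back), 1e-6)
  # direct path: normalized truth denormalizes to the exact truth
  fa <- ang[c("FA_x", "FA_y"), ]
  expect_equal(invert_normalization(fa, sdat$norm_angles),
               tr$angles[c("FA_x", "FA_y"), ], tolerance = 1e-9)
})

test_that("decoders run deterministically for a fixed scenario seed", {
  sdat <- shared_subject()
  scen <- quick_scenario("direct")
  d1 <- fit_decoder(sdat, scen)
  d2 <- fit_decoder(sdat, scen)
  expect_identical(d1$weights, d2$weights)
  expect_identical(predict(d1, sdat), predict(d2, sdat))
})
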