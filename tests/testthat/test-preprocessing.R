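test_that("segmentation recovers the labeled movements to within 50 ms", {
  cfg <- cohort_config(n_subjects = 1, n_targets = 4,
                       n_train_trials_per_target = 5,
                       n_validation_movements = 6, sampling_rate = 120,
                       movement_duration = 1.5, rest_duration = 0.5,
                       noise_sd = 0.5, seed = 9)
  ses <- generate_cohort(cfg)[[1]]$training
  trials <- segment_trials(ses)
  expect_length(trials, nrow(ses$movements))
  expect_equal(vapply(trials, function(tr) tr$target_id, integer(1)),
               ses$movements$target_id)
  # boundary accuracy: onsets and offsets within 50 ms of ground truth
  starts <- vapply(trials, function(tr) tr$start, integer(1))
  ends <- starts + vapply(trials, function(tr) ncol(tr$angles), integer(1))
  tol <- 0.05 * ses$rate
  expect_true(all(abs(starts - ses$movements$start) <= tol))
  expect_true(all(abs(ends - ses$movements$end) <= tol))
})

test_that("segmentation degenerate cases behave as specified", {
  flat <- structure(list(subject_id = "X", role = "training",
                         angles = matrix(10, 5, 500,
                                         dimnames = list(c("SH_x", "SH_y", "SH_z",
                                                           "FA_x", "FA_y"), NULL)),
                         rate = 120, movements = NULL, seed = 1),
                    class = "motion_session")
  expect_error(segment_trials(flat), "segmentation error")
  ses <- (.fixture_cache$cohort %||% generate_cohort(quick_config()))[[1]]$training
  whole <- segment_trials(ses, speed_threshold = 0)
  expect_length(whole, 1L)
  expect_equal(ncol(whole[[1]]$angles), ncol(ses$angles))
})

test_that("time normalization preserves endpoints and affine signals", {
  X <- rbind(lin = seq(0, 10, length.out = 150),
             sine = sin(2 * pi * seq(0, 1, length.out = 150)))
  tr <- motion_trial(1, 1, X, 120)
  expect_equal(time_normalize(tr, 150)$angles, X, tolerance = 1e-12)
  short <- time_normalize(tr, 60)
  expect_equal(short$angles["lin", ], seq(0, 10, length.out = 60),
               tolerance = 1e-12)
  expect_identical(short$angles[, 1], X[, 1])
  expect_identical(short$angles[, 60], X[, 150])
  # round trip 150 -> 100 -> 150: bounded by the linear-interpolation error
  # of sin(2*pi*s) on the 100-point grid, max|f''| h^2 / 8
  # triangle inequality: |L150(L100 f) - f| <= |L100 f - f| + |L150 f - f|,
  # each bounded by max|f''| h^2 / 8 on its grid; the 100-point grid term
  # dominates
  rt <- time_normalize(time_normalize(tr, 100), 150)
  bound <- 2 * (2 * pi)^2 * (1 / 99)^2 / 8
  expect_lt(max(abs(rt$angles["sine", ] - X["sine", ])), bound)
})

test_that("trial averaging is the element-wise mean and reduces noise as sqrt(n)", {
  X <- matrix(seq_len(20), 4, 5)
  tr <- motion_trial(1, 2, X, 100)
  expect_equal(average_trials(list(tr, tr, tr))$angles, X)
  tr2 <- motion_trial(2, 2, X + 1, 100)
  expect_equal(average_trials(list(tr, tr2))$angles, X + 0.5)
  expect_error(average_trials(list(tr, motion_trial(3, 4, X, 100))), "target")
  sigma <- 2
  clean <- matrix(sin(seq(0, 3, length.out = 300)), 5, 60, byrow = TRUE)
  ratios <- vapply(1:20, function(seed) {
    set.seed(seed)
    noisy <- lapply(1:15, function(i)
      motion_trial(i, 1, clean + matrix(rnorm(length(clean), 0, sigma),
                                        nrow(clean)), 100))
    avg <- average_trials(noisy)
    sqrt(mean((avg$angles - clean)^2)) / (sigma / sqrt(15))
  }, numeric(1))
  expect_lt(mean(ratios), 1.5)
  expect_gt(mean(ratios), 1 / 1.5)
})

test_that("the zero-phase Butterworth filter has the designed response", {
  const <- motion_trial(1, 1, matrix(7, 2, 300), 120)
  expect_lt(max(abs(lowpass(const)$angles - 7)), 1e-9)
  t <- seq(0, 2, by = 1 / 120)
  mid <- 80:160
  pass <- synspace:::lowpass_vector(sin(2 * pi * 2 * t), 120, 6, 10)
  expect_lt(1 - max(abs(pass[mid])), 0.01)       # < 1% attenuation at 2 Hz
  stopb <- synspace:::lowpass_vector(sin(2 * pi * 40 * t), 120, 6, 10)
  expect_lt(max(abs(stopb[mid])), 0.01)          # > 99% attenuation at 40 Hz
  expect_error(lowpass(const, cutoff = 60), "Nyquist")
})

test_that("normalization maps the training range onto [-1, 1] without clipping", {
  X <- rbind(a = seq(0, 90, length.out = 10), b = seq(-45, 45, length.out = 10))
  tr <- motion_trial(1, 1, X, 100)
  rec <- fit_normalization(list(tr))
  z <- apply_normalization(X, rec)
  expect_equal(unname(z["a", 1]), -1)
  expect_equal(unname(z["a", 10]), 1)
  mid <- matrix(c(45, 0), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(apply_normalization(mid, rec)[, 1]), c(0, 0))
  expect_equal(invert_normalization(z, rec), X, tolerance = 1e-9)
  probe <- matrix(c(120, 80), 2, 1, dimnames = list(c("a", "b"), NULL))
  zp <- apply_normalization(probe, rec)
  expect_gt(zp["a", 1], 1)   # outside the training range, not clipped
  expect_equal(unname(normalization_coverage(probe, rec)), c(1, 1))
  const <- motion_trial(1, 1, rbind(a = rep(1, 5), b = 1:5), 100)
  expect_error(fit_normalization(list(const)), "degenerate")
})

test_that("the source matrix concatenates normalized target blocks", {
  set.seed(1)
  mk <- function(tg) motion_trial(tg, tg,
                                  matrix(rnorm(5 * 150), 5,
                                         dimnames = list(c("SH_x", "SH_y", "SH_z",
                                                           "FA_x", "FA_y"), NULL)),
                                  120)
  avg <- lapply(1:8, mk)
  rec <- fit_normalization(avg)
  src <- assemble_source_matrix(avg, rec)
  expect_equal(dim(src$values), c(5L, 1200L))
  expect_true(all(abs(src$values) <= 1 + 1e-9))
  expect_equal(src$segment_boundaries, seq(1L, 1201L, by = 150L))
  # reading block k back and denormalizing recovers target k's trial
  blk3 <- src$values[, src$segment_boundaries[3]:(src$segment_boundaries[4] - 1L)]
  expect_equal(invert_normalization(blk3, rec), avg[[3]]$angles,
               tolerance = 1e-9)
  one <- assemble_source_matrix(avg[1], rec)
  expect_equal(one$values, apply_normalization(avg[[1]]$angles, rec))
  bad <- avg; bad[[2]] <- time_normalize(bad[[2]], 100)
  expect_error(assemble_source_matrix(bad, rec), "assembly error")
})

test_that("angular velocities are central differences scaled by the rate", {
  ch <- c("SH_x", "SH_y", "SH_z", "FA_x", "FA_y")
  X <- matrix(5, 5, 50, dimnames = list(ch, NULL))
  expect_true(all(angular_velocities(motion_trial(1, 1, X, 120)) == 0))
  ramp <- matrix(rep(seq(0, 49) * 0.3, each = 5), 5, dimnames = list(ch, NULL))
  v <- angular_velocities(motion_trial(1, 1, ramp, 120))
  expect_equal(unname(v), matrix(0.3 * 120, 3, 50), tolerance = 1e-9)
  t <- seq(0, 1, by = 1 / 120)
  X2 <- matrix(rep(sin(2 * pi * t), each = 5), 5, dimnames = list(ch, NULL))
  v2 <- angular_velocities(motion_trial(1, 1, X2, 120))
  truth <- 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1)
  h <- 1 / 120
  expect_lt(max(abs(v2["dSH_y", interior] - truth[interior])),
            (2 * pi)^3 * h^2 / 6)
  expect_error(angular_velocities(motion_trial(1, 1, X[, 1:2], 120)),
               "3 samples")
})

test_that("the preprocessing pipeline is deterministic and channel-equivariant", {
  coh <- .fixture_cache$cohort %||% generate_cohort(quick_config())
  a <- prepare_subject(coh[[1]]$training, NULL)
  b <- prepare_subject(coh[[1]]$training, NULL)
  expect_identical(a$source$values, b$source$values)
  expect_identical(a$decomp_full$loadings, b$decomp_full$loadings)
  # filtering commutes with channel relabeling
  tr <- a$trials[[1]]
  perm <- c(3, 1, 2, 5, 4)
  permuted <- motion_trial(1, 1, tr$angles[perm, ], tr$rate)
  expect_equal(lowpass(permuted)$angles, lowpass(tr)$angles[perm, ],
               tolerance = 1e-12)
})
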