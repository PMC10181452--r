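test_that("rmse pools outputs as the average of per-output MSEs", {
  x <- matrix(rnorm(20), 2)
  expect_identical(rmse(x, x), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(4)
  a <- matrix(rnorm(2 * 50), 2); p <- matrix(rnorm(2 * 50), 2)
  acc <- 0
  for (i in 1:2) for (j in 1:50) acc <- acc + (a[i, j] - p[i, j])^2
  expect_equal(rmse(a, p), sqrt(acc / 100), tolerance = 1e-12)
  # pooled rmse = sqrt(mean of per-output MSEs)
  expect_equal(rmse(a, p),
               sqrt(mean(c(mean((a[1, ] - p[1, ])^2), mean((a[2, ] - p[2, ])^2)))))
  expect_error(rmse(a, p[, 1:10]), "shape mismatch")
})

test_that("pearson matches the covariance/sd definition", {
  x <- rnorm(30)
  expect_equal(pearson(x, 2 * x), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(9)
  a <- rnorm(100); b <- rnorm(100)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), manual, tolerance = 1e-12)
  expect_error(pearson(rep(1, 10), rnorm(10)), "constant")
})

test_that("correlation strength bands assign boundaries to the stronger band", {
  expect_identical(interpret_r(0.85), "strong positive linear relationship")
  expect_identical(interpret_r(0.0), "not a linear relationship")
  expect_identical(interpret_r(-0.5), "distinct negative linear relationship")
  expect_identical(interpret_r(0.7), "strong positive linear relationship")
  expect_identical(interpret_r(-0.7), "strong negative linear relationship")
  expect_identical(interpret_r(0.1), "weak positive linear relationship")
  expect_identical(interpret_r(-0.3), "distinct negative linear relationship")
  expect_identical(interpret_r(0.05), "not a linear relationship")
  expect_error(interpret_r(1.2), "\\[-1, 1\\]")
})

test_that("group summaries report count, sum, mean and sample variance", {
  g <- group_summary(c(1, 2, 3), "toy")
  expect_equal(g$n, 3L); expect_equal(g$sum, 6)
  expect_equal(g$mean, 2); expect_equal(g$variance, 1)
  expect_equal(group_summary(rep(5, 4))$variance, 0)
  set.seed(1)
  big <- group_summary(rnorm(1000))
  expect_lt(abs(big$mean), 0.15)
  expect_lt(abs(big$variance - 1), 0.15)
  expect_error(group_summary(1), "2 values")
})

test_that("summary-based ANOVA equals the raw-data ANOVA", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(5:30, 1),
                                                   mean = rnorm(1),
                                                   sd = runif(1, 0.5, 2)))
    res <- anova_from_summaries(lapply(seq_len(k), function(j)
      group_summary(groups[[j]], paste0("g", j))))
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k), lengths(groups))))
    ref <- anova(lm(y ~ g, data = df))
    expect_equal(res$F, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
    expect_equal(res$ss_between, ref$`Sum Sq`[1], tolerance = 1e-9)
    expect_equal(res$ss_within, ref$`Sum Sq`[2], tolerance = 1e-9)
    expect_equal(res$ss_total, res$ss_between + res$ss_within,
                 tolerance = 1e-6)
  }
  equal_means <- lapply(1:3, function(j)
    group_summary_stats(paste0("g", j), n = 10, mean = 5, variance = 1 + j))
  expect_equal(anova_from_summaries(equal_means)$F, 0)
  expect_error(anova_from_summaries(list(group_summary(1:3))), "2")
})

test_that("F critical values match published quantiles", {
  expect_equal(round(f_critical(2, 39, 0.05), 3), 3.238)
  expect_equal(round(f_critical(2, 585, 0.05), 3), 3.011)
  expect_lt(f_critical(2, 39, 0.999), 0.01)  # alpha -> 1 sends the quantile to 0
  expect_error(f_critical(0, 10), "freedom")
})

test_that("Tukey HSD reproduces published Q statistics and the t reduction", {
  groups <- list(group_summary_stats("direct", 196, 11.006, 42.696),
                 group_summary_stats("one_synergy", 196, 10.336, 19.789),
                 group_summary_stats("two_synergy", 196, 9.673, 18.365))
  tk <- tukey_hsd(groups, ms_within = 26.950, df_within = 585)
  q_dir_two <- tk$Q[tk$group1 == "direct" & tk$group2 == "two_synergy"]
  expect_equal(q_dir_two, 3.593, tolerance = 0.005)
  same <- tukey_hsd(list(group_summary_stats("a", 10, 5, 1),
                         group_summary_stats("b", 10, 5, 2)),
                    ms_within = 1.5, df_within = 18)
  expect_equal(same$Q, 0)
  expect_equal(same$p, 1)
  # k = 2: the studentized range reduces to the pooled two-sample t
  for (q in c(0.5, 1.5, 3, 4.5)) for (df in c(10, 60, 585))
    expect_equal(ptukey(q, 2, df, lower.tail = FALSE),
                 2 * pt(q / sqrt(2), df, lower.tail = FALSE),
                 tolerance = 1e-6)
  uneq <- list(group_summary_stats("a", 10, 5, 1),
               group_summary_stats("b", 12, 6, 1))
  expect_error(tukey_hsd(uneq, 1, 20), "unsupported design")
})

test_that("cross-subject evaluation covers all pairs with exact self-pairs", {
  cfg <- quick_config(n_subjects = 2, seed = 77)
  coh <- generate_cohort(cfg)
  subs <- lapply(coh, function(s) prepare_subject(s$training, s$validation))
  decs <- lapply(subs, function(s) fit_decoder(s, quick_scenario("two_synergy")))
  M <- cross_subject_evaluate(subs, decs)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(length(as.numeric(M)), 2L^2)  # s^2 values per methodology
  for (s in 1:2)
    expect_equal(M[s, s], evaluate_decoder(decs[[s]], subs[[s]])$rmse,
                 tolerance = 1e-9)
  off <- cross_subject_evaluate(subs, decs, include_diagonal = FALSE)
  expect_true(all(is.na(diag(off))))
  expect_error(cross_subject_evaluate(subs, list(decs[[1]],
                                                 fit_decoder(subs[[2]],
                                                             quick_scenario("direct")))),
               "configuration error")
})

test_that("identical subjects transfer as well as they decode themselves", {
  # inter_subject_basis_sd = 0: off-diagonal RMSEs are statistically
  # indistinguishable from the diagonal across seeds
  diag_vals <- off_vals <- numeric(0)
  for (seed in 1:5) {
    cfg <- quick_config(n_subjects = 2, inter_subject_basis_sd = 0,
                        seed = 300 + seed)
    coh <- generate_cohort(cfg)
    subs <- lapply(coh, function(s) prepare_subject(s$training, s$validation))
    decs <- lapply(subs, function(s)
      fit_decoder(s, quick_scenario("two_synergy", n_hidden_layers = 1L)))
    M <- cross_subject_evaluate(subs, decs)
    diag_vals <- c(diag_vals, diag(M))
    off_vals <- c(off_vals, M[row(M) != col(M)])
  }
  pooled_sd <- sqrt((var(diag_vals) + var(off_vals)) / 2)
  expect_lt(abs(mean(off_vals) - mean(diag_vals)), 2 * pooled_sd)
})

test_that("published summary tables load from the shipped CSV", {
  g <- reported_rmse_summaries("personalized_m2_6")
  expect_length(g, 3L)
  expect_equal(vapply(g, `[[`, numeric(1), "n"), rep(14, 3))
  expect_equal(g[[1]]$mean, 6.197)
  expect_equal(reported_rmse_summaries("cross_subject_m2_6")[[1]]$variance,
               42.696)
})
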