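#' Root mean squared error, pooled over outputs
#'
#' `sqrt(mean((actual - predicted)^2))` over all outputs and time points;
#' with multiple outputs this equals the square root of the average of the
#' per-output mean squared errors.
#'
#' @param actual,predicted numeric vectors or matrices of identical shape.
#' @return nonnegative scalar (degrees when inputs are in degrees).
#' @export
rmse <- function(actual, predicted) {
  a <- as.matrix(actual); p <- as.matrix(predicted)
  if (!identical(dim(a), dim(p)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(p), collapse = "x"))
  if (length(a) < 1L) stop("need at least one sample")
  sqrt(mean((a - p)^2))
}

#' Sample Pearson correlation coefficient
#'
#' @param actual,predicted numeric vectors of equal length (>= 2), both
#'   non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(actual, predicted) {
  a <- as.numeric(actual); p <- as.numeric(predicted)
  if (length(a) != length(p)) stop("shape mismatch")
  if (length(a) < 2L) stop("need at least two samples")
  if (sd(a) == 0 || sd(p) == 0)
    stop("undefined correlation: constant input series")
  cor(a, p)
}

#' Qualitative interpretation of a correlation coefficient
#'
#' Assigns `r` to the conventional strength bands: |r| in \[0.7, 1\]
#' strong, \[0.3, 0.7) distinct, \[0.1, 0.3) weak, below 0.1 no linear
#' relationship. The published band notation overlaps at the boundaries;
#' boundary values are assigned to the band of larger |r| (so r = 0.7 is
#' "strong", r = 0.1 is "weak").
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @return a category label string.
#' @export
interpret_r <- function(r) {
  if (!is.finite(r) || abs(r) > 1) stop("r must lie in [-1, 1]")
  mag <- abs(r)
  strength <- if (mag >= 0.7) "strong"
              else if (mag >= 0.3) "distinct"
              else if (mag >= 0.1) "weak"
              else return("not a linear relationship")
  sign_lab <- if (r > 0) "positive" else "negative"
  sprintf("%s %s linear relationship", strength, sign_lab)
}

#' Descriptive summary of one group of values
#'
#' Count, sum, mean and sample variance (n-1 denominator) — the layout of
#' the published descriptive-statistics tables, and the sufficient
#' statistics for one-way ANOVA and Tukey HSD.
#'
#' @param values numeric vector (n >= 2).
#' @param label group label.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(values, label = "group") {
  if (length(values) < 2L) stop("a group needs at least 2 values")
  structure(list(label = label, n = length(values), sum = sum(values),
                 mean = mean(values), variance = var(values)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param n,mean,variance explicit summary statistics for a group whose raw
#'   values are unavailable (e.g. printed in a table); `sum` defaults to
#'   `n * mean`.
#' @export
group_summary_stats <- function(label, n, mean, variance, sum = n * mean) {
  if (n < 2L) stop("a group needs at least 2 values")
  if (variance < 0) stop("variance must be nonnegative")
  structure(list(label = label, n = as.integer(n), sum = sum, mean = mean,
                 variance = variance),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n=%d sum=%.3f mean=%.3f variance=%.3f\n",
              x$label, x$n, x$sum, x$mean, x$variance))
  invisible(x)
}

#' One-way ANOVA computed from group summaries
#'
#' Reconstructs the full one-way ANOVA table from per-group counts, means
#' and sample variances: the between-group sum of squares is
#' `sum(n_i * (m_i - grand)^2)` around the grand (weighted) mean, the
#' within-group sum of squares `sum((n_i - 1) * var_i)`; F is the ratio of
#' mean squares, with p from the upper tail of the F distribution. Applied
#' to summaries of raw groups this is identical to the raw-data ANOVA.
#'
#' @param groups list of [group_summary()] objects (>= 2 groups, each
#'   n >= 2).
#' @param alpha significance level for the critical value (default 0.05).
#' @return an object of class `anova_result` with fields `ss_between`,
#'   `ss_within`, `ss_total`, `df_between`, `df_within`, `ms_between`,
#'   `ms_within`, `F`, `p`, `F_critical`, `alpha`.
#' @export
anova_from_summaries <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2L)
  lapply(groups, function(g) stopifnot(inherits(g, "group_summary")))
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  v <- vapply(groups, `[[`, numeric(1), "variance")
  if (any(n < 2)) stop("every group needs n >= 2")
  k <- length(groups)
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * v)
  df_between <- k - 1L
  df_within <- as.integer(N - k)
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  Fstat <- ms_between / ms_within
  structure(list(
    ss_between = ss_between, ss_within = ss_within,
    ss_total = ss_between + ss_within,
    df_between = df_between, df_within = df_within,
    ms_between = ms_between, ms_within = ms_within,
    F = Fstat,
    p = pf(Fstat, df_between, df_within, lower.tail = FALSE),
    F_critical = f_critical(df_between, df_within, alpha),
    alpha = alpha,
    groups = vapply(groups, `[[`, character(1), "label")
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA from group summaries\n")
  tab <- data.frame(
    source = c("Between groups", "Within groups", "Total"),
    SS = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    MS = c(x$ms_between, x$ms_within, NA),
    F = c(x$F, NA, NA),
    p = c(x$p, NA, NA),
    F_critical = c(x$F_critical, NA, NA))
  print(tab, row.names = FALSE, digits = 4, na.print = "")
  invisible(x)
}

#' Upper critical value of the F distribution
#'
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param alpha upper-tail probability.
#' @return the `1 - alpha` quantile of F(df1, df2).
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  qf(1 - alpha, df1, df2)
}

#' Tukey HSD post hoc test from group summaries
#'
#' For each pair of groups computes the studentized-range statistic
#' `Q = |m_i - m_j| / sqrt(ms_within / n)` (equal group sizes `n`), its
#' p-value from the upper tail of the studentized range distribution with
#' `k` groups and `df_within` error degrees of freedom, and the common
#' critical value at level `alpha`. Unequal group sizes are rejected
#' (the Tukey-Kramer variant is deliberately out of scope).
#'
#' @param groups list of [group_summary()] objects with equal `n`.
#' @param ms_within within-group mean square from the ANOVA.
#' @param df_within its degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return an object of class `tukey_result`: a data frame of pairs with
#'   `Q`, `p`, plus attributes `Q_critical` and `alpha`.
#' @export
tukey_hsd <- function(groups, ms_within, df_within, alpha = 0.05) {
  stopifnot(length(groups) >= 2L, ms_within > 0)
  n <- vapply(groups, `[[`, numeric(1), "n")
  if (length(unique(n)) != 1L)
    stop("unsupported design: Tukey HSD here requires equal group sizes")
  k <- length(groups)
  m <- vapply(groups, `[[`, numeric(1), "mean")
  labs <- vapply(groups, `[[`, character(1), "label")
  se <- sqrt(ms_within / n[1L])
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    group1 = labs[pairs[1L, ]],
    group2 = labs[pairs[2L, ]],
    Q = abs(m[pairs[1L, ]] - m[pairs[2L, ]]) / se,
    stringsAsFactors = FALSE)
  out$p <- ptukey(out$Q, nmeans = k, df = df_within, lower.tail = FALSE)
  structure(out,
            Q_critical = qtukey(1 - alpha, nmeans = k, df = df_within),
            alpha = alpha,
            class = c("tukey_result", "data.frame"))
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (Q critical at alpha=%.2f: %.3f)\n",
              attr(x, "alpha"), attr(x, "Q_critical")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Score a decoder against a subject's actual forearm motion
#'
#' Decodes the requested feature set, drops the first `window - 1` samples
#' of each movement to align with the network outputs, and reports
#' per-output and pooled RMSE in degrees plus per-output Pearson
#' correlations with their qualitative interpretation.
#'
#' @param decoder a [fit_decoder()] result.
#' @param subject_data the target subject's [prepare_subject()] result
#'   (also supplies the reconstruction artifacts, so cross-subject
#'   evaluation is simply a decoder from another subject).
#' @param which evaluate on `"validation"` (default) or `"training"`
#'   movements.
#' @return an object of class `evaluation_report`.
#' @export
evaluate_decoder <- function(decoder, subject_data,
                             which = c("validation", "training")) {
  which <- match.arg(which)
  stopifnot(inherits(subject_data, "subject_data"))
  if (which == "validation" && is.null(subject_data$validation))
    stop("subject_data has no validation session")
  feats <- if (which == "validation") subject_data$validation$features
           else subject_data$features
  trials <- if (which == "validation") subject_data$validation$trials
            else subject_data$trials
  preds <- estimate_forearm(decoder, feats, artifacts = subject_data)
  w <- decoder$scenario$window
  keep <- !vapply(preds, is.null, logical(1))
  actual <- do.call(cbind, lapply(which(keep), function(i) {
    tr <- trials[[i]]
    tr$angles[FA_CHANNELS, w:ncol(tr$angles), drop = FALSE]
  }))
  predicted <- do.call(cbind, preds[keep])
  per_output <- vapply(FA_CHANNELS, function(ch)
    rmse(actual[ch, ], predicted[ch, ]), numeric(1))
  r <- vapply(FA_CHANNELS, function(ch)
    pearson(actual[ch, ], predicted[ch, ]), numeric(1))
  structure(list(
    subject_id = subject_data$subject_id,
    decoder_subject = decoder$subject_id,
    scenario = decoder$scenario,
    which = which,
    n_movements = sum(keep),
    n_samples = ncol(actual),
    rmse_per_output = per_output,
    rmse = rmse(actual, predicted),
    pearson = r,
    interpretation = vapply(r, interpret_r, character(1))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s decoder (%s) on subject %s [%s]\n",
              x$scenario$methodology, x$decoder_subject, x$subject_id, x$which))
  cat(sprintf("  pooled RMSE: %.3f deg over %d movements (%d samples)\n",
              x$rmse, x$n_movements, x$n_samples))
  for (ch in names(x$rmse_per_output))
    cat(sprintf("  %s: RMSE %.3f deg, r = %.3f (%s)\n", ch,
                x$rmse_per_output[ch], x$pearson[ch], x$interpretation[ch]))
  invisible(x)
}

#' Cross-subject transfer evaluation
#'
#' Evaluates every (target subject, source decoder) pair of a cohort:
#' entry `(A, B)` is the pooled RMSE of predicting subject A's validation
#' forearm motion with subject B's trained network, subject A's input
#' normalization records and — for the synergy methodologies — subject A's
#' synergy decomposition and channel means at reconstruction. Self-pairs
#' (A = B) are included by default so a cohort of `s` subjects yields `s^2`
#' values, matching the published design; set `include_diagonal = FALSE`
#' to restrict to true transfers.
#'
#' @param subjects list of [prepare_subject()] results.
#' @param decoders list of [fit_decoder()] results aligned with
#'   `subjects`, all sharing one scenario.
#' @param include_diagonal keep self-pairs (default TRUE).
#' @return an `s x s` matrix of pooled RMSEs (rows: target subject A,
#'   columns: decoder source B); excluded diagonals are `NA`.
#' @export
cross_subject_evaluate <- function(subjects, decoders, include_diagonal = TRUE) {
  s <- length(subjects)
  stopifnot(s >= 2L, length(decoders) == s)
  meth <- unique(vapply(decoders, function(d) d$scenario$methodology, character(1)))
  if (length(meth) != 1L)
    stop("configuration error: all decoders must share one scenario")
  M <- matrix(NA_real_, s, s,
              dimnames = list(target = vapply(subjects, `[[`, character(1), "subject_id"),
                              source = vapply(decoders, `[[`, character(1), "subject_id")))
  for (a in seq_len(s)) {
    for (b in seq_len(s)) {
      if (!include_diagonal && a == b) next
      M[a, b] <- evaluate_decoder(decoders[[b]], subjects[[a]])$rmse
    }
  }
  M
}

#' Read group summaries from CSV
#'
#' Reads a CSV with columns `label`, `n`, `mean`, `variance` (optionally
#' `sum` and a `study` column for filtering) into a list of
#' [group_summary_stats()] objects, so printed descriptive-statistics
#' tables can be fed straight into [anova_from_summaries()] and
#' [tukey_hsd()].
#'
#' @param path CSV file path.
#' @param study optional value of the `study` column to filter on.
#' @return list of `group_summary` objects.
#' @export
read_group_summaries <- function(path, study = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(study)) df <- df[df$study == study, , drop = FALSE]
  if (nrow(df) == 0L) stop("no groups found")
  lapply(seq_len(nrow(df)), function(i)
    group_summary_stats(df$label[i], df$n[i], df$mean[i], df$variance[i],
                        sum = if ("sum" %in% names(df)) df$sum[i] else df$n[i] * df$mean[i]))
}

#' Published RMSE group summaries shipped with the package
#'
#' The descriptive statistics (count, sum, mean, sample variance) of the
#' RMSE groups for the three learning methodologies, as printed for the
#' personalized evaluation (14 subjects, model M2 with 6 inputs) and the
#' two cross-subject evaluations (196 subject pairs, model M2 with 6 and
#' with 2 inputs). These are the inputs from which the package's ANOVA and
#' Tukey HSD reproduce the published statistical tables.
#'
#' @param study one of `"personalized_m2_6"`, `"cross_subject_m2_6"`,
#'   `"cross_subject_m2_2"`.
#' @return list of `group_summary` objects.
#' @export
reported_rmse_summaries <- function(study = c("personalized_m2_6",
                                              "cross_subject_m2_6",
                                              "cross_subject_m2_2")) {
  study <- match.arg(study)
  path <- system.file("extdata", "reported_rmse_summaries.csv",
                      package = "synspace", mustWork = TRUE)
  read_group_summaries(path, study = study)
}
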