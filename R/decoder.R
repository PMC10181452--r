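#' Training scenario specification
#'
#' One cell of the study's scenario grid: a learning methodology (synergy
#' space with 2 components, synergy space with 1 forearm-only component, or
#' direct forearm estimation), an LSTM depth, and an input-signal
#' combination, plus the windowing and optimization hyperparameters.
#'
#' @param methodology `"two_synergy"`, `"one_synergy"` or `"direct"`.
#' @param n_hidden_layers number of stacked LSTM layers (1, 2 or 3; the
#'   models called M1, M2, M3).
#' @param input_combo 2, 3, 4 or 6 input signals (see [select_inputs()]).
#' @param window number of previous time steps fed per prediction
#'   (default 10).
#' @param hidden_units LSTM units per layer (default 64).
#' @param dropout inter-layer dropout fraction (default 0.10).
#' @param epochs maximum training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 0.005).
#' @param val_fraction fraction of training windows held out for early
#'   stopping (default 0.1; 0 disables early stopping).
#' @param patience early-stopping patience in epochs (default 10).
#' @param seed integer seed for weight init, shuffling and dropout.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(methodology = c("two_synergy", "one_synergy", "direct"),
                          n_hidden_layers = 2L, input_combo = 6L, window = 10L,
                          hidden_units = 64L, dropout = 0.10, epochs = 100L,
                          batch_size = 32L, learning_rate = 0.005,
                          val_fraction = 0.1, patience = 10L, seed = 1L) {
  methodology <- match.arg(methodology)
  if (!n_hidden_layers %in% 1:3) stop("n_hidden_layers must be 1, 2 or 3")
  if (!input_combo %in% c(2L, 3L, 4L, 6L))
    stop("input_combo must be one of 2, 3, 4, 6")
  stopifnot_scalar_count(window, "window", min = 1L)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(
    methodology = methodology,
    n_hidden_layers = as.integer(n_hidden_layers),
    input_combo = as.integer(input_combo),
    window = as.integer(window),
    hidden_units = as.integer(hidden_units),
    dropout = dropout,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    val_fraction = val_fraction,
    patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s, %d layer(s) x %d units, %d inputs, window %d, seed %d\n",
              x$methodology, x$n_hidden_layers, x$hidden_units, x$input_combo,
              x$window, x$seed))
  invisible(x)
}

#' The full 36-cell scenario grid
#'
#' All combinations of 3 methodologies x 3 layer counts x 4 input
#' combinations, in deterministic sorted order.
#'
#' @return a data frame with columns `methodology`, `n_hidden_layers`,
#'   `input_combo`.
#' @export
scenario_grid <- function() {
  g <- expand.grid(methodology = c("direct", "one_synergy", "two_synergy"),
                   n_hidden_layers = 1:3,
                   input_combo = c(2L, 3L, 4L, 6L),
                   stringsAsFactors = FALSE)
  g <- g[order(g$methodology, g$n_hidden_layers, g$input_combo), ]
  rownames(g) <- NULL
  g
}

#' Input channel sets for each input-count scenario
#'
#' Maps the number of inputs to the shoulder signal combination used:
#' 2 = flexion-extension + abduction-adduction angles; 3 adds
#' internal-external rotation; 4 = the two angles plus their velocities;
#' 6 = all three angles and all three velocities.
#'
#' @param combo 2, 3, 4 or 6.
#' @return ordered character vector of channel names (`SH_*` angles,
#'   `dSH_*` velocities).
#' @export
select_inputs <- function(combo) {
  switch(as.character(combo),
         "2" = c("SH_y", "SH_z"),
         "3" = c("SH_x", "SH_y", "SH_z"),
         "4" = c("SH_y", "SH_z", "dSH_y", "dSH_z"),
         "6" = c("SH_x", "SH_y", "SH_z", "dSH_x", "dSH_y", "dSH_z"),
         stop("input_combo must be one of 2, 3, 4, 6"))
}

#' Build a windowed training dataset from per-movement sequences
#'
#' For each movement of length `T`, forms the `T - window + 1` sliding
#' windows of consecutive samples; example `i` covers samples
#' `[i, i + window - 1]` and its target is the sample at the window's final
#' time step. Windows never span a movement boundary; movements shorter
#' than the window contribute nothing.
#'
#' @param features list of `T_i x F` feature matrices (time in rows), one
#'   per movement.
#' @param targets list of `T_i x K` target matrices aligned with
#'   `features`.
#' @param window window length in samples.
#' @return list with `inputs` (array `window x F x N`), `targets`
#'   (`N x K`), `movement` (movement index per example) and `time_index`
#'   (window-end sample index within the movement).
#' @export
build_windows <- function(features, targets, window) {
  if (is.matrix(features)) features <- list(features)
  if (is.matrix(targets)) targets <- list(targets)
  stopifnot(length(features) == length(targets))
  window <- as.integer(window)
  counts <- vapply(features, function(f)
    max(0L, nrow(f) - window + 1L), integer(1))
  if (all(counts == 0L))
    stop("empty-dataset error: every movement is shorter than the window")
  N <- sum(counts)
  F_n <- ncol(features[[1L]])
  K <- ncol(targets[[1L]])
  inputs <- array(0, dim = c(window, F_n, N))
  targ <- matrix(0, N, K)
  movement <- integer(N)
  time_index <- integer(N)
  pos <- 0L
  for (m in seq_along(features)) {
    fm <- features[[m]]; tm <- targets[[m]]
    if (nrow(fm) != nrow(tm))
      stop("features and targets must be time-aligned per movement")
    if (counts[m] == 0L) next
    for (i in seq_len(counts[m])) {
      pos <- pos + 1L
      inputs[, , pos] <- fm[i:(i + window - 1L), , drop = FALSE]
      targ[pos, ] <- tm[i + window - 1L, ]
      movement[pos] <- m
      time_index[pos] <- i + window - 1L
    }
  }
  list(inputs = inputs, targets = targ, movement = movement,
       time_index = time_index)
}

#' Preprocess one subject's sessions into decoder-ready form
#'
#' Runs the full preprocessing chain on a training session (and optionally
#' a validation session, always mapped through the training session's
#' fitted records): segmentation, zero-phase low-pass filtering,
#' normalization-record fitting for angles and shoulder velocities,
#' time-normalized per-target averaging, source-matrix assembly, and
#' synergy extraction both for all 5 channels and for the 2 forearm
#' channels alone (the one-component methodology).
#'
#' @param training the subject's training `motion_session`.
#' @param validation optional validation `motion_session`.
#' @param speed_threshold,min_hold,smooth_cutoff,prominence segmentation
#'   settings, see [segment_trials()].
#' @param filter_order,filter_cutoff Butterworth settings, see
#'   [lowpass()].
#' @param variance_threshold cumulative explained-variance threshold for
#'   [select_components()] (default 0.85).
#' @return an object of class `subject_data` holding filtered trials,
#'   feature matrices, normalization records, the source matrix, both
#'   synergy decompositions, and (if given) the prepared validation
#'   trials/features.
#' @export
prepare_subject <- function(training, validation = NULL,
                            speed_threshold = 0.05, min_hold = 0.1,
                            smooth_cutoff = 3, prominence = 0.25,
                            filter_order = 6L, filter_cutoff = 10,
                            variance_threshold = 0.85) {
  stopifnot(inherits(training, "motion_session"))
  raw <- segment_trials(training, speed_threshold, min_hold, smooth_cutoff, prominence)
  trials <- lapply(raw, lowpass, order = filter_order, cutoff = filter_cutoff)
  norm_angles <- fit_normalization(trials, SYN_CHANNELS, role = "angles:training")
  vel_trials <- lapply(trials, function(tr)
    motion_trial(tr$trial_id, tr$target_id, angular_velocities(tr), tr$rate))
  norm_vel <- fit_normalization(vel_trials, role = "velocities:training")

  # source-matrix path: raw trials -> common length -> per-target average ->
  # filter -> normalize
  lens <- vapply(raw, function(tr) ncol(tr$angles), integer(1))
  tmax <- as.integer(round(stats::median(lens)))
  targets <- sort(unique(vapply(raw, function(tr) as.integer(tr$target_id), integer(1))))
  averaged <- lapply(targets, function(tg) {
    of_target <- Filter(function(tr) tr$target_id == tg, raw)
    avg <- average_trials(lapply(of_target, time_normalize, target_length = tmax))
    lowpass(avg, order = filter_order, cutoff = filter_cutoff)
  })
  source <- assemble_source_matrix(averaged, norm_angles)
  decomp_full <- extract_synergies(source, threshold = variance_threshold)
  fa_vals <- source$values[FA_CHANNELS, , drop = FALSE]
  decomp_forearm <- extract_synergies(fa_vals, threshold = variance_threshold)

  prep_features <- function(trs, vtrs) {
    lapply(seq_along(trs), function(i) {
      ang <- apply_normalization(trs[[i]]$angles, norm_angles)
      vel <- apply_normalization(vtrs[[i]]$angles, norm_vel)
      rbind(ang[SH_CHANNELS, , drop = FALSE], vel)
    })
  }
  features <- prep_features(trials, vel_trials)

  val <- NULL
  if (!is.null(validation)) {
    vraw <- segment_trials(validation, speed_threshold, min_hold, smooth_cutoff, prominence)
    vtrials <- lapply(vraw, lowpass, order = filter_order, cutoff = filter_cutoff)
    vvel <- lapply(vtrials, function(tr)
      motion_trial(tr$trial_id, tr$target_id, angular_velocities(tr), tr$rate))
    val <- list(trials = vtrials, features = prep_features(vtrials, vvel))
  }
  structure(list(
    subject_id = training$subject_id,
    rate = training$rate,
    trials = trials,
    features = features,
    norm_angles = norm_angles,
    norm_velocities = norm_vel,
    averaged = averaged,
    source = source,
    decomp_full = decomp_full,
    decomp_forearm = decomp_forearm,
    validation = val,
    settings = list(speed_threshold = speed_threshold, min_hold = min_hold,
                    smooth_cutoff = smooth_cutoff, filter_order = filter_order,
                    filter_cutoff = filter_cutoff,
                    variance_threshold = variance_threshold)
  ), class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data> %s: %d training trials, %d targets, %d validation trials\n",
              x$subject_id, length(x$trials),
              length(x$averaged), length(x$validation$trials %||% list())))
  cat(sprintf("  synergies retained: %d of 5 (%.1f%% variance)\n",
              x$decomp_full$n_retained,
              100 * sum(x$decomp_full$variance_fraction[seq_len(x$decomp_full$n_retained)])))
  invisible(x)
}

# Per-trial decoder targets for a methodology, as T x K matrices on the
# normalized scale (activation signals for the synergy methodologies,
# normalized forearm angles for direct estimation).
decoder_targets <- function(subject_data, methodology) {
  lapply(subject_data$trials, function(tr) {
    ang <- apply_normalization(tr$angles, subject_data$norm_angles)
    switch(methodology,
      two_synergy = t(project(subject_data$decomp_full, ang, n = 2L)),
      one_synergy = t(project(subject_data$decomp_forearm,
                              ang[FA_CHANNELS, , drop = FALSE], n = 1L)),
      direct = t(ang[FA_CHANNELS, , drop = FALSE]))
  })
}

n_outputs_for <- function(methodology) {
  switch(methodology, two_synergy = 2L, one_synergy = 1L, direct = 2L)
}

#' Fit a windowed recurrent forearm decoder for one subject
#'
#' Trains a stacked LSTM on the subject's segmented, filtered, normalized
#' training trials. Under the synergy methodologies the regression targets
#' are the activation signals obtained by projecting each trial through the
#' subject's synergy decomposition (2 components from the 5-channel
#' decomposition, or 1 component from the forearm-only decomposition);
#' under direct estimation the targets are the normalized forearm angles
#' themselves. Inputs are the scenario's shoulder angle/velocity channels
#' over a sliding window that never crosses a movement boundary.
#'
#' @param subject_data a [prepare_subject()] result.
#' @param scenario a [scenario_spec()].
#' @param averaged_only train on the 8 averaged movements instead of all
#'   raw trials (default FALSE).
#' @return an object of class `forearm_decoder` carrying the trained
#'   network, the scenario, the training history, and the subject's
#'   normalization and synergy artifacts needed for reconstruction.
#' @export
fit_decoder <- function(subject_data, scenario, averaged_only = FALSE) {
  stopifnot(inherits(subject_data, "subject_data"),
            inherits(scenario, "scenario_spec"))
  channels <- select_inputs(scenario$input_combo)
  if (averaged_only) {
    avg_vel <- lapply(subject_data$averaged, function(tr)
      motion_trial(tr$trial_id, tr$target_id, angular_velocities(tr), tr$rate))
    feats <- lapply(seq_along(subject_data$averaged), function(i) {
      ang <- apply_normalization(subject_data$averaged[[i]]$angles,
                                 subject_data$norm_angles)
      vel <- apply_normalization(avg_vel[[i]]$angles, subject_data$norm_velocities)
      rbind(ang[SH_CHANNELS, , drop = FALSE], vel)
    })
    sub <- subject_data
    sub$trials <- subject_data$averaged
    targs <- decoder_targets(sub, scenario$methodology)
  } else {
    feats <- subject_data$features
    targs <- decoder_targets(subject_data, scenario$methodology)
  }
  feats <- lapply(feats, function(f) t(f[channels, , drop = FALSE]))
  ds <- build_windows(feats, targs, scenario$window)
  fit <- cpp_lstm_train(ds$inputs, ds$targets,
                        n_layers = scenario$n_hidden_layers,
                        hidden = scenario$hidden_units,
                        dropout = scenario$dropout,
                        epochs = scenario$epochs,
                        batch_size = scenario$batch_size,
                        lr = scenario$learning_rate,
                        seed = scenario$seed,
                        val_fraction = scenario$val_fraction,
                        patience = scenario$patience)
  structure(list(
    subject_id = subject_data$subject_id,
    scenario = scenario,
    input_channels = channels,
    n_examples = nrow(ds$targets),
    weights = fit$weights,
    history = list(train_loss = fit$train_loss, val_loss = fit$val_loss,
                   best_epoch = fit$best_epoch),
    final_train_loss = fit$final_train_loss,
    norm_angles = subject_data$norm_angles,
    norm_velocities = subject_data$norm_velocities,
    decomp_full = subject_data$decomp_full,
    decomp_forearm = subject_data$decomp_forearm
  ), class = "forearm_decoder")
}

#' @export
print.forearm_decoder <- function(x, ...) {
  cat(sprintf("<forearm_decoder> %s for subject %s\n", x$scenario$methodology,
              x$subject_id))
  cat(sprintf("  %d LSTM layer(s) x %d units, inputs: %s, window %d\n",
              x$scenario$n_hidden_layers, x$scenario$hidden_units,
              paste(x$input_channels, collapse = ", "), x$scenario$window))
  cat(sprintf("  trained on %d windows; final train MSE %.3g%s\n",
              x$n_examples, x$final_train_loss,
              if (length(x$history$val_loss))
                sprintf(" (best epoch %d)", x$history$best_epoch) else ""))
  invisible(x)
}

#' @export
summary.forearm_decoder <- function(object, ...) {
  print(object)
  cat("\nTraining loss (first/last 5 epochs):\n")
  tl <- object$history$train_loss
  show <- unique(c(head(seq_along(tl), 5), tail(seq_along(tl), 5)))
  print(data.frame(epoch = show, mse = tl[show]), row.names = FALSE)
  invisible(object)
}

# Raw network outputs per movement: list of K x (T - window + 1) matrices.
decoder_outputs <- function(decoder, features) {
  window <- decoder$scenario$window
  channels <- decoder$input_channels
  lapply(features, function(f) {
    fm <- t(f[channels, , drop = FALSE])
    if (nrow(fm) < window) return(NULL)
    ds <- build_windows(list(fm),
                        list(matrix(0, nrow(fm), n_outputs_for(decoder$scenario$methodology))),
                        window)
    t(cpp_lstm_predict(decoder$weights, ds$inputs,
                       decoder$scenario$n_hidden_layers,
                       decoder$scenario$hidden_units))
  })
}

#' Estimate forearm trajectories in degrees from input features
#'
#' Applies the trained network to each movement's feature sequence and maps
#' the outputs back to forearm angles: through the 2-component (or
#' forearm-only 1-component) synergy reconstruction and denormalization for
#' the synergy methodologies, or by direct denormalization for direct
#' estimation. Reconstruction artifacts default to the decoder's own
#' subject but can be swapped for a different target subject's (the
#' cross-subject transfer protocol).
#'
#' @param decoder a [fit_decoder()] result.
#' @param features list of `6 x T` normalized feature matrices (rows
#'   `SH_*`, `dSH_*`), e.g. `subject_data$features` or
#'   `subject_data$validation$features`.
#' @param artifacts list with elements `decomp_full`, `decomp_forearm`,
#'   `norm_angles` supplying the synergy matrix, channel means and
#'   denormalization used at reconstruction; default: the decoder's own.
#' @return list, one element per movement, of `2 x (T - window + 1)`
#'   matrices of `FA_x`, `FA_y` angles in degrees aligned to the window-end
#'   time stamps (movements shorter than the window give `NULL`).
#' @export
estimate_forearm <- function(decoder, features, artifacts = NULL) {
  stopifnot(inherits(decoder, "forearm_decoder"))
  artifacts <- artifacts %||% decoder
  if (inherits(artifacts, "subject_data") || inherits(artifacts, "forearm_decoder"))
    artifacts <- list(decomp_full = artifacts$decomp_full,
                      decomp_forearm = artifacts$decomp_forearm,
                      norm_angles = artifacts$norm_angles)
  if (decoder$scenario$methodology != "direct" &&
      (is.null(artifacts$decomp_full) || is.null(artifacts$decomp_forearm)))
    stop("configuration error: synergy methodologies need a synergy decomposition")
  outs <- decoder_outputs(decoder, features)
  fa_rec <- artifacts$norm_angles
  # When a different subject's synergy matrix is substituted, align the
  # substituted components to the decoder subject's by the best orthogonal
  # transform (Procrustes on the loading columns) — the standard
  # synergy-matching step across subjects. The network predicts activation
  # signals in its own subject's component frame (sign convention and
  # within-subspace orientation), both of which are arbitrary outputs of
  # PCA; matching resolves them without touching the subspace itself.
  # Self-pairs give identical loadings, so the transform is the identity.
  component_match <- function(target_dec, source_dec, n) {
    M <- crossprod(target_dec$loadings[, seq_len(n), drop = FALSE],
                   source_dec$loadings[, seq_len(n), drop = FALSE])
    sv <- svd(M)
    sv$u %*% t(sv$v)
  }
  R2 <- component_match(artifacts$decomp_full, decoder$decomp_full, 2L)
  R1 <- component_match(artifacts$decomp_forearm, decoder$decomp_forearm, 1L)
  lapply(outs, function(o) {
    if (is.null(o)) return(NULL)
    z <- switch(decoder$scenario$methodology,
      two_synergy = reconstruct(artifacts$decomp_full, R2 %*% o, n = 2L,
                                channels = FA_CHANNELS),
      one_synergy = reconstruct(artifacts$decomp_forearm, R1 %*% o, n = 1L,
                                channels = FA_CHANNELS),
      direct = { rownames(o) <- FA_CHANNELS; o })
    rownames(z) <- FA_CHANNELS
    invert_normalization(z, fa_rec)
  })
}

#' @describeIn fit_decoder predict forearm trajectories for new data. With
#'   `newdata` a `subject_data`, decodes its validation (or training)
#'   features; with a `motion_session`, the session is prepared through the
#'   decoder subject's records first.
#' @param object a `forearm_decoder`.
#' @param newdata a [prepare_subject()] result or `motion_session`.
#' @param which `"validation"` or `"training"` features of a
#'   `subject_data`.
#' @param artifacts see [estimate_forearm()].
#' @param ... unused.
#' @export
predict.forearm_decoder <- function(object, newdata, which = c("validation", "training"),
                                    artifacts = NULL, ...) {
  which <- match.arg(which)
  if (inherits(newdata, "motion_session")) {
    raw <- segment_trials(newdata)
    trials <- lapply(raw, lowpass)
    feats <- lapply(trials, function(tr) {
      ang <- apply_normalization(tr$angles, object$norm_angles)
      vel <- apply_normalization(angular_velocities(tr), object$norm_velocities)
      rbind(ang[SH_CHANNELS, , drop = FALSE], vel)
    })
  } else if (inherits(newdata, "subject_data")) {
    feats <- if (which == "validation") {
      if (is.null(newdata$validation)) stop("subject_data has no validation session")
      newdata$validation$features
    } else newdata$features
    artifacts <- artifacts %||% newdata
  } else {
    stop("newdata must be a motion_session or subject_data")
  }
  estimate_forearm(object, feats, artifacts)
}
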