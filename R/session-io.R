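#' Write a recorded session to a directory (CSV + YAML manifest)
#'
#' The session is stored as `trials.csv` in long format (`trial_id` 0 for
#' rest samples, `target_id` NA for rest, `sample_index`, `time_s`, and the
#' five named angle columns) plus `manifest.yaml` recording channel names,
#' sampling rate, subject, role and seed. Ground truth (the generator's
#' basis, baseline and amplitudes), when supplied, goes to a `ground_truth/`
#' subdirectory so the pipeline can be run blind to it.
#'
#' @param session a `motion_session`.
#' @param dir output directory (created if needed).
#' @param ground_truth optional [ground_truth_subject()] to archive.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, ground_truth = NULL) {
  stopifnot(inherits(session, "motion_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(session$angles)
  trial_id <- integer(n)
  target_id <- rep(NA_integer_, n)
  for (k in seq_len(nrow(session$movements))) {
    idx <- session$movements$start[k]:(session$movements$end[k] - 1L)
    trial_id[idx] <- session$movements$trial_id[k]
    target_id[idx] <- session$movements$target_id[k]
  }
  df <- data.frame(trial_id = trial_id, target_id = target_id,
                   sample_index = seq_len(n),
                   time_s = (seq_len(n) - 1L) / session$rate)
  df <- cbind(df, as.data.frame(t(session$angles)))
  write.csv(df, file.path(dir, "trials.csv"), row.names = FALSE)
  manifest <- list(channels = SYN_CHANNELS,
                   sampling_rate = session$rate,
                   subject_id = session$subject_id,
                   role = session$role,
                   seed = session$seed,
                   ground_truth = if (!is.null(ground_truth)) "ground_truth/" else NULL)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(ground_truth)) {
    gt <- file.path(dir, "ground_truth")
    dir.create(gt, showWarnings = FALSE)
    write.csv(as.data.frame(ground_truth$true_basis),
              file.path(gt, "basis.csv"), row.names = FALSE)
    write.csv(data.frame(channel = SYN_CHANNELS,
                         baseline = ground_truth$baseline_posture),
              file.path(gt, "baseline.csv"), row.names = FALSE)
    write.csv(as.data.frame(ground_truth$target_amplitudes),
              file.path(gt, "amplitudes.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing `trials.csv` and `manifest.yaml`.
#' @return a `motion_session`.
#' @export
read_session <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  df <- read.csv(file.path(dir, "trials.csv"))
  angles <- t(as.matrix(df[, manifest$channels]))
  rownames(angles) <- manifest$channels
  ids <- unique(df$trial_id[df$trial_id > 0L])
  movements <- do.call(rbind, lapply(ids, function(k) {
    idx <- which(df$trial_id == k)
    data.frame(trial_id = k, target_id = df$target_id[idx[1]],
               start = idx[1], end = idx[length(idx)] + 1L)
  }))
  movements <- movements[order(movements$start), , drop = FALSE]
  rownames(movements) <- NULL
  structure(list(
    subject_id = manifest$subject_id,
    role = manifest$role,
    angles = angles,
    rate = manifest$sampling_rate,
    movements = movements,
    seed = manifest$seed
  ), class = "motion_session")
}
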