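#' Configuration for a full simulated study
#'
#' Bundles the cohort definition, the scenario grid, preprocessing
#' settings and decoder hyperparameters, under one master seed that
#' deterministically derives every stage seed (cohort generation, one
#' training seed per subject x scenario).
#'
#' @param cohort a [cohort_config()]; its own seed is replaced by one
#'   derived from `master_seed`.
#' @param grid data frame with columns `methodology`, `n_hidden_layers`,
#'   `input_combo` (default: the full 36-cell [scenario_grid()]).
#' @param window,hidden_units,dropout,epochs,batch_size,learning_rate,val_fraction,patience
#'   decoder hyperparameters shared across the grid (see
#'   [scenario_spec()]).
#' @param averaged_only train on averaged movements instead of raw trials.
#' @param speed_threshold,min_hold,smooth_cutoff,filter_order,filter_cutoff,variance_threshold
#'   preprocessing settings (see [prepare_subject()]).
#' @param master_seed integer master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              grid = scenario_grid(),
                              window = 10L, hidden_units = 64L, dropout = 0.10,
                              epochs = 100L, batch_size = 32L,
                              learning_rate = 0.005, val_fraction = 0.1,
                              patience = 10L, averaged_only = FALSE,
                              speed_threshold = 0.05, min_hold = 0.1,
                              smooth_cutoff = 3, filter_order = 6L,
                              filter_cutoff = 10, variance_threshold = 0.85,
                              master_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  stopifnot(all(c("methodology", "n_hidden_layers", "input_combo") %in% names(grid)))
  cohort$seed <- derive_seed(master_seed, "cohort")
  structure(list(
    cohort = cohort, grid = grid,
    window = as.integer(window), hidden_units = as.integer(hidden_units),
    dropout = dropout, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    val_fraction = val_fraction, patience = as.integer(patience),
    averaged_only = averaged_only,
    speed_threshold = speed_threshold, min_hold = min_hold,
    smooth_cutoff = smooth_cutoff, filter_order = as.integer(filter_order),
    filter_cutoff = filter_cutoff, variance_threshold = variance_threshold,
    master_seed = as.integer(master_seed)
  ), class = "experiment_config")
}

scenario_from_config <- function(config, methodology, n_hidden_layers,
                                 input_combo, seed) {
  scenario_spec(methodology = methodology,
                n_hidden_layers = n_hidden_layers,
                input_combo = input_combo,
                window = config$window, hidden_units = config$hidden_units,
                dropout = config$dropout, epochs = config$epochs,
                batch_size = config$batch_size,
                learning_rate = config$learning_rate,
                val_fraction = config$val_fraction, patience = config$patience,
                seed = seed)
}

prepare_cohort <- function(config) {
  cohort <- generate_cohort(config$cohort)
  lapply(cohort, function(subj)
    prepare_subject(subj$training, subj$validation,
                    speed_threshold = config$speed_threshold,
                    min_hold = config$min_hold,
                    smooth_cutoff = config$smooth_cutoff,
                    filter_order = config$filter_order,
                    filter_cutoff = config$filter_cutoff,
                    variance_threshold = config$variance_threshold))
}

#' Run the personalized (within-subject) study
#'
#' Generates the cohort, preprocesses every subject, trains one decoder per
#' subject and grid cell (stage seeds derived from the master seed), scores
#' each on the subject's own validation movements, and runs the
#' between-methodology one-way ANOVA on the pooled RMSEs of the chosen
#' comparison model (by default 2 hidden layers with 6 inputs).
#'
#' @param config an [experiment_config()].
#' @param anova_layers,anova_inputs the grid cell whose per-subject RMSEs
#'   enter the methodology ANOVA (defaults 2 and 6).
#' @param keep_models retain the trained decoders and prepared subjects in
#'   the result (default FALSE to keep the object small).
#' @return list with `reports` (one row per subject x scenario: RMSEs,
#'   correlations, final training loss), `summaries` (per-methodology
#'   [group_summary()] list), `anova` (the [anova_from_summaries()]
#'   result, `NULL` when fewer than 2 subjects), and optionally `subjects`
#'   and `decoders`.
#' @export
run_personalized <- function(config, anova_layers = 2L, anova_inputs = 6L,
                             keep_models = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  subjects <- prepare_cohort(config)
  grid <- config$grid
  rows <- vector("list", length(subjects) * nrow(grid))
  decoders <- if (keep_models) list() else NULL
  k <- 0L
  for (s in seq_along(subjects)) {
    sd_s <- subjects[[s]]
    for (g in seq_len(nrow(grid))) {
      seed <- derive_seed(config$master_seed, "train", sd_s$subject_id,
                          grid$methodology[g], grid$n_hidden_layers[g],
                          grid$input_combo[g])
      scen <- scenario_from_config(config, grid$methodology[g],
                                   grid$n_hidden_layers[g],
                                   grid$input_combo[g], seed)
      dec <- fit_decoder(sd_s, scen, averaged_only = config$averaged_only)
      rep <- evaluate_decoder(dec, sd_s, which = "validation")
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = sd_s$subject_id,
        methodology = grid$methodology[g],
        n_hidden_layers = grid$n_hidden_layers[g],
        input_combo = grid$input_combo[g],
        rmse = rep$rmse,
        rmse_FA_x = rep$rmse_per_output[["FA_x"]],
        rmse_FA_y = rep$rmse_per_output[["FA_y"]],
        r_FA_x = rep$pearson[["FA_x"]],
        r_FA_y = rep$pearson[["FA_y"]],
        train_loss = dec$final_train_loss,
        seed = seed,
        stringsAsFactors = FALSE)
      if (keep_models)
        decoders[[sprintf("%s|%s|%d|%d", sd_s$subject_id, grid$methodology[g],
                          grid$n_hidden_layers[g], grid$input_combo[g])]] <- dec
    }
  }
  reports <- do.call(rbind, rows)
  sel <- reports$n_hidden_layers == anova_layers &
    reports$input_combo == anova_inputs
  methodologies <- unique(reports$methodology[sel])
  summaries <- anova_res <- NULL
  if (length(methodologies) >= 2L && length(subjects) >= 2L) {
    summaries <- lapply(methodologies, function(m)
      group_summary(reports$rmse[sel & reports$methodology == m], label = m))
    anova_res <- anova_from_summaries(summaries)
  }
  out <- list(reports = reports, summaries = summaries, anova = anova_res,
              config = config)
  if (keep_models) {
    out$subjects <- subjects
    out$decoders <- decoders
  }
  out
}

#' Run the cross-subject transfer study
#'
#' For each requested scenario (default: the 2-layer model with 6 inputs
#' and with 2 inputs) and each methodology, trains one decoder per subject
#' and evaluates every (target, source) pair including self-pairs, then
#' summarizes the `s^2` RMSEs per methodology and runs the
#' between-methodology ANOVA followed by Tukey HSD.
#'
#' @param config an [experiment_config()].
#' @param scenarios data frame with columns `n_hidden_layers` and
#'   `input_combo`, one row per evaluated scenario.
#' @param methodologies methodologies to compare (default all three).
#' @param subjects optional pre-prepared cohort (list of
#'   [prepare_subject()] results) to reuse; default: generated from the
#'   config.
#' @return named list per scenario: `matrices` (per-methodology RMSE
#'   matrices from [cross_subject_evaluate()]), `summaries`, `anova`, and
#'   `tukey`.
#' @export
run_cross_subject <- function(config,
                              scenarios = data.frame(
                                n_hidden_layers = c(2L, 2L),
                                input_combo = c(6L, 2L)),
                              methodologies = c("direct", "one_synergy", "two_synergy"),
                              subjects = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  subjects <- subjects %||% prepare_cohort(config)
  out <- list()
  for (i in seq_len(nrow(scenarios))) {
    lay <- scenarios$n_hidden_layers[i]
    inp <- scenarios$input_combo[i]
    matrices <- list()
    summaries <- list()
    for (m in methodologies) {
      decoders <- lapply(subjects, function(sd_s) {
        seed <- derive_seed(config$master_seed, "train", sd_s$subject_id,
                            m, lay, inp)
        fit_decoder(sd_s, scenario_from_config(config, m, lay, inp, seed),
                    averaged_only = config$averaged_only)
      })
      M <- cross_subject_evaluate(subjects, decoders)
      matrices[[m]] <- M
      summaries[[m]] <- group_summary(as.numeric(M), label = m)
    }
    anova_res <- anova_from_summaries(summaries)
    tk <- tukey_hsd(summaries, anova_res$ms_within, anova_res$df_within)
    out[[sprintf("M%d_inputs%d", lay, inp)]] <-
      list(n_hidden_layers = lay, input_combo = inp, matrices = matrices,
           summaries = summaries, anova = anova_res, tukey = tk)
  }
  out
}
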