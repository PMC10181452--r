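# synspace

Synergy-space recurrent decoding of forearm motion from residual shoulder
kinematics, for movement neuroscience and rehabilitation-engineering work on
upper-limb prosthesis control.

After a transhumeral amputation the user retains shoulder motion but no
elbow or forearm. This package implements the synergy-space decoding
strategy for estimating the two missing distal angles — elbow
flexion–extension and forearm pronation–supination — from the three
recorded shoulder orientation angles (and optionally their velocities)
during planar reaching:

1. **Spatial synergy extraction.** The preprocessed training data
   (segmented, per-target averaged, 6th-order zero-phase Butterworth
   filtered at 10 Hz, min–max normalized to [−1, 1]) form a
   channels-by-time matrix *X* that is factorized by PCA as *X ≈ W·C*,
   where the columns of *W* are spatial synergy loadings and the rows of
   *C* their activation signals; the factorization minimizes the Frobenius
   error ‖X − W·C‖_F at fixed rank. Components are retained until the
   cumulative explained variance exceeds 85% (two, in practice).
2. **Windowed recurrent regression.** A stacked LSTM (1–3 layers, 10%
   inter-layer dropout, Adam on MSE, 10-previous-time-step input windows)
   predicts the activation signals from shoulder kinematics — or the
   forearm angles directly, in the baseline "direct estimation"
   methodology.
3. **Reconstruction.** Predicted activations are pushed through the
   forearm rows of *W* and denormalized to degrees.
4. **Evaluation and statistics.** RMSE (pooled over outputs) and Pearson
   correlations per subject; cross-subject transfer over all
   (target, source) subject pairs with the target subject's synergy
   matrix substituted at reconstruction; one-way ANOVA computed from group
   summaries and Tukey HSD post hoc tests on the studentized range
   distribution — runnable directly from printed descriptive-statistics
   tables as well as from raw RMSE groups.

Because no human recordings are distributed with the method, the package
includes a first-class synthetic cohort generator (`generate_cohort()`)
emulating the study design — 8 reaching targets × 15 training repetitions
plus 35 random-target validation movements per subject at 120 Hz, with a
known low-rank synergy structure — so every stage is testable end to end
against ground truth. See the vignette
(`vignettes/synergy-space-decoding.Rmd`) for the model, the generator's
assumptions, and all numerical choices.

## Worked example

```r
library(synspace)
cfg <- cohort_config(n_subjects = 2, n_targets = 6, n_train_trials_per_target = 8,
                     n_validation_movements = 12, sampling_rate = 60,
                     noise_sd = 1, seed = 20)
cohort <- generate_cohort(cfg)
subject <- prepare_subject(cohort[[1]]$training, cohort[[1]]$validation)
subject
#> <subject_data> S01: 48 training trials, 6 targets, 12 validation trials
#>   synergies retained: 2 of 5 (100.0% variance)

scen <- scenario_spec("two_synergy", n_hidden_layers = 2, input_combo = 6,
                      hidden_units = 16, epochs = 15, batch_size = 64,
                      learning_rate = 0.01, val_fraction = 0, seed = 3)
decoder <- fit_decoder(subject, scen)
evaluate_decoder(decoder, subject)
#> <evaluation_report> two_synergy decoder (S01) on subject S01 [validation]
#>   pooled RMSE: 0.944 deg over 12 movements (1014 samples)
#>   FA_x: RMSE 1.026 deg, r = 0.988 (strong positive linear relationship)
#>   FA_y: RMSE 0.855 deg, r = 0.997 (strong positive linear relationship)
```

The report gives validation-set accuracy in degrees for pronation–
supination (`FA_x`) and elbow flexion–extension (`FA_y`): here the
two-synergy decoder tracks both angles to about 1° with strong linear
correlation, i.e. the two retained synergies carry essentially all of this
synthetic subject's forearm motion.

The statistics layer consumes printed descriptive tables directly:

```r
anova_from_summaries(reported_rmse_summaries("cross_subject_m2_6"))
#> One-way ANOVA from group summaries
#>          source      SS  df    MS     F       p F_critical
#>  Between groups   174.1   2 87.07 3.231 0.04023      3.011
#>   Within groups 15765.8 585 26.95
#>           Total 15939.9 587
```

An F of 3.23 above the critical 3.011 (p ≈ 0.04) says the three learning
methodologies differ significantly in cross-subject transfer; `tukey_hsd()`
then localizes the difference to direct estimation versus the two-synergy
decoder.

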