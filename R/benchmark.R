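# Desk-scale end-to-end experiment on the synthetic cohort: generate
# subjects, run the full preprocessing pipeline, build balanced bundles,
# and evaluate the Siamese model under stratified k-fold cross-validation.

#' Run the synthetic end-to-end verification experiment
#'
#' Generates `n_subjects` synthetic subjects, synthesizes one record per
#' subject long enough to hold `beats_per_subject` usable beats, runs
#' R-peak detection, segmentation and DFT featurization, keeps the first
#' `beats_per_subject` feature matrices per subject, builds
#' `n_pos + n_neg` balanced bundles and evaluates the ensemble Siamese
#' model with stratified `k`-fold cross-validation. All randomness derives
#' from `seed`.
#'
#' Default sizes (20 subjects, 30 beats each, 400 bundles, 2 folds, 15
#' epochs) are chosen so the whole experiment runs in minutes on one CPU
#' while leaving the verification task non-trivial.
#'
#' @param seed Master integer seed.
#' @param n_subjects Number of synthetic subjects.
#' @param beats_per_subject Feature matrices kept per subject.
#' @param n_ref References per bundle.
#' @param n_pos,n_neg Positive / negative bundle counts.
#' @param k Cross-validation folds.
#' @param epochs Training epochs per fold.
#' @param preset Preprocessing preset (see [ecg_preset()]).
#' @param noise_sd,rr_jitter_sd,baseline_amp Cohort noise settings, passed
#'   to [sample_subjects()].
#' @param verbose Print progress.
#' @return The [crossval()] `eval_report`, with the segment dataset and
#'   bundles attached as attributes `dataset` and `bundles`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_subjects = 20L,
                                    beats_per_subject = 30L, n_ref = 3L,
                                    n_pos = 200L, n_neg = 200L, k = 2L,
                                    epochs = 15L, preset = "ecgid-like",
                                    noise_sd = 0.02, rr_jitter_sd = 0.02,
                                    baseline_amp = 0.05, verbose = FALSE) {
  dataset <- synth_segment_dataset(seed, n_subjects, beats_per_subject,
                                   preset, noise_sd, rr_jitter_sd,
                                   baseline_amp)
  bundles <- build_bundles(dataset, n_ref = n_ref, n_pos = n_pos,
                           n_neg = n_neg, seed = seed + 1L)
  folds <- kfold(bundles, k = k, seed = seed + 2L)
  config <- esn_config(epochs = epochs, seed = seed + 3L)
  report <- crossval(bundles, folds, config, verbose = verbose)
  attr(report, "dataset") <- dataset
  attr(report, "bundles") <- bundles
  report
}

#' Build a per-subject feature-matrix dataset from synthetic records
#'
#' Full pipeline (simulate, detect R peaks, segment, featurize), keeping at
#' most `beats_per_subject` segments per subject. Record durations are
#' sized per subject from its mean RR interval so enough interior beats
#' exist.
#'
#' @inheritParams run_synthetic_benchmark
#' @return Named list mapping subject id to a list of L x 2 feature
#'   matrices, as consumed by [build_bundles()].
#' @export
synth_segment_dataset <- function(seed = 1L, n_subjects = 20L,
                                  beats_per_subject = 30L,
                                  preset = "ecgid-like", noise_sd = 0.02,
                                  rr_jitter_sd = 0.02, baseline_amp = 0.05) {
  ps <- ecg_preset(preset)
  subjects <- sample_subjects(n_subjects, fs = ps$fs, seed = seed,
                              noise_sd = noise_sd,
                              rr_jitter_sd = rr_jitter_sd,
                              baseline_amp = baseline_amp)
  dataset <- list()
  for (i in seq_along(subjects)) {
    sp <- subjects[[i]]
    duration <- (beats_per_subject + 4) * sp$mean_rr
    rec <- synth_record(sp, duration = duration, fs = ps$fs,
                        seed = seed * 1000L + i)
    fms <- preprocess_record(rec, L = ps$L)
    if (length(fms) > beats_per_subject) fms <- fms[seq_len(beats_per_subject)]
    dataset[[sp$subject_id]] <- fms
  }
  dataset
}
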