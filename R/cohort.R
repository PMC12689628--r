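#' Run the spectral pipeline for one synthetic animal
#'
#' Generates a one-day hypnogram, synthesizes EEG/EMG for a
#' phase-balanced subset of its epochs (epochs sampled evenly across
#' the light and the dark phase, which keeps the day-1 light reference
#' states represented while bounding compute), scores the recording
#' with the rule-based scorer, and returns the dark-phase
#' cross-state-normalized NREM delta power.
#'
#' @param profile a [spectral_profile()].
#' @param seed integer seed for this animal.
#' @param epochs_per_phase epochs synthesized per phase (default 300).
#' @param band delta band (default SWA 1.0-4.5 Hz).
#' @param use_scorer score states from the signal (default) instead of
#'   using the generating hypnogram.
#' @return list: `ndelta_dark` (normalized NREM delta power, %),
#'   `agreement` (scored-vs-truth epoch agreement).
#' @export
animal_ndelta_dark <- function(profile = spectral_profile(), seed = 1L,
                               epochs_per_phase = 300L,
                               band = band_def("delta_swa"),
                               use_scorer = TRUE) {
  hyp_full <- gen_hypnogram(hypnogram_params(days = 1, seed = seed))
  light <- which(hyp_full$zt_phase == "light")
  dark <- which(hyp_full$zt_phase == "dark")
  pick <- function(ix) ix[unique(round(seq(1, length(ix),
                                           length.out = epochs_per_phase)))]
  hyp <- subset_hypnogram(hyp_full, c(pick(light), pick(dark)))

  rec <- gen_eeg_emg(hyp, profile, fs = 128, seed = seed + 1L,
                     channels = "parietal")
  spec <- rebin(epoch_psd(rec, channel = "parietal"))
  scored <- score(rec)
  hyp_used <- hyp
  if (use_scorer) hyp_used$state <- scored$state

  norm <- normalize_cross_state(spec, hyp_used, phase = "dark", day = 1)
  ix <- which(attr(norm, "bin_hz") >= band$lo - 1e-9 &
                attr(norm, "bin_hz") <= band$hi + 1e-9)
  list(ndelta_dark = mean(norm["NREM", ix]),
       agreement = epoch_agreement(scored, hyp))
}

#' Cohort-level detection of a programmed NREM delta reduction
#'
#' Simulates paired cohorts (default n = 8 vs 8) in which one group's
#' NREM delta-bump power is reduced by `reduction` (default 20%), runs
#' the full signal pipeline per animal, and per replicate records
#' whether the reduced group's mean dark-phase normalized NREM delta
#' power falls below the control group's (the programmed direction).
#'
#' @param n_replicates simulation replicates (default 100).
#' @param n_per_group animals per group (default 8).
#' @param reduction fractional NREM delta-bump reduction (default 0.2).
#' @param epochs_per_phase per-animal epochs per phase (default 300).
#' @param seed master seed; per-animal seeds derive from it.
#' @return list: `direction_rate` (fraction of replicates separating
#'   in the programmed direction), `diffs` (control minus reduced
#'   group mean, per replicate).
#' @export
cohort_delta_experiment <- function(n_replicates = 100L, n_per_group = 8L,
                                    reduction = 0.2,
                                    epochs_per_phase = 300L, seed = 1L) {
  prof_ctrl <- spectral_profile()
  states <- default_state_profiles()
  states$NREM$bumps$power <- states$NREM$bumps$power * (1 - reduction)
  prof_red <- spectral_profile(states)

  seeds <- with_seed(seed, matrix(sample.int(2^30, n_replicates *
                                               2 * n_per_group),
                                  nrow = n_replicates))
  diffs <- vapply(seq_len(n_replicates), function(rep_i) {
    s <- seeds[rep_i, ]
    ctrl <- vapply(seq_len(n_per_group), function(a)
      animal_ndelta_dark(prof_ctrl, seed = s[a],
                         epochs_per_phase = epochs_per_phase)$ndelta_dark,
      numeric(1))
    red <- vapply(seq_len(n_per_group), function(a)
      animal_ndelta_dark(prof_red, seed = s[n_per_group + a],
                         epochs_per_phase = epochs_per_phase)$ndelta_dark,
      numeric(1))
    mean(ctrl) - mean(red)
  }, numeric(1))
  list(direction_rate = mean(diffs > 0), diffs = diffs)
}
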