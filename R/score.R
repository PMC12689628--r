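#' Rule-based vigilance-state scoring
#'
#' A transparent rule-based stand-in for machine-learning sleep
#' scorers.  Per 4-s epoch: WAKE if the EMG RMS exceeds `k_emg` times
#' the recording's median epoch EMG RMS; otherwise the epoch is
#' classified from the EEG theta(6-9 Hz)/delta(1.0-4.5 Hz) power
#' ratio: REM if the ratio >= `rem_ratio` (rhythmic theta activity),
#' NREM if the ratio <= `nrem_ratio` (high-amplitude slow waves), and
#' TREM (transition to REM: mixed slow-wave and theta activity) in
#' between.
#'
#' @param rec preprocessed 128 Hz [recording()].
#' @param channel EEG channel used for the spectral rules.
#' @param k_emg WAKE threshold as a multiple of the median epoch EMG
#'   RMS (default 1.5).
#' @param rem_ratio theta/delta ratio at or above which a low-EMG epoch
#'   is REM (default 2.0).
#' @param nrem_ratio theta/delta ratio at or below which a low-EMG
#'   epoch is NREM (default 1.0).
#' @return A `hypnogram` (phases derived from `rec$start_zt`).
#' @export
score <- function(rec, channel = "parietal", k_emg = 1.5,
                  rem_ratio = 2.0, nrem_ratio = 1.0) {
  stop_if_not(inherits(rec, "recording"), "rec must be a recording")
  n_ep <- n_epochs(rec)
  stop_if_not(n_ep >= 1, "recording shorter than one 4-s epoch")
  N <- as.integer(rec$fs * EPOCH_S)

  emg_rms <- sqrt(colMeans(matrix(rec$emg[seq_len(n_ep * N)], nrow = N)^2))
  wake <- emg_rms > k_emg * stats::median(emg_rms)

  spec <- rebin(epoch_psd(rec, channel = channel))
  ix_d <- band_bins(spec, band_def("delta_swa"))
  ix_t <- band_bins(spec, band_def("theta"))
  ratio <- rowMeans(spec[, ix_t, drop = FALSE]) /
    rowMeans(spec[, ix_d, drop = FALSE])

  states <- ifelse(wake, "WAKE",
            ifelse(ratio >= rem_ratio, "REM",
            ifelse(ratio <= nrem_ratio, "NREM", "TREM")))
  as_hypnogram(states, start_zt = rec$start_zt)
}

#' Sleep-architecture summary
#'
#' Minutes per vigilance state per light/dark phase per day (4 s per
#' epoch), plus per-phase total sleep and the percentage of total
#' sleep occurring in the light phase.  TREM epochs count toward total
#' REM sleep durations (reported as `REM_incl_trem`) and toward total
#' sleep; they are also listed separately.
#'
#' @param hyp a `hypnogram` with phase labels.
#' @return list with `minutes` (data.frame day x phase x state),
#'   `sleep_minutes` (per day/phase), `pct_sleep_in_light`.
#' @export
architecture <- function(hyp) {
  stop_if_not(inherits(hyp, "hypnogram"), "hyp must be a hypnogram")
  tab <- as.data.frame(table(day = hyp$day_index, phase = hyp$zt_phase,
                             state = hyp$state), stringsAsFactors = FALSE)
  tab$minutes <- tab$Freq * EPOCH_S / 60
  tab$Freq <- NULL
  wide <- stats::reshape(tab, idvar = c("day", "phase"),
                         timevar = "state", direction = "wide")
  names(wide) <- sub("^minutes\\.", "", names(wide))
  for (s in VIGILANCE_STATES) if (!s %in% names(wide)) wide[[s]] <- 0
  wide$REM_incl_trem <- wide$REM + wide$TREM
  wide$sleep <- wide$NREM + wide$REM + wide$TREM
  rownames(wide) <- NULL

  sleep_light <- sum(wide$sleep[wide$phase == "light"])
  sleep_total <- sum(wide$sleep)
  list(minutes = wide,
       sleep_minutes = wide[, c("day", "phase", "sleep")],
       pct_sleep_in_light = if (sleep_total > 0)
         100 * sleep_light / sleep_total else NA_real_)
}

#' Per-epoch agreement between two hypnograms
#'
#' @param scored,truth hypnograms of equal length.
#' @return fraction of epochs with identical state labels.
#' @export
epoch_agreement <- function(scored, truth) {
  stop_if_not(nrow(scored) == nrow(truth), "hypnogram lengths differ")
  mean(as.character(scored$state) == as.character(truth$state))
}
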