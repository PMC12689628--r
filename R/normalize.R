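#' Cross-state spectral normalization
#'
#' For each frequency bin, state-specific mean power is expressed as a
#' percentage of the summed power of that bin across NREM sleep, REM
#' sleep, and wakefulness in the 12-h light phase of recording day 1.
#' This reference accounts for inter-individual differences in both
#' absolute spectra and time spent in each state while preserving
#' between-state contrasts.  TREM epochs are excluded from all state
#' spectra.
#'
#' By default the reference "summed power" is the sum of the three
#' state means over the reference window (`reference = "state_mean"`);
#' `reference = "pooled"` instead divides by the mean over all
#' reference epochs pooled regardless of state.
#'
#' @param spec `binned_spectra` (epoch x 30 bins).
#' @param hyp matching `hypnogram`.
#' @param phase,day window whose state spectra are normalized
#'   (defaults: the reference window itself, light phase of day 1).
#' @param reference `"state_mean"` (default) or `"pooled"`.
#' @return matrix (3 states x 30 bins) of percentages.
#' @export
normalize_cross_state <- function(spec, hyp, phase = "light", day = 1,
                                  reference = c("state_mean", "pooled")) {
  reference <- match.arg(reference)
  stop_if_not(nrow(spec) == nrow(hyp), "spectra and hypnogram must align")
  states <- c("NREM", "REM", "WAKE")

  ref_sel <- hyp$zt_phase == "light" & hyp$day_index == 1
  ref_means <- state_mean_spectra(spec, hyp, states, ref_sel)
  missing <- states[!states %in% rownames(ref_means)]
  stop_if_not(length(missing) == 0,
              "reference window (day-1 light phase) lacks state(s): %s",
              paste(missing, collapse = ", "))
  denom <- if (reference == "state_mean") colSums(ref_means)
  else {
    # pooled reading of the reference: mean over all day-1 light-phase
    # WAKE/NREM/REM epochs regardless of state (TREM still excluded);
    # the sum-to-100% identity holds only for "state_mean"
    pool <- ref_sel & hyp$state %in% states
    colMeans(spec[pool, , drop = FALSE])
  }

  q_sel <- hyp$zt_phase == phase & hyp$day_index == day
  q_means <- state_mean_spectra(spec, hyp, states, q_sel)
  out <- matrix(NA_real_, length(states), ncol(spec),
                dimnames = list(states, colnames(spec)))
  out[rownames(q_means), ] <- sweep(q_means, 2, denom, "/") * 100
  attr(out, "bin_hz") <- attr(spec, "bin_hz")
  out
}

# mean spectrum per state over selected epochs; states absent from the
# selection are dropped (rownames say which are present)
state_mean_spectra <- function(spec, hyp, states, sel) {
  res <- lapply(states, function(s) {
    ix <- sel & hyp$state == s
    if (!any(ix)) NULL else colMeans(spec[ix, , drop = FALSE])
  })
  keep <- !vapply(res, is.null, logical(1))
  m <- do.call(rbind, res[keep])
  rownames(m) <- states[keep]
  m
}

#' Within-state spectral normalization
#'
#' Each bin's mean power in the given state is expressed as a
#' percentage of the total power (sum over all 30 bins) of that same
#' state, so the profile sums to 100% over bins.
#'
#' @inheritParams normalize_cross_state
#' @param state one of WAKE/NREM/REM.
#' @return named numeric vector (30 bins, percentages summing to 100).
#' @export
normalize_within_state <- function(spec, hyp, state = "NREM",
                                   phase = "light", day = 1) {
  stop_if_not(nrow(spec) == nrow(hyp), "spectra and hypnogram must align")
  stop_if_not(state %in% c("WAKE", "NREM", "REM"),
              "state must be WAKE/NREM/REM (TREM is excluded)")
  sel <- hyp$zt_phase == phase & hyp$day_index == day & hyp$state == state
  stop_if_not(any(sel), "state %s absent in the requested window", state)
  m <- colMeans(spec[sel, , drop = FALSE])
  out <- 100 * m / sum(m)
  attr(out, "bin_hz") <- attr(spec, "bin_hz")
  out
}

#' Slow-wave-activity timecourse
#'
#' NREM delta power per time interval, normalized to the mean NREM
#' delta power during the last four hours of the light period (ZT8-12)
#' of recording day 1, in percent.  Intervals containing no NREM
#' epochs are reported as `NA`.
#'
#' @param spec `binned_spectra`; @param hyp matching `hypnogram`.
#' @param interval_h interval length in hours (must divide 24).
#' @param band delta band (default SWA, 1.0-4.5 Hz; configurable).
#' @return data.frame with `interval_start_h` (hours from recording
#'   start), `swa_pct`, `n_nrem_epochs`.
#' @export
swa_timecourse <- function(spec, hyp, interval_h = 1,
                           band = band_def("delta_swa")) {
  stop_if_not(nrow(spec) == nrow(hyp), "spectra and hypnogram must align")
  ix <- band_bins(spec, band)
  delta <- rowMeans(spec[, ix, drop = FALSE])
  nrem <- hyp$state == "NREM"

  # reference: ZT8-12 of day 1; true zeitgeber time is carried by the
  # hypnogram where present (subsets), else derived from epoch index
  zt_h <- if (!is.null(hyp$zt_h)) hyp$zt_h
          else (hyp$epoch_index - 1) * EPOCH_S / 3600
  ref <- nrem & hyp$day_index == 1 & (zt_h %% 24) >= 8 & (zt_h %% 24) < 12
  stop_if_not(any(ref),
              "no NREM epochs in the ZT8-12 day-1 reference window")
  ref_mean <- mean(delta[ref])

  iv <- floor(zt_h / interval_h)
  starts <- sort(unique(iv))
  res <- lapply(starts, function(k) {
    sel <- nrem & iv == k
    data.frame(interval_start_h = k * interval_h,
               swa_pct = if (any(sel)) 100 * mean(delta[sel]) / ref_mean
                         else NA_real_,
               n_nrem_epochs = sum(sel))
  })
  do.call(rbind, res)
}
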