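#' Per-epoch Welch power spectral density at 0.25 Hz resolution
#'
#' EEG spectral power for consecutive 4-s epochs.  At 128 Hz a 4-s
#' epoch holds exactly 512 samples, so a 0.25 Hz-resolution Welch
#' estimate with non-overlapping Hann-windowed segments degenerates to
#' a single windowed periodogram per epoch; that is what is computed,
#' with the standard window power correction (sum of squared window
#' weights) so that the PSD integrates to signal variance.  A trailing
#' partial epoch is dropped.
#'
#' @param rec a preprocessed [recording()] at 128 Hz.
#' @param channel EEG channel name (default `"parietal"`, falling back
#'   to the first channel if absent).
#' @param epoch_s epoch length in seconds (fixed 4).
#' @return A matrix (epochs x 0.25 Hz bins) of one-sided PSD values;
#'   column names are the bin frequencies `0.25, 0.5, ..., 64` Hz.
#' @export
epoch_psd <- function(rec, channel = "parietal", epoch_s = EPOCH_S) {
  stop_if_not(inherits(rec, "recording"), "rec must be a recording")
  stop_if_not(rec$fs == 128,
              "epoch_psd expects a 128 Hz recording; run preprocess() first")
  stop_if_not(epoch_s == EPOCH_S, "epoch length is fixed at 4 s")
  if (!channel %in% names(rec$eeg)) channel <- names(rec$eeg)[1]
  x <- rec$eeg[[channel]]
  N <- as.integer(rec$fs * epoch_s)  # 512 samples, 0.25 Hz resolution
  n_ep <- length(x) %/% N
  stop_if_not(n_ep >= 1, "recording shorter than one epoch")
  xm <- matrix(x[seq_len(n_ep * N)], nrow = N)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(N) / N))  # periodic Hann window
  X <- stats::mvfft(xm * w)
  half <- N %/% 2L
  # one-sided PSD: 2|X|^2 / (fs * sum(w^2)), no doubling at Nyquist
  scale <- 1 / (rec$fs * sum(w^2))
  p <- Mod(X[2:(half + 1L), , drop = FALSE])^2 * scale
  p[seq_len(half - 1L), ] <- 2 * p[seq_len(half - 1L), ]
  p <- t(p)
  colnames(p) <- as.character((1:half) * rec$fs / N)
  attr(p, "df") <- rec$fs / N
  attr(p, "channel") <- channel
  p
}

#' Re-bin 0.25 Hz spectra into the hybrid 0.5/1 Hz scheme
#'
#' Adjacent 0.25 Hz bins are averaged into 0.5 Hz bins for 0.5-5 Hz
#' (10 bins) and groups of four into 1 Hz bins spanning 5.25-25 Hz
#' (20 bins), 30 bins total.  Bin labels are upper edges: a 0.5 Hz bin
#' labelled f averages the quarter-bins at f-0.25 and f; a 1 Hz bin
#' labelled g averages the quarter-bins at g-0.75 .. g.
#'
#' @param raw an epoch x 0.25 Hz-bin matrix from [epoch_psd()].
#' @return A `binned_spectra`: epoch x 30-bin matrix with numeric
#'   upper-edge labels `0.5, 1, ..., 5, 6, 7, ..., 25` as an attribute
#'   `bin_hz` (and as column names).
#' @export
rebin <- function(raw) {
  df <- attr(raw, "df")
  stop_if_not(!is.null(df) && isTRUE(all.equal(df, 0.25)),
              "input must be 0.25 Hz-resolution spectra from epoch_psd()")
  qf <- (seq_len(ncol(raw))) * 0.25
  stop_if_not(max(qf) >= 25, "input spectra must cover at least 25 Hz")
  labels <- c(seq(0.5, 5, by = 0.5), 6:25)
  members <- lapply(labels, function(lb) {
    if (lb <= 5) which(abs(qf - lb) < 1e-9 | abs(qf - (lb - 0.25)) < 1e-9)
    else which(qf > lb - 1 + 1e-9 & qf < lb + 1e-9 | abs(qf - lb) < 1e-9)
  })
  out <- vapply(members, function(ix) rowMeans(raw[, ix, drop = FALSE]),
                numeric(nrow(raw)))
  if (nrow(raw) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- as.character(labels)
  attr(out, "bin_hz") <- labels
  attr(out, "channel") <- attr(raw, "channel")
  class(out) <- c("binned_spectra", class(out))
  out
}

#' Band definitions used in the analyses
#'
#' delta_swa 1.0-4.5 Hz (slow-wave activity), delta_sig 1.5-4.5 Hz,
#' sigma 10-15 Hz, theta 6-9 Hz.  Membership is inclusive at both
#' edges in bin-label space.
#'
#' @param name one of `"delta_swa"`, `"delta_sig"`, `"sigma"`,
#'   `"theta"`, or `"custom"`.
#' @param lo,hi band edges in Hz (used when `name = "custom"`).
#' @return list with `name`, `lo`, `hi`.
#' @export
band_def <- function(name = c("delta_swa", "delta_sig", "sigma", "theta",
                              "custom"), lo = NULL, hi = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
    delta_swa = c(1.0, 4.5), delta_sig = c(1.5, 4.5),
    sigma = c(10, 15), theta = c(6, 9), custom = c(lo, hi))
  stop_if_not(length(edges) == 2 && edges[1] < edges[2],
              "band needs lo < hi")
  list(name = name, lo = edges[1], hi = edges[2])
}

band_bins <- function(spec, band) {
  labels <- attr(spec, "bin_hz")
  ix <- which(labels >= band$lo - 1e-9 & labels <= band$hi + 1e-9)
  stop_if_not(length(ix) > 0, "band %g-%g Hz resolves to no bins",
              band$lo, band$hi)
  ix
}

#' Band power per epoch and per phase
#'
#' Mean binned power over the bins whose labels fall inside the band,
#' restricted to epochs of the given state.  TREM epochs never
#' contribute to NREM or REM spectra (they are excluded from spectral
#' analysis), so `state` must be one of WAKE/NREM/REM.
#'
#' @param spec a `binned_spectra`; @param hyp matching `hypnogram`;
#' @param band a [band_def()]; @param state vigilance state.
#' @param phase optionally restrict to `"light"` or `"dark"` epochs.
#' @param day optionally restrict to one recording day.
#' @return list with `epoch` (value per selected epoch, named by epoch
#'   index) and `mean` (their mean; `NA` if no epochs selected).
#' @export
band_power <- function(spec, hyp, band = band_def("delta_swa"),
                       state = "NREM", phase = NULL, day = NULL) {
  stop_if_not(nrow(spec) == nrow(hyp),
              "spectra (%d epochs) and hypnogram (%d) must align",
              nrow(spec), nrow(hyp))
  stop_if_not(state %in% c("WAKE", "NREM", "REM"),
              "band power is defined for WAKE/NREM/REM (TREM is excluded)")
  ix <- band_bins(spec, band)
  sel <- hyp$state == state
  if (!is.null(phase)) sel <- sel & hyp$zt_phase == phase
  if (!is.null(day)) sel <- sel & hyp$day_index == day
  vals <- rowMeans(spec[sel, ix, drop = FALSE])
  names(vals) <- hyp$epoch_index[sel]
  list(epoch = vals, mean = if (length(vals)) mean(vals) else NA_real_)
}
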