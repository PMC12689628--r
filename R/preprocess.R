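#' Band-pass filter and decimate a raw recording
#'
#' Applies a zero-phase band-pass to each channel (default 0.1-48 Hz
#' for EEG, 10-30 Hz for EMG) and decimates to `fs_out` (default
#' 128 Hz) with anti-alias filtering.  The band-pass is realized as a
#' 4th-order Butterworth high-pass followed by a 4th-order Butterworth
#' low-pass, each factored into second-order sections and run
#' forward-backward (zero phase).  The cascade of biquads is required
#' for numerical stability: at a 0.1 Hz edge on a 512 Hz signal the
#' direct-form transfer function has poles too close to the unit
#' circle for double-precision filtering.
#'
#' @param raw a [recording()].
#' @param eeg_band,emg_band numeric length-2 pass bands in Hz.
#' @param fs_out output sampling rate; must divide `raw$fs`.
#' @return A `recording` at `fs_out`.
#' @export
preprocess <- function(raw, eeg_band = c(0.1, 48), emg_band = c(10, 30),
                       fs_out = 128) {
  stop_if_not(inherits(raw, "recording"), "raw must be a recording")
  fs <- raw$fs
  stop_if_not(fs >= 2 * eeg_band[2], "EEG band edge above Nyquist")
  stop_if_not(fs >= 2 * emg_band[2], "EMG band edge above Nyquist")
  stop_if_not(fs %% fs_out == 0, "fs_out (%g) must divide fs (%g)", fs_out, fs)
  q <- as.integer(fs / fs_out)

  eeg <- lapply(raw$eeg, bandpass_decimate, fs = fs, band = eeg_band, q = q)
  emg <- bandpass_decimate(raw$emg, fs = fs, band = emg_band, q = q)
  recording(eeg = eeg, emg = emg, fs = fs_out, start_zt = raw$start_zt)
}

# 4th-order Butterworth as second-order sections (conjugate pole
# pairs; zeros at z = 1 for high-pass, z = -1 for low-pass), each
# section normalized to unit gain at its reference frequency
butter_sos <- function(n, W, type) {
  zp <- signal::as.Zpg(signal::butter(n, W, type = type))
  p <- zp$p[Im(zp$p) >= 0]
  stop_if_not(length(p) * 2 == length(zp$p),
              "expected conjugate pole pairs (even filter order)")
  lapply(p, function(pk) {
    a <- c(1, -2 * Re(pk), Mod(pk)^2)
    if (type == "high") {
      b <- c(1, -2, 1)
      g <- sum(a * c(1, -1, 1)) / 4      # unit gain at Nyquist
    } else {
      b <- c(1, 2, 1)
      g <- sum(a) / 4                    # unit gain at DC
    }
    signal::Arma(b = g * b, a = a)
  })
}

# zero-phase HP + LP biquad cascade, then decimate
bandpass_decimate <- function(x, fs, band, q) {
  secs <- c(butter_sos(4, band[1] / (fs / 2), "high"),
            butter_sos(4, band[2] / (fs / 2), "low"))
  # remove the DC offset first: filtfilt's edge transients decay over
  # ~1/(1-|p|) samples, so letting the high-pass absorb a large offset
  # leaks it back in at the record edges
  y <- x - mean(x)
  for (s in secs) y <- signal::filtfilt(s, y)
  if (q > 1L) y <- as.numeric(signal::decimate(y, q, ftype = "iir"))
  y
}

#' Theoretical magnitude response of the preprocessing band-pass
#'
#' Squared-magnitude (forward-backward) response of the Butterworth
#' cascade at the requested frequencies; used to reason about stop-band
#' attenuation independently of any signal.
#'
#' @param f frequencies (Hz); @param fs input sampling rate (Hz);
#' @param band pass band (Hz).
#' @return |H(f)| of the zero-phase cascade (linear scale).
#' @export
bandpass_response <- function(f, fs, band = c(0.1, 48)) {
  secs <- c(butter_sos(4, band[1] / (fs / 2), "high"),
            butter_sos(4, band[2] / (fs / 2), "low"))
  w <- 2 * pi * f / fs
  h <- rep(1 + 0i, length(f))
  for (s in secs) {
    num <- vapply(w, function(wi)
      sum(s$b * exp(-1i * wi * (seq_along(s$b) - 1))), complex(1))
    den <- vapply(w, function(wi)
      sum(s$a * exp(-1i * wi * (seq_along(s$a) - 1))), complex(1))
    h <- h * num / den
  }
  # filtfilt applies the cascade twice: magnitude squared
  Mod(h)^2
}
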