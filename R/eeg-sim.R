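#' State-dependent EEG/EMG spectral profile
#'
#' Describes, per vigilance state, the EEG power spectral density used
#' by the synthetic signal generator as a 1/f^alpha background plus
#' Gaussian band bumps, and the EMG root-mean-square level.  The
#' defaults encode the classical state signatures: NREM dominated by a
#' delta bump (high-amplitude slow waves), REM dominated by a 6-9 Hz
#' theta rhythm with muscle atonia, WAKE broadband with high EMG tone,
#' and TREM an intermediate mix of slow-wave and theta activity.
#'
#' @param states named list; each element a list with fields
#'   `bg` (background scale), `alpha` (1/f exponent), `bumps`
#'   (data.frame center/width/power in Hz and arbitrary power units),
#'   `emg_rms` (median epoch EMG RMS, arbitrary units), `emg_gsd`
#'   (geometric SD of the per-epoch lognormal RMS variability; muscle
#'   tone fluctuates within a state, most strongly during active
#'   wakefulness).
#' @return Object of class `spectral_profile`.
#' @export
spectral_profile <- function(states = default_state_profiles()) {
  stop_if_not(all(VIGILANCE_STATES %in% names(states)),
              "profiles required for all of WAKE/NREM/REM/TREM")
  for (s in VIGILANCE_STATES) {
    p <- states[[s]]
    stop_if_not(p$bg >= 0 && all(p$bumps$power >= 0) && p$emg_rms >= 0,
                "all powers and levels must be >= 0 (state %s)", s)
  }
  db <- function(s) { b <- states[[s]]$bumps
    sum(b$power[b$center >= 1 & b$center <= 4.5]) }
  tb <- function(s) { b <- states[[s]]$bumps
    sum(b$power[b$center >= 6 & b$center <= 9]) }
  stop_if_not(db("NREM") > db("WAKE"),
              "NREM delta bump must exceed WAKE delta bump")
  stop_if_not(tb("REM") > tb("NREM"),
              "REM theta bump must exceed NREM theta bump")
  structure(states, class = "spectral_profile")
}

#' @rdname spectral_profile
#' @export
default_state_profiles <- function() {
  bump <- function(center, width, power)
    data.frame(center = center, width = width, power = power)
  no_bump <- bump(numeric(0), numeric(0), numeric(0))
  list(
    WAKE = list(bg = 1, alpha = 1, bumps = no_bump,
                emg_rms = 4.0, emg_gsd = 1.3),
    NREM = list(bg = 1, alpha = 1, bumps = bump(2.5, 1.0, 3.0),
                emg_rms = 1.0, emg_gsd = 1.1),
    REM  = list(bg = 1, alpha = 1, bumps = bump(7.5, 0.75, 3.0),
                emg_rms = 0.7, emg_gsd = 1.1),
    TREM = list(bg = 1, alpha = 1,
                bumps = bump(c(2.5, 7.5), c(1.0, 0.75), c(0.8, 2.2)),
                emg_rms = 1.0, emg_gsd = 1.1)
  )
}

# Target EEG PSD (arbitrary units^2/Hz) of one state at frequencies f
state_psd <- function(p, f) {
  s <- p$bg * pmax(f, 0.25)^(-p$alpha)
  if (nrow(p$bumps))
    for (i in seq_len(nrow(p$bumps)))
      s <- s + p$bumps$power[i] *
        exp(-(f - p$bumps$center[i])^2 / (2 * p$bumps$width[i]^2))
  s
}

#' Synthesize an EEG/EMG recording from a hypnogram
#'
#' Each 4-s epoch of EEG is synthesized in the frequency domain as
#' random-phase noise whose power spectral density follows the state's
#' profile (1/f^alpha background plus band bumps); consecutive epochs
#' are stitched with a 0.25-s linear crossfade to avoid edge clicks.
#' EMG is white noise at the state's RMS level.  The generator targets
#' spectra, not waveform morphology: downstream assertions are all
#' spectral.
#'
#' @param hypnogram a `hypnogram` (from [gen_hypnogram()] or
#'   [as_hypnogram()]).
#' @param profile a [spectral_profile()].
#' @param fs sampling rate in Hz (>= 128; default 128, the rate the
#'   spectral pipeline expects).
#' @param seed integer seed.
#' @param channels EEG channel names to synthesize (default frontal and
#'   parietal, drawn independently from the same profile).
#' @return A `recording`: list with `eeg` (named list of numeric
#'   vectors), `emg`, `fs`, `start_zt`.
#' @export
gen_eeg_emg <- function(hypnogram, profile = spectral_profile(), fs = 128,
                        seed = 1L, channels = c("frontal", "parietal")) {
  stop_if_not(inherits(hypnogram, "hypnogram") && nrow(hypnogram) > 0,
              "hypnogram must be a non-empty hypnogram")
  stop_if_not(fs >= 128, "fs must be >= 128 Hz")
  stop_if_not(inherits(profile, "spectral_profile"),
              "profile must come from spectral_profile()")
  n_ep <- nrow(hypnogram)
  N <- as.integer(EPOCH_S * fs)          # samples per epoch
  L <- as.integer(0.25 * fs)             # crossfade overlap
  nseg <- N + L
  half <- nseg %/% 2L
  df <- fs / nseg
  f <- (1:half) * df
  st <- as.integer(hypnogram$state)

  # per-state cosine amplitudes for the half-spectrum
  amp <- vapply(VIGILANCE_STATES, function(s)
    sqrt(2 * state_psd(profile[[s]], f) * df), numeric(half))

  with_seed(seed, {
    out <- list(eeg = list(), emg = NULL, fs = fs,
                start_zt = 0)
    chunk <- 4096L
    for (ch in channels) {
      sig <- numeric(n_ep * N + L)
      for (lo in seq(1L, n_ep, by = chunk)) {
        hi <- min(lo + chunk - 1L, n_ep)
        k <- hi - lo + 1L
        phi <- matrix(stats::runif(half * k, 0, 2 * pi), half, k)
        X <- matrix(0+0i, nseg, k)
        X[2:(half + 1L), ] <- (nseg / 2) * amp[, st[lo:hi], drop = FALSE] *
          exp(1i * phi)
        X[nseg:(nseg - half + 2L), ] <- Conj(X[2:half, , drop = FALSE])
        seg <- Re(stats::mvfft(X, inverse = TRUE)) / nseg
        # overlap-add with linear crossfade over L samples;
        # segment e covers samples (e-1)*N + 1 .. e*N + L
        ramp <- seq(0, 1, length.out = L + 2L)[2:(L + 1L)]
        wseg <- seg * c(ramp, rep(1, N - L), rev(ramp))
        for (j in seq_len(k)) {
          e <- lo + j - 1L
          idx <- ((e - 1L) * N + 1L):(e * N + L)
          sig[idx] <- sig[idx] + wseg[, j]
        }
      }
      sig <- sig[seq_len(n_ep * N)]
      out$eeg[[ch]] <- sig
    }
    emg <- stats::rnorm(n_ep * N)
    lev <- vapply(VIGILANCE_STATES, function(s) profile[[s]]$emg_rms,
                  numeric(1))
    gsd <- vapply(VIGILANCE_STATES, function(s)
      if (is.null(profile[[s]]$emg_gsd)) 1 else profile[[s]]$emg_gsd,
      numeric(1))
    ep_rms <- unname(lev[st] * exp(stats::rnorm(n_ep) * log(gsd[st])))
    out$emg <- emg * rep(ep_rms, each = N)
    structure(out, class = "recording")
  })
}

#' Construct a recording object
#'
#' @param eeg named list of equal-length numeric vectors (channels).
#' @param emg numeric vector, same length as the EEG channels.
#' @param fs sampling rate (Hz).
#' @param start_zt zeitgeber hour at the first sample (default 0:
#'   recordings start at light onset).
#' @export
recording <- function(eeg, emg, fs, start_zt = 0) {
  stop_if_not(is.list(eeg) && length(eeg) >= 1, "eeg must be a named list")
  len <- unique(c(vapply(eeg, length, 1L), length(emg)))
  stop_if_not(length(len) == 1L, "all channels must share one length")
  stop_if_not(fs > 0, "fs must be positive")
  structure(list(eeg = eeg, emg = emg, fs = fs, start_zt = start_zt),
            class = "recording")
}

#' Number of whole 4-s epochs in a recording
#' @param rec a `recording`.
#' @export
n_epochs <- function(rec) {
  as.integer(length(rec$eeg[[1]]) %/% (rec$fs * EPOCH_S))
}

#' Write / read a recording as columnar CSV
#'
#' Columns: one per EEG channel plus `emg`; sampling rate and start ZT
#' are stored in a `# fs=<Hz> start_zt=<h>` header comment.
#'
#' @param rec a `recording`; @param path file path.
#' @export
write_signals_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g start_zt=%g", rec$fs, rec$start_zt), con)
  d <- as.data.frame(c(rec$eeg, list(emg = rec$emg)))
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  stop_if_not(grepl("^# fs=", hdr), "missing fs header in signals CSV")
  fs <- as.numeric(sub("^# fs=([0-9.]+).*", "\\1", hdr))
  start_zt <- as.numeric(sub(".*start_zt=([0-9.]+).*", "\\1", hdr))
  d <- utils::read.csv(path, comment.char = "#")
  emg <- d$emg
  eeg <- as.list(d[setdiff(names(d), "emg")])
  recording(eeg = eeg, emg = emg, fs = fs, start_zt = start_zt)
}
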