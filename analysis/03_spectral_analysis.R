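#!/usr/bin/env Rscript
# State-resolved spectral analysis of the simulated recording:
# cross-state and within-state normalized spectra and the SWA
# timecourse over the day.

suppressMessages(library(sleepedit))
dir.create("results", showWarnings = FALSE)

rec <- read_signals_csv("results/sim/eeg_emg_sample.csv")
hyp_full <- read_hypnogram_csv("results/sim/hypnogram_day1.csv")
idx <- round(c(seq(1, 10800, length.out = 450),
               seq(10801, 21600, length.out = 450)))
hyp <- subset_hypnogram(hyp_full, idx)

spec <- rebin(epoch_psd(rec, channel = "parietal"))

rows <- list()
for (ph in c("light", "dark")) {
  norm <- normalize_cross_state(spec, hyp, phase = ph, day = 1)
  for (s in rownames(norm))
    rows[[length(rows) + 1]] <- data.frame(
      phase = ph, state = s, bin_hz = attr(norm, "bin_hz"),
      power_pct = norm[s, ])
}
cross <- do.call(rbind, rows)
utils::write.csv(cross, "results/spectra_cross_state.csv",
                 row.names = FALSE)

within <- do.call(rbind, lapply(c("NREM", "REM", "WAKE"), function(s)
  data.frame(state = s, bin_hz = attr(spec, "bin_hz"),
             power_pct = as.vector(normalize_within_state(spec, hyp,
                                                          state = s)))))
utils::write.csv(within, "results/spectra_within_state.csv",
                 row.names = FALSE)

tc <- swa_timecourse(spec, hyp, interval_h = 4)
utils::write.csv(tc, "results/swa_timecourse.csv", row.names = FALSE)

nrem_delta_light <- mean(subset(cross, phase == "light" & state == "NREM" &
                                  bin_hz >= 1 & bin_hz <= 4.5)$power_pct)
cat(sprintf("light-phase NREM delta (cross-state normalized): %.1f%%\n",
            nrem_delta_light))
cat(sprintf("SWA timecourse: %d intervals, reference (ZT8-12) = %.1f%%\n",
            nrow(tc), tc$swa_pct[tc$interval_start_h == 8]))
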