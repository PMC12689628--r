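#!/usr/bin/env Rscript
# Score the simulated recording with the rule-based scorer, compare
# against the generating hypnogram, and tabulate sleep architecture.

suppressMessages(library(sleepedit))
dir.create("results", showWarnings = FALSE)

rec <- read_signals_csv("results/sim/eeg_emg_sample.csv")
hyp_full <- read_hypnogram_csv("results/sim/hypnogram_day1.csv")
idx <- round(c(seq(1, 10800, length.out = 450),
               seq(10801, 21600, length.out = 450)))
truth <- subset_hypnogram(hyp_full, idx)

scored <- score(rec)
agr <- epoch_agreement(scored, truth)
cat(sprintf("scorer vs generating hypnogram: %.1f%% epoch agreement\n",
            100 * agr))

arch <- architecture(hyp_full)
utils::write.csv(arch$minutes, "results/sleep_architecture.csv",
                 row.names = FALSE)
cat(sprintf("full-day architecture written; %.1f%% of sleep in light phase\n",
            arch$pct_sleep_in_light))
print(arch$minutes[, c("day", "phase", "WAKE", "NREM", "REM_incl_trem")])
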