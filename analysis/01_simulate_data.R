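#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# steps: a full-day hypnogram with EEG/EMG for a phase-balanced epoch
# sample, amplicon read sets for three "cortex" samples, open-field
# trajectories, and a plaque/microglia probability volume.

suppressMessages(library(sleepedit))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
set.seed(1)

## sleep: one example animal
hyp <- gen_hypnogram(hypnogram_params(days = 1, seed = 101))
write_hypnogram_csv(hyp, "results/sim/hypnogram_day1.csv")
idx <- round(c(seq(1, 10800, length.out = 450),
               seq(10801, 21600, length.out = 450)))
hyp_sub <- subset_hypnogram(hyp, idx)
rec <- gen_eeg_emg(hyp_sub, spectral_profile(), fs = 128, seed = 102)
write_signals_csv(rec, "results/sim/eeg_emg_sample.csv")
cat(sprintf("hypnogram: %d epochs (%.1f%% sleep in light phase)\n",
            nrow(hyp),
            architecture(hyp)$pct_sleep_in_light))

## editing: three cortex samples at increasing AAV transduction
refv <- local({ set.seed(103); sample(c("A", "C", "G", "T"), 200, TRUE) })
pos <- which(refv == "C" & seq_along(refv) >= 90 & seq_along(refv) <= 110)[1] - 1L
ref <- paste(refv, collapse = "")
spec <- edit_spec(data.frame(position = pos, ref_base = "C", alt_base = "T"),
                  ref, window = c(pos - 30L, pos + 31L), name = "A187V")
write_fasta(c(adrb1_amplicon = ref), "results/sim/reference.fa")
rates <- c(low = 0.04, mid = 0.13, high = 0.28)
for (nm in names(rates)) {
  rs <- gen_reads(read_sim_params(ref, spec, p_edit = rates[[nm]],
                                  p_indel = 0.01, n_reads = 20000,
                                  seed = 104 + match(nm, names(rates))))
  write_fastq(rs, sprintf("results/sim/cortex_%s.fastq", nm))
}
cat(sprintf("amplicon reads for %d samples written (edit at position %d)\n",
            length(rates), pos))

## open field: two animals with different activity profiles
prof_active <- data.frame(duration_s = c(120, 120, 120, 120, 120),
                          speed_cm_s = c(12, 3, 9, 2, 10))
prof_quiet <- data.frame(duration_s = c(150, 150, 150, 150),
                         speed_cm_s = c(6, 1, 4, 2))
write_trajectory_csv(gen_trajectory(prof_active, seed = 108),
                     "results/sim/of_active.csv")
write_trajectory_csv(gen_trajectory(prof_quiet, seed = 109),
                     "results/sim/of_quiet.csv")

## cleared-hemisphere volume
vs <- gen_volume(volume_sim_params(shape = c(64, 64, 64), n_plaques = 20,
                                   n_microglia = 6, engulfed_fraction = 0.4,
                                   seed = 110))
write_volume_tiff(vs$prob_plaque, "results/sim/prob_plaque.tif")
write_volume_tiff(vs$prob_microglia, "results/sim/prob_microglia.tif")
utils::write.csv(vs$truth, "results/sim/plaque_truth.csv", row.names = FALSE)
cat(sprintf("volume: %d plaques programmed, %d engulfed\n",
            nrow(vs$truth), sum(vs$truth$engulfed)))
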