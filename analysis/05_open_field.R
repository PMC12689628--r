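#!/usr/bin/env Rscript
# Open-field kinematics for the simulated trajectories: 4-frame
# sliding-window velocity, 5 cm/s running episodes, average running
# speed, distance, and centre time.

suppressMessages(library(sleepedit))
dir.create("results", showWarnings = FALSE)

rows <- lapply(c(active = "of_active", quiet = "of_quiet"), function(f) {
  tr <- read_trajectory_csv(sprintf("results/sim/%s.csv", f),
                            frame_rate = 25, arena = c(50, 50))
  out <- detect_episodes(tr)
  cbind(data.frame(animal = sub("of_", "", f)),
        out$summary,
        center_time_s = center_time(tr))
})
summary_tab <- do.call(rbind, rows)
utils::write.table(summary_tab, "results/open_field_summary.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
print(summary_tab[, c("animal", "distance_cm", "n_episodes",
                      "running_time_s", "avg_running_speed_cm_s",
                      "center_time_s")], row.names = FALSE)
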