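#!/usr/bin/env Rscript
# Plaque quantification on the simulated probability volumes:
# binarize at 0.2, 26-connected components, size and std/mean
# filtering, microglia colocalization, and per-region counts against
# a toy region-label volume.

suppressMessages(library(sleepedit))
dir.create("results", showWarnings = FALSE)

pp <- probability_volume(read_volume_tiff("results/sim/prob_plaque.tif"))
pm <- probability_volume(read_volume_tiff("results/sim/prob_microglia.tif"))
truth <- utils::read.csv("results/sim/plaque_truth.csv")

out <- quantify_plaques(pp, pm)
cand <- out$candidates
cand$engulfed <- cand$id %in% out$plaques$id[out$plaques$engulfed]
utils::write.table(cand, "results/plaque_candidates.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat(sprintf("candidates: %d, retained plaques: %d (truth: %d), engulfed: %d (truth: %d)\n",
            nrow(cand), nrow(out$plaques), nrow(truth),
            sum(out$plaques$engulfed), sum(truth$engulfed)))
cat(sprintf("microglia overlap fraction of plaque volume: %.3f\n",
            out$overlap_fraction))

# toy anatomical partition of the volume along z
labv <- array(0L, dim(pp$values))
labv[1:21, , ] <- 1L; labv[22:42, , ] <- 2L; labv[43:64, , ] <- 3L
regions <- c("1" = "isocortex", "2" = "hippocampal_formation",
             "3" = "thalamus")
rc <- region_counts(out$plaques, labv, regions)
print(rc$counts)
utils::write.csv(data.frame(region = names(rc$counts),
                            plaques = as.vector(rc$counts)),
                 "results/plaque_region_counts.csv", row.names = FALSE)
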