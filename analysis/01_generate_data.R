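#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a network timelapse (traveling-wave
# expansion imaged every 2 h for 200 h), a phosphorus-depletion harvest assay
# (8 replicate plates, distinct harvest times), and a transect training set
# (3,000 labelled intensity profiles with augmentation).

suppressPackageStartupMessages(library(myconet))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_run_config(seed = 1)

snaps <- generate_timelapse(cfg)
write_snapshots(snaps, "results/data/snapshots")
gt <- attr(snaps, "ground_truth")
write.csv(gt, "results/data/ground_truth.csv", row.names = FALSE)
cat(sprintf("timelapse: %d snapshots to %g h; final network %.2g m of hyphae, %d spores\n",
            length(snaps), cfg$duration_h,
            tail(gt$length_um, 1) / 1e6, tail(gt$n_spores, 1)))

assay <- generate_depletion_assay(cfg, J_true = 3)
write.csv(assay, "results/data/assay.csv", row.names = FALSE)
cat(sprintf("assay: %d replicates, Pf spans %.1f-%.1f ug over intS %.0f-%.0f mm^2 h\n",
            nrow(assay), min(assay$Pf_ug), max(assay$Pf_ug),
            min(assay$intS_mm2h), max(assay$intS_mm2h)))

transects <- generate_transect_dataset(cfg, 3000)
write.csv(transects, "results/data/transects.csv", row.names = FALSE)
cat(sprintf("transects: %d profiles, labels %.1f-%.1f um (%.0f%% empty)\n",
            nrow(transects), min(transects$label_um), max(transects$label_um),
            100 * mean(transects$label_um == 0)))
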