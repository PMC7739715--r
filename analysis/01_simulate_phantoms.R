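#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses consume —
# an abdominal MRI/CT phantom pair with exact ground-truth depot masses, a
# dynamic tissue TAC with known kinetics, and a two-group intervention
# cohort. Everything is written under results/simulated/.

suppressPackageStartupMessages(library(adipoquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Generating the abdominal phantom (6 slices, 5% fat-signal noise, 15% bias) ...")
spec <- phantom_spec(n_slices = 6, noise_sd = 50, bias_amplitude = 0.15,
                     internal_fat_fraction = 0.08,
                     seed = stage_seed(seed, "simulate"))
ph <- generate_phantom(spec, region = "abdomen")
write_volume(ph$mri, file.path(out, "phantom_mri.nii.gz"))
write_volume(ph$ct, file.path(out, "phantom_ct.nii.gz"))
write_volume(ph$truth$labels, file.path(out, "phantom_labels.nii.gz"))
jsonlite::write_json(as.list(ph$truth$depot_masses_kg),
                     file.path(out, "phantom_truth_masses.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("  true SAT %.4f kg, visceral %.4f kg",
                ph$truth$depot_masses_kg[["sat"]],
                ph$truth$depot_masses_kg[["visceral"]]))

message("Simulating the dynamic FDG acquisition (26 frames / 60 min) ...")
sched <- build_frame_schedule()
inp <- simulate_input_function(times_min = seq(0, 60, by = 0.05))
truth_k <- kinetic_params(0.05, 0.25, 0.06, Vb = 0.05)
tc <- simulate_tissue_tac(inp, truth_k, sched, noise_sd = 0.05,
                          seed = stage_seed(seed, "tac"))
write_tac_csv(tc, file.path(out, "tissue_tac.csv"))
utils::write.csv(data.frame(times_min = inp$times_min,
                            cp_kBq_per_ml = inp$cp_kBq_per_ml),
                 file.path(out, "input_function.csv"), row.names = FALSE)
message(sprintf("  true Ki = %.5f mL/mL/min", truth_k$ki))

message("Simulating the intervention cohort (20 + 20 women, -4% SAT / -6% VAT) ...")
cohort <- simulate_cohort(cohort_spec(seed = stage_seed(seed, "cohort")))
write_cohort_csv(cohort, file.path(out, "cohort.csv"))
message(sprintf("  %d rows written", nrow(cohort)))
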