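#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# Builds a six-chemical screen spanning the screened potency patterns
# (complex I / complex III inhibitor profiles, two uncouplers, a baseline
# toxicant) at the standard design — 11-point 1:2 dilution series,
# duplicate wells, three independent runs, 16 solvent controls per
# 384-well plate, 5% CV noise — plus one fully characterised synthetic
# water extract mixing the two uncouplers, with its detection table.
# Everything downstream reads only the delimited tables written here.

suppressPackageStartupMessages(library(mitotox))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

chems <- example_chemicals()
wells <- simulate_plate(chems, plate_design(), noise_model(), seed = seed)
write_well_table(wells, "results/data/chemical_wells.csv")
write_chemical_table(chemical_table(chems), "results/data/chemicals.csv")
write_full_precision(truth_table(chems), "results/data/truth.csv")

cat(sprintf("chemical screen: %d wells, %d plates, %d runs\n",
            nrow(wells), length(unique(wells$plate_id)),
            length(unique(wells$run_id))))

# Synthetic water extract: both uncouplers at environmentally plausible
# concentrations; mixture follows strict concentration addition.
cons <- list(list(chem = chems$unc_24dnp_like, conc = 3e-6),
             list(chem = chems$unc_potent, conc = 5e-8))
mix <- simulate_mixture_sample(cons, plate_design(), noise_model(),
                               seed = seed + 1, sample_id = "SW01",
                               top_ref = 100)
write_well_table(mix$wells, "results/data/water_wells.csv")
write_detection_table(mix$detections, "results/data/detections.csv")

cat(sprintf("water sample SW01: true MMP EC10 at REF %.3g; %d detections\n",
            mix$truth$mmp_ec10_ref, nrow(mix$detections)))
cat("wrote results/data/{chemical_wells,chemicals,truth,water_wells,detections}.csv\n")
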