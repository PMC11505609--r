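#!/usr/bin/env Rscript
# Generate one exemplar synthetic dataset per analysis arm, with ground
# truth, and write them under results/simulated/. Everything downstream
# (02-05) regenerates its own inputs through the pipeline; this script exists
# to show what the generators produce and on what scales.

suppressPackageStartupMessages(library(admodal))
outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

## Fluorescence phantom at the 20x scale (0.5128 um/px)
spec_img <- image_phantom_spec(width_px = 512, height_px = 512,
                               pixel_size_um = 0.5128, plaque_count = 6,
                               plaque_radius_px = 12, filament_count = 8,
                               nucleus_count = 120, nucleus_radius_px = 4,
                               noise_sd = 0.02, channel = "DAPI", seed = seed)
ph <- gen_fluorescence_image(spec_img)
invisible(tiff::writeTIFF(ph$image$pixels,
                          file.path(outdir, "phantom_dapi.tiff"),
                          bits.per.sample = 16))
jsonlite::write_json(
  list(pixel_size_um = 0.5128, n_nuclei = ph$truth$n_nuclei,
       n_plaques = ph$truth$n_plaques, positive_px = ph$truth$positive_px),
  file.path(outdir, "phantom_dapi_truth.json"), auto_unbox = TRUE)
cat(sprintf("phantom: %d nuclei, %d plaques, %d foreground px of %d (%.2f%%)\n",
            ph$truth$n_nuclei, ph$truth$n_plaques, ph$truth$positive_px,
            length(ph$image$pixels),
            100 * ph$truth$positive_px / length(ph$image$pixels)))

## GC-MS style isotopologue replicates for the three tracer substrates
for (substrate in c("U13C_glucose", "12C13_acetate", "U13C_glutamine")) {
  tbl <- gen_mids(tracer_spec(substrate, n_replicates = 4, seed = seed))
  write.csv(tbl, file.path(outdir, paste0("mids_", substrate, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s: %d replicate MID rows, %d metabolites\n", substrate,
              nrow(tbl), length(unique(tbl$metabolite))))
}

## DKI phantom on the 5 b0 + 4 x 30 scheme, SNR 50
spec_dki <- dki_phantom_spec(shape = c(6L, 4L, 2L), snr = 50, seed = seed)
vol <- gen_dki_volume(spec_dki)
paths <- write_dki_phantom(vol, outdir, prefix = "dwi_phantom")
truth <- do.call(rbind, lapply(names(vol$truth), function(r) {
  data.frame(region = r, MD = vol$truth[[r]]$MD, FA = vol$truth[[r]]$FA,
             MK = vol$truth[[r]]$MK)
}))
write.csv(truth, file.path(outdir, "dwi_phantom_truth.csv"),
          row.names = FALSE)
cat("DKI phantom ground truth:\n"); print(truth, row.names = FALSE)

## Cohort table with the study's factor structure (null effects)
cohort <- gen_cohort(cohort_spec(n_per_group = 7, seed = seed))
write.csv(cohort, file.path(outdir, "cohort_null.csv"), row.names = FALSE)
cat(sprintf("cohort: %d subjects x %d ROIs\n",
            length(unique(cohort$subject_id)),
            length(unique(cohort$roi))))
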