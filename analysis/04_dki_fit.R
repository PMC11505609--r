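#!/usr/bin/env Rscript
# Diffusion arm: voxelwise DKI fit of a two-region phantom (anisotropic
# white-matter-like slab and an isotropic two-compartment gray-matter-like
# slab) at SNR 50 on the 5 b0 + 4 shells x 30 directions scheme, ROI
# summaries with whole-brain-normalized volumes, and comparison with the
# analytic ground truth.

suppressPackageStartupMessages(library(admodal))
cfg <- default_config(arm = "dki", seed = 31L, outdir = "results/dki")
run_pipeline(cfg)

summ <- read.csv("results/dki/dki_roi_summary.csv")
cat("ROI summary (fitted vs analytic truth):\n")
print(summ[c("roi", "MD", "MD_true", "FA", "FA_true", "MK", "MK_true",
             "relative_volume")], row.names = FALSE, digits = 3)
cat("\nnote: the gm slab is a true biexponential, so its fitted MK sits",
    "below the b->0 analytic value (cumulant truncation at b_max = 2).\n")

perm <- read.csv("results/dki/dki_perm_anova.csv")
cat("\npermutational three-way mixed ANOVA on the ROI metric cohort:\n")
print(perm, row.names = FALSE, digits = 3)
cat("\nROI differences dominate (as expected from the simulated regional",
    "profile); genotype and age stay at their null rates.\n")
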