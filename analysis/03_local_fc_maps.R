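#!/usr/bin/env Rscript
# Stage 3 — preprocessing and per-subject local-connectivity maps.
#
# Reads the cohort written by stage 2 back from disk (exercising the NIfTI
# path), applies 6-mm Gaussian smoothing, and computes for every subject the
# regional-homogeneity map (Kendall's W over 27-voxel neighbourhoods of the
# 0.01-0.08 Hz band-passed series) and the fALFF map (0.01-0.08 over
# 0.01-0.25 Hz spectral amplitude of the detrended, unfiltered series), both
# standardized by their within-mask mean. Maps go to scratch/maps/.

suppressPackageStartupMessages(library(restingstop))
dir.create("scratch/maps", showWarnings = FALSE, recursive = TRUE)

cohort <- read.delim("scratch/cohort/cohort.tsv")
mask_file <- "scratch/cohort/mask.nii.gz"
cfg <- pipeline_config()
for (i in seq_len(nrow(cohort))) {
  vol <- read_volume_series(
    file.path("scratch/cohort", paste0(cohort$id[i], "_bold.nii.gz")),
    mask = mask_file)
  sm <- smooth_volume(vol, cfg$fwhm_mm)
  reho <- standardize_map(reho_map(bandpass(sm, cfg$band_low_hz,
                                            cfg$band_high_hz)))
  falff <- standardize_map(falff_map(detrend(sm), cfg$bands))
  write_volume(reho, file.path("scratch/maps", paste0(cohort$id[i], "_reho.nii.gz")))
  write_volume(falff, file.path("scratch/maps", paste0(cohort$id[i], "_falff.nii.gz")))
  cat(sprintf("\r%-60s", paste0(cohort$id[i], ": reho + falff written")))
}
cat("\nwrote scratch/maps/*.nii.gz for", nrow(cohort), "subjects\n")
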