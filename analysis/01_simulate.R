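#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study bundle.
#
# Emulates the study conditions the downstream analyses assume: a cohort of
# 500 subjects with 12 metabolic risk-factor variables and 100 morphometric
# parcels, a rank-one latent coupling between the blocks (coupling 0.8,
# residual SD 0.5), linear confound contamination, 5% MCAR missingness in
# the clinical block, and cognition generated with a planted mediation chain
# (a = 0.3, b = 0.3, c' = 0.1). Parcel geometry, two connectomes, and a
# cell-category expression matrix with two signal categories complete the
# bundle.

suppressPackageStartupMessages(library(brainpls))

seed <- 2026L
out <- "results/data"

bundle <- gen_study_bundle(
  n_subjects = 500L, n_parcels = 100L, n_clinical = 12L, seed = seed,
  coupling_strength = 0.8, noise_sd = 0.5, missing_rate = 0.05,
  confound_effects = "default",
  mediation_effects = c(a = 0.3, b = 0.3, c_prime = 0.1)
)
write_bundle(bundle, out)

cat("Wrote study bundle to", out, "\n")
cat("  subjects:", nrow(bundle$cohort$clinical),
    " parcels:", nrow(bundle$geometry),
    " genes:", ncol(bundle$expression), "\n")
cat("  missing clinical cells:", sum(is.na(bundle$cohort$clinical)), "\n")
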