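#!/usr/bin/env Rscript
# Stage 3: partial least squares correlation of the two blocks.
#
# SVD of the region-by-risk-factor correlation matrix; latent-variable
# significance by permutation (n = 500 here), stability by bootstrap
# (n = 500), subject scores, and 10-fold cross-validation of the
# score-score association.

suppressPackageStartupMessages(library(brainpls))

X <- brainpls:::read_matrix_csv("results/X_preprocessed.csv")
Y <- brainpls:::read_matrix_csv("results/Y_preprocessed.csv")

fit <- pls_fit(X, Y, n_perm = 500L, n_boot = 500L, cv_folds = 10L, seed = 2026L)

dir.create("results/pls", showWarnings = FALSE)
brainpls:::write_matrix_csv(fit$U, "results/pls/U.csv")
brainpls:::write_matrix_csv(fit$V, "results/pls/V.csv")
brainpls:::write_matrix_csv(fit$boot_ratio, "results/pls/boot_ratio.csv")
scores <- cbind(imaging = fit$scores_imaging[, 1],
                clinical = fit$scores_clinical[, 1])
rownames(scores) <- rownames(X)
brainpls:::write_matrix_csv(scores, "results/pls/scores_lv1.csv")
brainpls:::json_write(
  list(delta = fit$delta, explained_variance = fit$explained_variance,
       perm_p = fit$perm_p, score_spearman = fit$score_spearman,
       cv_mean_spearman = fit$cv$mean_spearman,
       n_significant_regions_lv1 = sum(abs(fit$boot_ratio[, 1]) > 1.96)),
  "results/pls/pls_summary.json")

cat(sprintf("LV1 explains %.1f%% of shared variance (perm p = %.4g)\n",
            100 * fit$explained_variance[1], fit$perm_p[1]))
cat(sprintf("LV1 score-score Spearman r = %.3f (CV mean %.3f)\n",
            fit$score_spearman[1], fit$cv$mean_spearman[1]))
cat(sprintf("%d of %d regions have |bootstrap ratio| > 1.96 on LV1\n",
            sum(abs(fit$boot_ratio[, 1]) > 1.96), nrow(fit$boot_ratio)))
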