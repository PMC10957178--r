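#!/usr/bin/env Rscript
# Stage 2: impute, deconfound, and standardize both data blocks.
#
# Missing clinical values are imputed by group-restricted k-NN (k = 4,
# distances within the variable's own risk-factor group); age, sex,
# education, and cohort are regressed out of both blocks; columns are then
# z-scored. The preprocessed matrices feed the PLS stage.

suppressPackageStartupMessages(library(brainpls))

inputs <- load_inputs("results/data")
cat("Loaded", inputs$validation$n_subjects, "subjects;",
    sum(inputs$validation$n_missing_clinical), "missing clinical cells\n")

clin <- impute_knn(inputs$clinical, inputs$clinical_groups, k = 4)
Y <- zscore_columns(residualize_confounds(clin, inputs$confounds))
X <- zscore_columns(residualize_confounds(inputs$morph, inputs$confounds))

# residual confound correlation is a preprocessing sanity check
conf <- as.matrix(inputs$confounds[, c("age", "sex", "education", "cohort")])
cat("Max |confound correlation| after residualization:",
    format(max(abs(stats::cor(conf, Y)), abs(stats::cor(conf, X))), digits = 3), "\n")

rownames(X) <- inputs$morph$subject_id
rownames(Y) <- inputs$clinical$subject_id
brainpls:::write_matrix_csv(X, "results/X_preprocessed.csv")
brainpls:::write_matrix_csv(Y, "results/Y_preprocessed.csv")
cat("Wrote results/X_preprocessed.csv and results/Y_preprocessed.csv\n")
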