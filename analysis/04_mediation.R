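#!/usr/bin/env Rscript
# Stage 4: does the imaging latent score mediate the association between the
# clinical latent score and cognition?
#
# One single-mediator bootstrap model per cognitive test (500 resamples
# here), adjusted for age, sex, and education; FDR correction within each
# path type across tests; full/partial/none classification.

suppressPackageStartupMessages(library(brainpls))

inputs <- load_inputs("results/data")
scores <- brainpls:::read_matrix_csv("results/pls/scores_lv1.csv")

tab <- mediate_batch(scores[, "clinical"], scores[, "imaging"],
                     inputs$cognition,
                     covariates = inputs$confounds[, c("age", "sex", "education")],
                     n_boot = 500L, seed = 2026L)
utils::write.csv(tab, "results/mediation.csv", row.names = FALSE)

for (i in seq_len(nrow(tab)))
  cat(sprintf("%s: ab = %.3f [%.3f, %.3f], c' = %.3f, c = %.3f -> %s mediation\n",
              tab$test[i], tab$ab[i], tab$ci_ab_lower[i], tab$ci_ab_upper[i],
              tab$c_prime[i], tab$c[i], tab$class[i]))
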