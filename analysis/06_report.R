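#!/usr/bin/env Rscript
# Stage 6: collate all stage outputs into results/report.md.

suppressPackageStartupMessages(library(brainpls))

# stage outputs live at the paths write_report() expects
dir.create("results/report", showWarnings = FALSE)
for (f in c("pls/pls_summary.json", "mediation.csv", "context_network.csv",
            "context_gcea.csv"))
  file.copy(file.path("results", f), file.path("results/report", basename(f)),
            overwrite = TRUE)
path <- write_report("results/report")
file.copy(path, "results/report.md", overwrite = TRUE)
cat("Report written to results/report.md\n")
cat(readLines("results/report.md")[1:12], sep = "\n")
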