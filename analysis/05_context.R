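#!/usr/bin/env Rscript
# Stage 5: contextualize the LV1 bootstrap-ratio map.
#
# Relates the regional effect map to (a) cell-category expression via
# ensemble gene-category enrichment with spatial-lag surrogates, and (b)
# connectome topology: degree-centrality ranks, neighborhood abnormality
# (with spin and degree-preserving rewiring nulls), and diffusion-map
# connectivity gradients.

suppressPackageStartupMessages(library(brainpls))

inputs <- load_inputs("results/data")
br <- brainpls:::read_matrix_csv("results/pls/boot_ratio.csv")[, 1]
seed <- 2026L
n_null <- 500L

perms <- brainpls:::spin_permutation_indices(inputs$geometry, n = n_null, seed = seed)
rows <- list()
for (mod in c("functional", "structural")) {
  conn <- inputs[[paste0("connectome_", mod)]]
  deg <- degree_centrality_rank(conn)
  nab <- neighborhood_abnormality(conn, br)
  r1 <- spatial_correlation(deg, br, nulls = "spin", n_null = n_null,
                            geometry = inputs$geometry, seed = seed,
                            spin_perms = perms)
  r2 <- spatial_correlation(nab, br, nulls = c("spin", "rewire"), n_null = n_null,
                            geometry = inputs$geometry, connectome = conn,
                            base_map = br, seed = seed, spin_perms = perms)
  rows[[paste0(mod, "_degree")]] <- c(rsp = r1$rsp, p_spin = r1$p_spin, p_rewire = NA)
  rows[[paste0(mod, "_neighborhood")]] <- c(rsp = r2$rsp, p_spin = r2$p_spin,
                                            p_rewire = r2$p_rewire)
}
grads <- connectivity_gradients(inputs$connectome_functional, 2L)
for (gidx in 1:2) {
  rg <- spatial_correlation(grads[, gidx], br, nulls = "spin", n_null = n_null,
                            geometry = inputs$geometry, seed = seed,
                            spin_perms = perms)
  rows[[paste0("functional_gradient_", gidx)]] <-
    c(rsp = rg$rsp, p_spin = rg$p_spin, p_rewire = NA)
}
net <- data.frame(comparison = names(rows), do.call(rbind, rows),
                  row.names = NULL)
net$q_spin <- fdr_adjust(net$p_spin)
utils::write.csv(net, "results/context_network.csv", row.names = FALSE)

gcea <- gcea_cell_types(br, inputs$expression, inputs$catalog,
                        n_surrogates = n_null, seed = seed,
                        geometry = inputs$geometry)
utils::write.csv(gcea, "results/context_gcea.csv", row.names = FALSE)

cat("Network contextualization:\n")
for (i in seq_len(nrow(net)))
  cat(sprintf("  %s: rsp = %.3f, p_spin = %.3g\n",
              net$comparison[i], net$rsp[i], net$p_spin[i]))
cat("Cell-category enrichment (q < 0.05):",
    paste(gcea$category[gcea$q < 0.05], collapse = ", "), "\n")
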