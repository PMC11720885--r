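#!/usr/bin/env Rscript
# Stage 4: differential protein abundance and PCA.
#
# Per-protein pooled two-sample t-tests (T2D vs HC) on the imputed log2
# matrix with BH FDR < 0.05, and PCA of the samples with per-protein
# contribution percentages to identify separation drivers.

source("analysis/00_config.R")

m <- read_quant_matrix(file.path(OUT_DIR, "protein_log2_imputed.tsv"), "log2")
design <- read_design()
origin <- ifelse(grepl("^HUM_", rownames(m$values)), "human", "bacterial")
names(origin) <- rownames(m$values)

tab <- differential_table(m, design, alpha = PARAMS$alpha_diff,
                          origin = origin)
write.table(tab, file.path(OUT_DIR, "differential_proteins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- tab[tab$direction != "ns", ]
message(nrow(sig), " differentially abundant proteins of ", nrow(tab),
        " (q < ", PARAMS$alpha_diff, "): ",
        sum(sig$direction == "up"), " up (",
        sum(sig$direction == "up" & sig$origin == "human"), " human, ",
        sum(sig$direction == "up" & sig$origin == "bacterial"), " bacterial), ",
        sum(sig$direction == "down"), " down (",
        sum(sig$direction == "down" & sig$origin == "human"), " human, ",
        sum(sig$direction == "down" & sig$origin == "bacterial"), " bacterial)")

pca <- pca_quant(m)
message(sprintf("PC1 %.1f%% + PC2 %.1f%% = %.1f%% of variance",
                pca$var_explained[1], pca$var_explained[2],
                sum(pca$var_explained[1:2])))
drivers <- pca_drivers(pca, 1, 25)
write.table(drivers, file.path(OUT_DIR, "pc1_drivers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top PC1 drivers: ", paste(head(drivers$feature_id, 5), collapse = ", "))
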