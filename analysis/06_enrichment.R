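#!/usr/bin/env Rscript
# Stage 6: functional enrichment.
#
# 1D rank-based enrichment of annotation terms on protein log2 fold changes
# (BH FDR < 0.02); 2D enrichment of bacterial-peptide terms on per-group
# mean log2 intensities; hierarchical clustering (Euclidean, z-scored rows)
# of peptides from the two most differential genera with per-cluster Fisher
# exact enrichment.

source("analysis/00_config.R")

ann <- utils::read.delim(file.path(INPUT_DIR, "annotations.tsv"),
                         stringsAsFactors = FALSE)
tab <- utils::read.delim(file.path(OUT_DIR, "differential_proteins.tsv"),
                         stringsAsFactors = FALSE)
fc <- stats::setNames(tab$log2fc, tab$feature_id)
e1 <- enrich_1d(fc, ann, alpha = PARAMS$alpha_enrich)
write.table(e1, file.path(OUT_DIR, "enrichment_1d.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("1D enrichment: ", sum(e1$significant), " of ", nrow(e1),
        " terms significant; strongest: ",
        paste(head(e1$term, 3), collapse = ", "))

design <- read_design()
pep_imp <- read_quant_matrix(file.path(OUT_DIR, "peptide_log2_imputed.tsv"),
                             "log2")
asn <- utils::read.delim(file.path(OUT_DIR, "peptide_assignments.tsv"),
                         stringsAsFactors = FALSE)
bact <- intersect(rownames(pep_imp$values), asn$peptide)
pepv <- pep_imp$values[bact, , drop = FALSE]
t2d <- rowMeans(pepv[, design$group == "T2D", drop = FALSE])
hc <- rowMeans(pepv[, design$group == "HC", drop = FALSE])
e2 <- enrich_2d(t2d, hc, ann, alpha = PARAMS$alpha_enrich)
write.table(e2, file.path(OUT_DIR, "enrichment_2d.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("2D enrichment: ", sum(e2$significant), " of ", nrow(e2),
        " terms significant")

gdiff <- utils::read.delim(file.path(OUT_DIR, "genus_differential.tsv"),
                           stringsAsFactors = FALSE)
top_gen <- gdiff$feature_id[order(gdiff$p)][1:2]
peps <- intersect(asn$peptide[asn$genus %in% top_gen], rownames(pep_imp$values))
cl <- hcluster(pep_imp$values[peps, , drop = FALSE], k = 2)
fe <- fisher_cluster(cl$labels, ann, alpha = PARAMS$alpha_enrich)
write.table(fe, file.path(OUT_DIR, "cluster_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("clustered ", length(peps), " peptides from genera ",
        paste(top_gen, collapse = " and "), "; ",
        sum(fe$significant), " cluster-term pairs significant")
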