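#!/usr/bin/env Rscript
# Stage 5: peptide-level taxonomic profiling.
#
# LCA assignment of bacterial peptides, genus/phylum mapping rates, per-
# sample genus relative abundance, genus-level differential intensity (raw
# sums of genus-specific peptides, re-log2ed, t-test + BH), differential
# relative abundance of the top 20 genera, and metaproteomics-vs-16S
# concordance (Pearson on per-genus totals).

source("analysis/00_config.R")

tree <- read_taxonomy(file.path(INPUT_DIR, "taxonomy.tsv"))
pmap <- read_protein_map(file.path(INPUT_DIR, "protein_map.tsv"))
info <- read_peptide_info()
bact <- info[!grepl("^HUM_", info$protein_ids), ]
asn <- assign_peptides(bact, pmap, tree)
write.table(asn, file.path(OUT_DIR, "peptide_assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

mapping <- summarize_mapping(asn)
write.table(mapping, file.path(OUT_DIR, "mapping_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("of ", nrow(asn), " bacterial peptides: ",
        mapping$n_mapped[mapping$level == "genus"], " (",
        mapping$percent[mapping$level == "genus"], "%) map to genus, ",
        mapping$n_mapped[mapping$level == "phylum"], " (",
        mapping$percent[mapping$level == "phylum"], "%) to phylum")

mats <- read_quant_report(file.path(INPUT_DIR, "quant_report.tsv"))
raw_bact <- quant_matrix(mats$peptides$values[
  intersect(rownames(mats$peptides$values), bact$peptide), , drop = FALSE],
  "raw")
comp <- relative_abundance(raw_bact, asn, "genus")
write.table(data.frame(genus = rownames(comp), comp, check.names = FALSE),
            file.path(OUT_DIR, "genus_composition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

design <- read_design()
pep_imp <- read_quant_matrix(file.path(OUT_DIR, "peptide_log2_imputed.tsv"),
                             "log2")
bact_imp <- quant_matrix(pep_imp$values[
  intersect(rownames(pep_imp$values), bact$peptide), , drop = FALSE], "log2")
gdiff <- genus_intensity_diff(bact_imp, asn, design,
                              alpha = PARAMS$alpha_diff)
write.table(gdiff, file.path(OUT_DIR, "genus_differential.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("genus intensity: ", sum(gdiff$direction != "ns"), " of ",
        nrow(gdiff), " genera significant (",
        paste(gdiff$feature_id[gdiff$direction != "ns"], collapse = ", "), ")")

radiff <- relative_abundance_diff(comp, design, top_k = PARAMS$top_k_taxa,
                                  alpha = PARAMS$alpha_diff)
write.table(radiff, file.path(OUT_DIR, "relative_abundance_differential.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("relative abundance (top ", nrow(radiff), "): ",
        sum(radiff$significant), " genera significant")

s16 <- utils::read.delim(file.path(INPUT_DIR, "s16_counts.tsv"),
                         check.names = FALSE)
s16_tot <- rowSums(as.matrix(s16[, -1]))
names(s16_tot) <- s16[[1]]
v <- raw_bact$values; v[is.na(v)] <- 0
genus_of <- asn$genus[match(rownames(v), asn$peptide)]
ms_tot <- rowSums(rowsum(v[!is.na(genus_of), , drop = FALSE],
                         genus_of[!is.na(genus_of)]))
conc <- concordance(ms_tot, s16_tot[names(ms_tot)])
message(sprintf("metaproteomics vs 16S concordance: r = %.4f (p = %.2g, %d genera)",
                conc$r, conc$p, conc$n))
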