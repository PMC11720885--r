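#!/usr/bin/env Rscript
# Stage 7: peptide-trait association.
#
# For bacterial peptides of the differential genera: OLS of each ln-
# transformed, z-scaled clinical trait on peptide log2 abundance, adjusting
# for age, sex, smoking and glycemic status; plus a glycemic-status
# interaction model. BH FDR jointly across all peptide x trait pairs;
# q < 0.05 significant, p < 0.05 suggestive.

source("analysis/00_config.R")

traits <- read_traits()
pep_imp <- read_quant_matrix(file.path(OUT_DIR, "peptide_log2_imputed.tsv"),
                             "log2")
asn <- utils::read.delim(file.path(OUT_DIR, "peptide_assignments.tsv"),
                         stringsAsFactors = FALSE)
gdiff <- utils::read.delim(file.path(OUT_DIR, "genus_differential.tsv"),
                           stringsAsFactors = FALSE)

sel_gen <- gdiff$feature_id[order(gdiff$p)][1:3]
peps <- intersect(asn$peptide[asn$genus %in% sel_gen],
                  rownames(pep_imp$values))
message("testing ", length(peps), " peptides from genera ",
        paste(sel_gen, collapse = ", "))

m <- quant_matrix(pep_imp$values[peps, , drop = FALSE], "log2")
res <- associate_all(m, traits,
                     trait_cols = c("insulin_t30", "waist", "fat_pct"),
                     alpha = PARAMS$alpha_diff)
res$genus <- asn$genus[match(res$peptide, asn$peptide)]
write.table(res, file.path(OUT_DIR, "associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(nrow(res), " peptide x trait pairs: ", sum(res$significant),
        " significant (q < 0.05), ", sum(res$suggestive), " suggestive")
sig <- res[res$significant, ]
if (nrow(sig)) {
  message("significant associations:")
  for (i in seq_len(nrow(sig))) {
    message(sprintf("  %s (%s) ~ %s: beta = %.2f, q = %.3g",
                    sig$peptide[i], sig$genus[i], sig$trait[i],
                    sig$beta[i], sig$q[i]))
  }
}
message("interaction terms significant at p < 0.05: ",
        sum(res$interaction_p < 0.05))
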