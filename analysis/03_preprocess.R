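#!/usr/bin/env Rscript
# Stage 3: quantification-matrix preprocessing.
#
# Protein track: proteotypic rollup -> log2 -> 70% valid-value filter ->
# downshifted-normal imputation (shift 1.8 SD, width 0.3 SD).
# Peptide track: log2 -> 70% filter -> iterative random-forest imputation.

source("analysis/00_config.R")

mats <- read_quant_report(file.path(INPUT_DIR, "quant_report.tsv"))
message("quantified: ", nrow(mats$proteins$values), " proteins, ",
        nrow(mats$peptides$values), " peptides")

prot <- filter_valid(log2_transform(mats$proteins), PARAMS$min_valid_frac)
message("proteins after 70% filter: ", nrow(prot$values),
        sprintf(" (%.1f%% cells missing)", 100 * mean(is.na(prot$values))))
prot_imp <- impute_downshift(prot, impute_params(PARAMS$shift, PARAMS$width,
                                                 seed = SEED))

pep <- filter_valid(log2_transform(mats$peptides), PARAMS$min_valid_frac)
message("peptides after 70% filter: ", nrow(pep$values),
        sprintf(" (%.1f%% cells missing)", 100 * mean(is.na(pep$values))))
t0 <- Sys.time()
pep_imp <- impute_iterative(pep, seed = SEED, num_trees = PARAMS$rf_trees)
message(sprintf("iterative imputation done in %.1f s",
                as.numeric(Sys.time() - t0, units = "secs")))

write_quant_matrix(prot_imp, file.path(OUT_DIR, "protein_log2_imputed.tsv"))
write_quant_matrix(pep_imp, file.path(OUT_DIR, "peptide_log2_imputed.tsv"))
message("imputed matrices written to ", OUT_DIR)
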