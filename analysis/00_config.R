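# Shared configuration for the numbered analysis drivers. Each driver reads
# its inputs from the previous stage's outputs, so they can be run one by one
# or in sequence:
#
#   for f in analysis/0*.R; do Rscript "$f"; done

library(salivamp)

SEED <- 1L
INPUT_DIR <- "results/inputs"
OUT_DIR <- "results"

COHORT_CONFIG <- sim_config(seed = SEED)

PARAMS <- list(
  min_score = 450, top_k = 200,     # 16S alignment retention
  min_valid_frac = 0.7,             # valid-value filter
  shift = 1.8, width = 0.3,         # downshift imputation
  alpha_diff = 0.05,                # differential FDR
  alpha_enrich = 0.02,              # enrichment FDR
  top_k_taxa = 20,                  # taxa tested for relative abundance
  rf_trees = 50                     # iterative peptide imputer
)

read_traits <- function() {
  utils::read.delim(file.path(INPUT_DIR, "traits.tsv"),
                    stringsAsFactors = FALSE)
}

read_design <- function() read_traits()[, c("sample_id", "group")]

read_peptide_info <- function() {
  qr <- utils::read.delim(file.path(INPUT_DIR, "quant_report.tsv"),
                          stringsAsFactors = FALSE)
  unique(qr[, c("peptide", "protein_ids", "proteotypic")])
}
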