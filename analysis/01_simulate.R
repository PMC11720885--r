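#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates a 30-participant (15 HC / 15 T2D) salivary metaproteomics cohort:
# a 7-phylum x 35-genus oral taxonomy, per-species reference 16S + proteins,
# a long-format peptide quantification report with left-censored missingness
# over ~4.5 decades of intensity, per-participant ASV FASTA, genus 16S
# counts, clinical traits and annotations, with planted group/genus/trait
# effects recorded as ground truth.

source("analysis/00_config.R")

tree <- make_taxonomy(COHORT_CONFIG)
bundle <- make_reference_bundle(tree, COHORT_CONFIG$proteins_per_species,
                                seed = SEED)
cohort <- simulate_cohort(COHORT_CONFIG, bundle)
write_cohort(cohort, bundle, INPUT_DIR)

message("taxonomy: ", sum(tree$rank == "genus"), " genera / ",
        sum(tree$rank == "phylum"), " phyla / ",
        sum(tree$rank == "species"), " species")
message("peptides: ", nrow(cohort$peptide_map), " (",
        sum(cohort$peptide_map$origin == "human"), " human, ",
        sum(cohort$peptide_map$origin == "bacterial"), " bacterial)")
message(sprintf("missing cells: %.1f%%",
                100 * mean(is.na(cohort$peptide_matrix$values))))
span <- diff(range(rowMeans(cohort$peptide_log2))) / log2(10)
message(sprintf("dynamic range of feature means: %.2f decades", span))
message("planted: ", nrow(cohort$truth$protein_effects), " protein effects, ",
        nrow(cohort$truth$genus_effects), " genus effects, ",
        nrow(cohort$truth$trait_effects), " trait effects")
message("inputs written to ", INPUT_DIR)
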