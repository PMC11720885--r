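#!/usr/bin/env Rscript
# Stage 2: sample-specific protein-database reduction.
#
# Merges all participants' ASV FASTA into one query set (exact-duplicate
# removal), aligns it to the reference 16S set (Smith-Waterman local, match
# +2 / mismatch -3 / gap 5+2L), retains per query the top 200 hits with raw
# score > 450, and extracts every protein of the retained taxa as the
# reduced search database.

source("analysis/00_config.R")

bundle <- read_reference_bundle(INPUT_DIR)
asv_files <- list.files(file.path(INPUT_DIR, "asv"), full.names = TRUE)
queries <- merge_dedupe(asv_files)
message("merged ", length(queries), " unique ASVs from ",
        length(asv_files), " participants")

params <- reduction_params(min_score = PARAMS$min_score,
                           top_k = PARAMS$top_k)
refs <- stats::setNames(bundle$ref16s$sequence, bundle$ref16s$seq_id)
hits <- filter_hits(align_16s(queries, refs, params), params)
db <- build_reduced_db(hits, bundle)

write.table(hits, file.path(OUT_DIR, "hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(db$provenance, file.path(OUT_DIR, "reduced_db_provenance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(paste0(">", db$proteins$protein_id, "\n", db$proteins$sequence),
           file.path(OUT_DIR, "reduced_db.fasta"))

message(sum(hits$retained), " retained alignments (of ", nrow(hits), ")")
message("reduced database: ", nrow(db$proteins), " proteins from ",
        length(unique(db$proteins$taxon_id)), " taxa (full bundle: ",
        nrow(bundle$proteins), " proteins)")
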