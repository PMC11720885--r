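#' End-to-end pipeline orchestration
#'
#' Runs the full analysis on a synthetic cohort: simulate, database
#' reduction, matrix preprocessing and imputation, differential statistics
#' and PCA, taxonomic profiling, functional enrichment, and trait
#' association. Every stage writes TSV outputs under the run directory and
#' the run report records package version, parameters, seed and output
#' hashes, so two runs with the same configuration are byte-identical.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Stage parameters default to the workflow's canonical values: alignment
#' score > 450 with top 200 hits per query, 70% valid-value filter, downshift
#' 1.8 / width 0.3, FDR 0.05 for differential tests, FDR 0.02 for enrichment,
#' top 20 taxa.
#'
#' @param out_dir run directory.
#' @param seed global seed.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param min_score,top_k alignment filtering ([reduction_params()]).
#' @param min_valid_frac valid-value filter fraction.
#' @param shift,width downshift-imputation parameters.
#' @param alpha_diff,alpha_enrich FDR thresholds.
#' @param top_k_taxa taxa tested for relative-abundance differences.
#' @param rf_trees trees for the iterative peptide imputer.
#' @param asv_subsample optional cap on merged ASVs aligned in the
#'   database-reduction stage (NULL = all).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            min_score = 450, top_k = 200,
                            min_valid_frac = 0.7, shift = 1.8, width = 0.3,
                            alpha_diff = 0.05, alpha_enrich = 0.02,
                            top_k_taxa = 20, rf_trees = 50L,
                            asv_subsample = NULL) {
  sim$seed <- seed
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 min_score = min_score, top_k = top_k,
                 min_valid_frac = min_valid_frac, shift = shift,
                 width = width, alpha_diff = alpha_diff,
                 alpha_enrich = alpha_enrich, top_k_taxa = top_k_taxa,
                 rf_trees = rf_trees, asv_subsample = asv_subsample),
            class = "pipeline_config")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return the run report (also written as `run_report.json`), invisibly
#'   containing headline tables per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  report <- list(
    package = "salivamp",
    version = as.character(utils::packageVersion("salivamp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir", "sim"))],
    sim = config$sim[setdiff(names(config$sim),
                             c("planted_protein_effects",
                               "planted_genus_effects", "trait_effects"))],
    stages = character())

  ## simulate ------------------------------------------------------------
  cohort <- with_stage("simulate", {
    tree <- make_taxonomy(config$sim)
    bundle <- make_reference_bundle(tree, config$sim$proteins_per_species,
                                    seed = config$seed)
    ch <- simulate_cohort(config$sim, bundle)
    write_cohort(ch, bundle, out("inputs"))
    ch$bundle <- bundle
    ch
  })
  report$stages <- c(report$stages, "simulate")

  ## build-db ------------------------------------------------------------
  db <- with_stage("build_db", {
    merged <- merge_dedupe(unname(cohort$asv))
    if (!is.null(config$asv_subsample) && length(merged) > config$asv_subsample) {
      merged <- merged[seq_len(config$asv_subsample)]
    }
    params <- reduction_params(min_score = config$min_score,
                               top_k = config$top_k)
    refs <- stats::setNames(cohort$bundle$ref16s$sequence,
                            cohort$bundle$ref16s$seq_id)
    hits <- filter_hits(align_16s(merged, refs, params), params)
    red <- build_reduced_db(hits, cohort$bundle)
    write_tsv(hits, out("hits.tsv"))
    write_tsv(red$provenance, out("reduced_db_provenance.tsv"))
    write_fasta(stats::setNames(red$proteins$sequence, red$proteins$protein_id),
                out("reduced_db.fasta"))
    list(n_merged = length(merged), n_hits = sum(hits$retained),
         n_proteins = nrow(red$proteins),
         n_taxa = length(unique(red$proteins$taxon_id)))
  })
  report$stages <- c(report$stages, "build_db")
  report$build_db <- db

  ## preprocess ----------------------------------------------------------
  pp <- with_stage("preprocess", {
    mats <- read_quant_report(cohort$quant_report)
    prot <- filter_valid(log2_transform(mats$proteins), config$min_valid_frac)
    prot_imp <- impute_downshift(prot, impute_params(config$shift, config$width,
                                                     seed = config$seed))
    pep <- filter_valid(log2_transform(mats$peptides), config$min_valid_frac)
    pep_imp <- impute_iterative(pep, seed = config$seed,
                                num_trees = config$rf_trees)
    write_quant_matrix(prot_imp, out("protein_log2_imputed.tsv"))
    write_quant_matrix(pep_imp, out("peptide_log2_imputed.tsv"))
    list(proteins = prot_imp, peptides = pep_imp, info = mats$peptide_info,
         n_proteins = nrow(prot_imp$values), n_peptides = nrow(pep_imp$values))
  })
  report$stages <- c(report$stages, "preprocess")
  report$preprocess <- pp[c("n_proteins", "n_peptides")]

  design <- cohort$traits[, c("sample_id", "group")]
  origin <- ifelse(grepl("^HUM_", rownames(pp$proteins$values)),
                   "human", "bacterial")
  names(origin) <- rownames(pp$proteins$values)

  ## diff ----------------------------------------------------------------
  diff <- with_stage("diff", {
    tab <- differential_table(pp$proteins, design, alpha = config$alpha_diff,
                              origin = origin)
    pca <- pca_quant(pp$proteins)
    write_tsv(tab, out("differential_proteins.tsv"))
    write_tsv(pca_drivers(pca, 1, 25), out("pc1_drivers.tsv"))
    list(tab = tab, pca = pca)
  })
  report$stages <- c(report$stages, "diff")
  report$diff <- list(
    n_significant = sum(diff$tab$direction != "ns"),
    n_up = sum(diff$tab$direction == "up"),
    n_down = sum(diff$tab$direction == "down"),
    by_origin = as.list(table(diff$tab$origin[diff$tab$direction != "ns"])),
    pc1_pc2_var = sum(diff$pca$var_explained[1:2]))

  ## taxa ----------------------------------------------------------------
  taxa <- with_stage("taxa", {
    bact <- cohort$peptide_map[cohort$peptide_map$origin == "bacterial", ]
    asn <- assign_peptides(bact,
                           cohort$bundle$proteins[, c("protein_id", "taxon_id")],
                           cohort$tree)
    mapping <- summarize_mapping(asn)
    raw_pep <- quant_matrix(
      cohort$peptide_matrix$values[
        intersect(rownames(cohort$peptide_matrix$values), bact$peptide), ,
        drop = FALSE], "raw")
    comp <- relative_abundance(raw_pep, asn, "genus")
    bact_in_mat <- intersect(rownames(pp$peptides$values), bact$peptide)
    gdiff <- genus_intensity_diff(
      quant_matrix(pp$peptides$values[bact_in_mat, , drop = FALSE], "log2"),
      asn, design, alpha = config$alpha_diff)
    radiff <- relative_abundance_diff(comp, design, top_k = config$top_k_taxa,
                                      alpha = config$alpha_diff)
    v <- raw_pep$values; v[is.na(v)] <- 0
    genus_of <- asn$genus[match(rownames(v), asn$peptide)]
    keep <- !is.na(genus_of)
    ms_raw <- rowsum(v[keep, , drop = FALSE], genus_of[keep])
    conc <- concordance(rowSums(ms_raw),
                        rowSums(cohort$s16_counts)[rownames(ms_raw)])
    write_tsv(asn, out("peptide_assignments.tsv"))
    write_tsv(mapping, out("mapping_summary.tsv"))
    write_matrix_tsv(comp, out("genus_composition.tsv"), id_col = "genus")
    write_tsv(gdiff, out("genus_differential.tsv"))
    write_tsv(radiff, out("relative_abundance_differential.tsv"))
    list(asn = asn, mapping = mapping, gdiff = gdiff, radiff = radiff,
         conc = conc)
  })
  report$stages <- c(report$stages, "taxa")
  report$taxa <- list(mapping = taxa$mapping,
                      concordance_r = taxa$conc$r,
                      concordance_p = taxa$conc$p,
                      n_genera_significant = sum(taxa$gdiff$direction != "ns"))

  ## enrich --------------------------------------------------------------
  enr <- with_stage("enrich", {
    fc <- stats::setNames(diff$tab$log2fc, diff$tab$feature_id)
    e1 <- enrich_1d(fc, cohort$annotations, alpha = config$alpha_enrich)
    bact_in_mat <- intersect(rownames(pp$peptides$values),
                             cohort$peptide_map$peptide[
                               cohort$peptide_map$origin == "bacterial"])
    pepv <- pp$peptides$values[bact_in_mat, , drop = FALSE]
    hc_mean <- rowMeans(pepv[, design$group == "HC", drop = FALSE])
    t2d_mean <- rowMeans(pepv[, design$group == "T2D", drop = FALSE])
    e2 <- enrich_2d(t2d_mean, hc_mean, cohort$annotations,
                    alpha = config$alpha_enrich)
    # cluster peptides of the two most differential genera
    top_gen <- taxa$gdiff$feature_id[order(taxa$gdiff$p)][1:2]
    peps <- taxa$asn$peptide[taxa$asn$genus %in% top_gen]
    peps <- intersect(rownames(pp$peptides$values), peps)
    cl <- hcluster(pp$peptides$values[peps, , drop = FALSE], k = 2)
    fe <- fisher_cluster(cl$labels, cohort$annotations,
                         alpha = config$alpha_enrich)
    write_tsv(e1, out("enrichment_1d.tsv"))
    write_tsv(e2, out("enrichment_2d.tsv"))
    write_tsv(fe, out("cluster_enrichment.tsv"))
    list(e1 = e1, e2 = e2, fe = fe, clustered_genera = top_gen)
  })
  report$stages <- c(report$stages, "enrich")
  report$enrich <- list(n_terms_1d = sum(enr$e1$significant),
                        n_terms_2d = sum(enr$e2$significant),
                        n_cluster_terms = sum(enr$fe$significant),
                        clustered_genera = enr$clustered_genera)

  ## associate -----------------------------------------------------------
  assoc <- with_stage("associate", {
    sel_gen <- unique(c(enr$clustered_genera,
                        cohort$truth$genus_effects$genus))
    peps <- taxa$asn$peptide[taxa$asn$genus %in% sel_gen]
    peps <- intersect(rownames(pp$peptides$values), peps)
    if (!length(peps)) stop("no peptides from selected genera survive filtering")
    am <- quant_matrix(pp$peptides$values[peps, , drop = FALSE], "log2")
    res <- associate_all(am, cohort$traits,
                         trait_cols = c("insulin_t30", "waist", "fat_pct"),
                         alpha = config$alpha_diff)
    write_tsv(res, out("associations.tsv"))
    res
  })
  report$stages <- c(report$stages, "associate")
  report$associate <- list(n_pairs = nrow(assoc),
                           n_significant = sum(assoc$significant),
                           n_suggestive = sum(assoc$suggestive))

  tsvs <- list.files(config$out_dir, pattern = "[.]tsv$", full.names = TRUE)
  report$output_md5 <- as.list(tools::md5sum(tsvs))
  names(report$output_md5) <- basename(tsvs)
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = 10, force = TRUE)
  invisible(report)
}
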