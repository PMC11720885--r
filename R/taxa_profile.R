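#' Peptide-level taxonomic profiling
#'
#' Assigns each bacterial peptide to the lowest common ancestor (LCA) of the
#' taxa of its matched proteins, projects the LCA onto genus and phylum
#' (peptides resolving below genus count as that genus), summarises mapping
#' rates, rolls raw intensities up into per-taxon relative abundances, tests
#' genus-level intensity differences, and measures metaproteomics-vs-16S
#' concordance.
#'
#' @name taxa_profile
NULL

#' Assign peptides to taxa by LCA
#'
#' @param peptide_map data.frame with `peptide` and `protein_ids`
#'   (semicolon-joined matched proteins; empty = unmatched).
#' @param protein_map data.frame (`protein_id`, `taxon_id`); every matched
#'   protein must have a taxon.
#' @param tree a [taxonomy_tree()].
#' @return data.frame: peptide, protein_ids, n_taxa, lca, lca_rank, genus,
#'   phylum, genus_specific, mapped.
#' @export
assign_peptides <- function(peptide_map, protein_map, tree) {
  req <- c("peptide", "protein_ids")
  miss <- setdiff(req, names(peptide_map))
  if (length(miss)) stop("peptide_map lacks column(s): ", paste(miss, collapse = ", "))
  ptax <- stats::setNames(protein_map$taxon_id, protein_map$protein_id)
  n <- nrow(peptide_map)
  lca_id <- genus <- phylum <- rep(NA_character_, n)
  n_taxa <- integer(n)
  for (i in seq_len(n)) {
    pids <- strsplit(peptide_map$protein_ids[[i]], ";")[[1]]
    pids <- pids[nzchar(pids)]
    if (!length(pids)) next
    missing_prot <- setdiff(pids, names(ptax))
    if (length(missing_prot)) {
      stop("protein(s) without taxon mapping: ", paste(missing_prot, collapse = ", "))
    }
    taxa <- unique(unname(ptax[pids]))
    n_taxa[[i]] <- length(taxa)
    lca_id[[i]] <- lca(tree, taxa)
    genus[[i]] <- ancestor_at_rank(tree, lca_id[[i]], "genus")
    phylum[[i]] <- ancestor_at_rank(tree, lca_id[[i]], "phylum")
  }
  data.frame(peptide = peptide_map$peptide,
             protein_ids = peptide_map$protein_ids,
             n_taxa = n_taxa, lca = lca_id,
             lca_rank = ifelse(is.na(lca_id), NA, unname(tree$rank[lca_id])),
             genus = genus, phylum = phylum,
             genus_specific = !is.na(genus),
             mapped = !is.na(lca_id),
             stringsAsFactors = FALSE)
}

#' Integer mapping percentage
#'
#' @param n_mapped,n_total counts.
#' @return `round(100 * n_mapped / n_total)`.
#' @export
mapping_percentage <- function(n_mapped, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  round(100 * n_mapped / n_total)
}

#' Summarise peptide-to-taxon mapping
#'
#' Counts peptides whose LCA projects to genus and to phylum, with integer
#' percentages of the total.
#'
#' @param assignments an [assign_peptides()] result.
#' @return data.frame: level, n_mapped, n_total, percent.
#' @export
summarize_mapping <- function(assignments) {
  total <- nrow(assignments)
  ng <- sum(!is.na(assignments$genus))
  np <- sum(!is.na(assignments$phylum))
  data.frame(level = c("genus", "phylum"),
             n_mapped = c(ng, np), n_total = total,
             percent = c(mapping_percentage(ng, total),
                         mapping_percentage(np, total)),
             stringsAsFactors = FALSE)
}

#' Per-sample relative abundance at a taxonomic rank
#'
#' Sums raw peptide intensities per taxon at the requested rank within each
#' sample (missing cells contribute 0), adds an `unassigned` bin for peptides
#' without a taxon at that rank, and divides by the sample total, so every
#' column sums to 1.
#'
#' @param m a raw-space peptide [quant_matrix()].
#' @param assignments an [assign_peptides()] result.
#' @param rank `"genus"` or `"phylum"`.
#' @return taxa x samples matrix of relative abundances (class
#'   `composition`), last row `unassigned`.
#' @export
relative_abundance <- function(m, assignments, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  stopifnot(inherits(m, "quant_matrix"))
  if (m$space != "raw") stop("relative_abundance expects raw-space intensities")
  tax <- assignments[[rank]][match(rownames(m$values), assignments$peptide)]
  tax[is.na(tax)] <- "unassigned"
  v <- m$values
  v[is.na(v)] <- 0
  agg <- rowsum(v, group = tax)
  taxa <- setdiff(sort(rownames(agg)), "unassigned")
  agg <- agg[c(taxa, intersect("unassigned", rownames(agg))), , drop = FALSE]
  totals <- colSums(agg)
  if (any(totals == 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(colnames(agg)[totals == 0], collapse = ", "))
  }
  comp <- sweep(agg, 2, totals, "/")
  class(comp) <- c("composition", class(comp))
  comp
}

#' Genus-level differential intensity
#'
#' Exactly the four-step genus rollup: back-transform the imputed log2
#' peptide matrix, sum raw intensity per genus over unique genus-specific
#' bacterial peptides, log2-transform the genus totals, then per-genus pooled
#' t tests with BH adjustment.
#'
#' @param m an imputed log2 peptide [quant_matrix()].
#' @param assignments an [assign_peptides()] result.
#' @param design data.frame with `sample_id`, `group`.
#' @param groups reference group first.
#' @param alpha FDR threshold.
#' @return a [differential_table()]-shaped data.frame, one row per genus.
#' @export
genus_intensity_diff <- function(m, assignments, design,
                                 groups = c("HC", "T2D"), alpha = 0.05) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$space != "log2") stop("expects a log2 matrix (imputed)")
  raw <- back_transform(m)
  keep <- assignments$peptide[assignments$genus_specific]
  keep <- intersect(rownames(raw$values), unique(keep))
  if (!length(keep)) stop("no genus-specific peptides in the matrix")
  g <- assignments$genus[match(keep, assignments$peptide)]
  totals <- rowsum(raw$values[keep, , drop = FALSE], group = g)
  genus_log2 <- quant_matrix(log2(totals), "log2")
  differential_table(genus_log2, design, groups = groups, alpha = alpha)
}

#' Differential relative abundance of the top-k taxa
#'
#' Pooled t tests on per-sample relative abundances of the `top_k` taxa by
#' overall mean abundance (the `unassigned` bin is never ranked), BH-adjusted
#' across the `top_k`.
#'
#' @param comp a [relative_abundance()] matrix.
#' @param design data.frame with `sample_id`, `group`.
#' @param top_k number of taxa tested.
#' @param groups reference group first.
#' @param alpha FDR threshold.
#' @return data.frame: taxon, mean_abundance, diff (group2 - group1), t, p,
#'   q, significant.
#' @export
relative_abundance_diff <- function(comp, design, top_k = 20,
                                    groups = c("HC", "T2D"), alpha = 0.05) {
  taxa <- setdiff(rownames(comp), "unassigned")
  if (top_k > length(taxa)) top_k <- length(taxa)
  mean_ab <- rowMeans(comp[taxa, , drop = FALSE])
  top <- names(sort(mean_ab, decreasing = TRUE))[seq_len(top_k)]
  idx <- group_split(comp, design, groups)
  rows <- lapply(top, function(tx) {
    v <- comp[tx, ]
    ts <- two_sample_t(v[idx[[2]]], v[idx[[1]]])
    data.frame(taxon = tx, mean_abundance = mean_ab[[tx]],
               diff = mean(v[idx[[2]]]) - mean(v[idx[[1]]]),
               t = ts$t, p = ts$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out
}

#' Metaproteomics vs 16S concordance
#'
#' Pearson correlation between per-genus total intensity in the
#' metaproteomics data and per-genus total reads in the 16S data, over the
#' union of genera (a genus absent from one dataset contributes 0, with a
#' warning); two-sided p via the t transform.
#'
#' @param ms_totals,s16_totals named numeric vectors (genus -> total).
#' @return list: `r`, `p`, `n`, `genera`.
#' @export
concordance <- function(ms_totals, s16_totals) {
  stopifnot(!is.null(names(ms_totals)), !is.null(names(s16_totals)))
  genera <- union(names(ms_totals), names(s16_totals))
  if (length(genera) < 3) stop("need >= 3 genera for a correlation")
  only <- c(setdiff(names(ms_totals), names(s16_totals)),
            setdiff(names(s16_totals), names(ms_totals)))
  if (length(only)) {
    warning("genera present in only one dataset filled with 0: ",
            paste(only, collapse = ", "))
  }
  x <- stats::setNames(rep(0, length(genera)), genera)
  y <- x
  x[names(ms_totals)] <- ms_totals
  y[names(s16_totals)] <- s16_totals
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genera),
       genera = genera)
}
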