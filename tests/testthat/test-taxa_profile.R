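tiny_protein_map <- function() {
  data.frame(protein_id = c("P1", "P2", "P3", "P4", "P5"),
             taxon_id = c("s1a", "s1b", "s2a", "s3a", "s1a"),
             stringsAsFactors = FALSE)
}

test_that("assign_peptides agrees with the lineage-intersection oracle", {
  tr <- tiny_tree()
  pm <- tiny_protein_map()
  peps <- data.frame(
    peptide = c("single", "two_sp_one_genus", "two_phyla", "unmatched"),
    protein_ids = c("P1", "P1;P2", "P1;P4", ""),
    stringsAsFactors = FALSE)
  asn <- assign_peptides(peps, pm, tr)

  expect_equal(asn$lca[1], "s1a")
  expect_equal(asn$genus[1], "g1")
  expect_equal(asn$phylum[1], "pA")
  expect_equal(asn$lca[2], "g1")
  expect_true(asn$genus_specific[2])
  expect_equal(asn$lca[3], "root")
  expect_true(is.na(asn$genus[3]) && is.na(asn$phylum[3]))
  expect_false(asn$mapped[4])

  # randomized fixtures vs full-lineage intersection
  set.seed(30)
  ptax <- stats::setNames(pm$taxon_id, pm$protein_id)
  for (i in 1:30) {
    pick <- sample(pm$protein_id, sample(1:3, 1))
    a <- assign_peptides(data.frame(peptide = "q",
                                    protein_ids = paste(pick, collapse = ";")),
                         pm, tr)
    expect_equal(a$lca, oracle_lca(tr, unique(unname(ptax[pick]))))
  }
  expect_error(assign_peptides(data.frame(peptide = "q", protein_ids = "PX"),
                               pm, tr), "without taxon")
})

test_that("mapping summary counts and percentages", {
  expect_equal(mapping_percentage(3519, 7452), 47)
  expect_equal(mapping_percentage(3150, 7452), 42)
  tr <- tiny_tree()
  pm <- tiny_protein_map()
  peps <- data.frame(peptide = paste0("q", 1:4),
                     protein_ids = c("P1", "P2", "P1;P4", "P3"),
                     stringsAsFactors = FALSE)
  s <- summarize_mapping(assign_peptides(peps, pm, tr))
  expect_equal(s$n_mapped[s$level == "genus"], 3L)   # q3 spans phyla
  expect_equal(s$n_mapped[s$level == "phylum"], 3L)
  expect_equal(s$percent[s$level == "genus"], 75)

  all_single <- data.frame(peptide = paste0("q", 1:3),
                           protein_ids = c("P1", "P3", "P4"))
  s2 <- summarize_mapping(assign_peptides(all_single, pm, tr))
  expect_equal(s2$percent, c(100, 100))
})

test_that("relative abundance normalises per sample with an unassigned bin", {
  tr <- tiny_tree()
  pm <- tiny_protein_map()
  peps <- data.frame(peptide = c("q1", "q2", "q3"),
                     protein_ids = c("P1", "P3", "P1;P4"),
                     stringsAsFactors = FALSE)
  asn <- assign_peptides(peps, pm, tr)
  v <- matrix(c(3, 1, 4,
                6, 2, 0), 3, 2,
              dimnames = list(c("q1", "q2", "q3"), c("s1", "s2")))
  v[v == 0] <- NA
  comp <- relative_abundance(quant_matrix(v, "raw"), asn, "genus")
  # s1: g1 = 3, g2 = 1, unassigned = 4 -> totals 8
  expect_equal(comp["g1", "s1"], 3 / 8)
  expect_equal(comp["g2", "s1"], 1 / 8)
  expect_equal(comp["unassigned", "s1"], 4 / 8)
  # s2: 3:1 ratio
  expect_equal(comp["g1", "s2"], 0.75)
  expect_equal(unname(colSums(comp)), c(1, 1))

  single <- relative_abundance(quant_matrix(v[1, , drop = FALSE], "raw"),
                               asn, "genus")
  expect_equal(unname(single["g1", ]), c(1, 1))

  vz <- v; vz[, 2] <- NA
  expect_error(relative_abundance(quant_matrix(vz, "raw"), asn, "genus"),
               "zero total")
})

test_that("genus rollup conserves total assigned intensity", {
  tr <- tiny_tree()
  pm <- tiny_protein_map()
  peps <- data.frame(peptide = paste0("q", 1:6),
                     protein_ids = c("P1", "P2", "P3", "P4", "P1;P2", "P1;P4"),
                     stringsAsFactors = FALSE)
  asn <- assign_peptides(peps, pm, tr)
  set.seed(31)
  v <- matrix(runif(12, 10, 100), 6, 2,
              dimnames = list(peps$peptide, c("s1", "s2")))
  genus_of <- asn$genus[match(rownames(v), asn$peptide)]
  roll <- rowsum(v[!is.na(genus_of), ], genus_of[!is.na(genus_of)])
  expect_equal(unname(colSums(roll)),
               unname(colSums(v) - colSums(v[is.na(genus_of), , drop = FALSE])))
})

test_that("genus_intensity_diff is exact on a noiseless planted shift", {
  tr <- tiny_tree()
  pm <- tiny_protein_map()
  design <- two_group_design(3)
  peps <- data.frame(peptide = c("q1", "q2", "q3"),
                     protein_ids = c("P1", "P2", "P3"),
                     stringsAsFactors = FALSE)
  asn <- assign_peptides(peps, pm, tr)
  base <- matrix(rep(c(10, 11, 12), 6), 3, 6,
                 dimnames = list(peps$peptide, design$sample_id))
  delta <- 1.7
  shifted <- base
  shifted[c("q1", "q2"), design$group == "T2D"] <-
    shifted[c("q1", "q2"), design$group == "T2D"] + delta
  # add tiny within-group jitter so variances are nonzero
  set.seed(32)
  jit <- matrix(rep(rnorm(6, 0, 0.01), each = 3), 3, 6)
  res <- genus_intensity_diff(quant_matrix(shifted + jit, "log2"), asn, design)
  expect_equal(res$log2fc[res$feature_id == "g1"], delta, tolerance = 0.02)
  # single-peptide genus equals that peptide's log2 value
  g2row <- res[res$feature_id == "g2", ]
  expect_equal(g2row$log2fc, 0, tolerance = 0.02)

  # a genus with no genus-specific peptides is excluded
  peps2 <- data.frame(peptide = "q9", protein_ids = "P1;P4")
  asn2 <- assign_peptides(peps2, pm, tr)
  m2 <- quant_matrix(matrix(10, 1, 6, dimnames = list("q9", design$sample_id)),
                     "log2")
  expect_error(genus_intensity_diff(m2, asn2, design), "genus-specific")
})

test_that("planted genus effects are detected with high power, null controlled", {
  n_rep <- 200
  detected <- logical(n_rep)
  null_fdr <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_per_group = 15, n_human_peptides = 2,
                      n_bacterial_peptides = 24, n_phyla = 2,
                      genera_per_phylum = 2, species_per_genus = 1,
                      proteins_per_species = 3, missing_rate = 0,
                      feature_sd = 0.5,
                      planted_protein_effects = data.frame(
                        feature = character(), log2fc = numeric()),
                      planted_genus_effects = data.frame(genus = "p01_g01",
                                                         log2fc = 1),
                      seed = 5000 + r)
    b <- make_reference_bundle(make_taxonomy(cfg), 3, seed = 5000 + r)
    ch <- simulate_cohort(cfg, b)
    bact <- ch$peptide_map[ch$peptide_map$origin == "bacterial", ]
    asn <- assign_peptides(bact, b$proteins[, c("protein_id", "taxon_id")],
                           b$tree)
    m <- log2_transform(quant_matrix(
      ch$peptide_matrix$values[bact$peptide, , drop = FALSE], "raw"))
    res <- genus_intensity_diff(m, asn, ch$traits[, c("sample_id", "group")])
    detected[r] <- isTRUE(res$direction[res$feature_id == "p01_g01"] == "up")
    nulls <- res[res$feature_id != "p01_g01", ]
    null_fdr[r] <- if (nrow(nulls)) mean(nulls$q < 0.05) else 0
  }
  expect_gt(mean(detected), 0.9)
  expect_lte(mean(null_fdr), 0.05)
})

test_that("relative_abundance_diff tests the top-k taxa", {
  design <- two_group_design(4)
  comp <- matrix(c(rep(c(0.5, 0.3, 0.2), 4),    # HC columns
                   rep(c(0.3, 0.5, 0.2), 4)),   # T2D columns
                 3, 8, dimnames = list(c("g1", "g2", "g3"), design$sample_id))
  set.seed(33)
  comp <- comp + matrix(rnorm(24, 0, 0.01), 3, 8)
  comp <- sweep(comp, 2, colSums(comp), "/")
  res <- relative_abundance_diff(comp, design, top_k = 3)
  expect_true(res$significant[res$taxon == "g1"])
  expect_lt(res$diff[res$taxon == "g1"], 0)
  expect_gt(res$diff[res$taxon == "g2"], 0)

  # identical compositions -> all p = 1
  flat <- matrix(rep(c(0.6, 0.4), 8), 2, 8,
                 dimnames = list(c("g1", "g2"), design$sample_id))
  res_flat <- relative_abundance_diff(flat, design, top_k = 2)
  expect_equal(res_flat$p, rep(1, 2))

  # top-k selection equals a sort oracle
  set.seed(34)
  big <- matrix(runif(80), 10, 8,
                dimnames = list(paste0("t", 1:10), design$sample_id))
  big <- sweep(big, 2, colSums(big), "/")
  res_big <- relative_abundance_diff(big, design, top_k = 4)
  expect_setequal(res_big$taxon,
                  names(sort(rowMeans(big), decreasing = TRUE))[1:4])
})

test_that("concordance computes Pearson r with union-fill semantics", {
  x <- stats::setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  expect_equal(concordance(x, x)$r, 1)
  rev_lin <- stats::setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  expect_equal(concordance(x, rev_lin)$r, -1)
  set.seed(35)
  a <- stats::setNames(runif(10), paste0("g", 1:10))
  b <- stats::setNames(runif(10), paste0("g", 1:10))
  got <- concordance(a, b)
  expect_equal(got$r, sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_equal(got$p, cor.test(a, b)$p.value)
  expect_warning(concordance(a, b[1:5]), "filled with 0")
  expect_error(concordance(a[1:2], b[1:2]), ">= 3")
})
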