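test_that("config validation and taxonomy shape", {
  expect_error(sim_config(n_phyla = 0), "invalid config")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(censoring_strength = -1), "censoring_strength")
  tr <- make_taxonomy(sim_config(n_phyla = 7, genera_per_phylum = 5,
                                 species_per_genus = 3))
  expect_equal(sum(tr$rank == "genus"), 35L)
  expect_equal(sum(tr$rank == "phylum"), 7L)
  expect_equal(sum(tr$rank == "species"), 105L)
})

test_that("reference bundle: ID pattern, referential integrity, 16S structure", {
  cfg <- tiny_config()
  tr <- make_taxonomy(cfg)
  b <- make_reference_bundle(tr, proteins_per_species = 3, seed = 3)
  expect_true(all(grepl("^SEQF[0-9]{4}_[0-9]{5}$", b$proteins$protein_id)))
  expect_true(all(b$proteins$taxon_id %in% tr$nodes$taxon_id))
  expect_equal(nrow(b$ref16s), sum(tr$rank == "species"))
  expect_equal(sum(b$proteins$taxon_id == b$ref16s$taxon_id[1]), 3L)

  # brute-force Hamming identity: within-genus pairs > cross-phylum pairs
  ident <- function(x, y) {
    a <- strsplit(x, "")[[1]]; bb <- strsplit(y, "")[[1]]
    mean(a == bb)
  }
  genus_of <- vapply(b$ref16s$taxon_id, function(s) tr$parent[[s]], character(1))
  phylum_of <- vapply(b$ref16s$taxon_id,
                      function(s) ancestor_at_rank(tr, s, "phylum"), character(1))
  within_genus <- c(); cross_phylum <- c()
  n <- nrow(b$ref16s)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- ident(b$ref16s$sequence[i], b$ref16s$sequence[j])
    if (genus_of[i] == genus_of[j]) within_genus <- c(within_genus, id)
    if (phylum_of[i] != phylum_of[j]) cross_phylum <- c(cross_phylum, id)
  }
  expect_gt(min(within_genus), max(cross_phylum))
})

test_that("cohort simulation is seed-deterministic and bookkeeps truth", {
  cfg <- tiny_config(seed = 21)
  b <- make_reference_bundle(make_taxonomy(cfg), cfg$proteins_per_species, seed = 21)
  ch1 <- simulate_cohort(cfg, b)
  ch2 <- simulate_cohort(cfg, b)
  expect_identical(ch1, ch2)

  # every bacterial peptide maps to >= 1 bundle protein
  bact <- ch1$peptide_map[ch1$peptide_map$origin == "bacterial", ]
  prots <- unlist(strsplit(bact$protein_ids, ";"))
  expect_true(all(prots %in% b$proteins$protein_id))

  # truth lists exactly the planted non-null features
  expect_true(all(ch1$truth$protein_effects$log2fc != 0))
  expect_true(all(ch1$truth$genus_effects$genus %in%
                    b$tree$nodes$taxon_id[b$tree$rank == "genus"]))
  expect_error(
    simulate_cohort(tiny_config(planted_protein_effects = data.frame(
      feature = "NOPE", log2fc = 2)), b),
    "unknown feature")
})

test_that("missingness is left-censored and hits the target rate", {
  cfg <- tiny_config(seed = 31, missing_rate = 0.3, censoring_strength = 2)
  b <- make_reference_bundle(make_taxonomy(cfg), cfg$proteins_per_species, seed = 31)
  ch <- simulate_cohort(cfg, b)
  x <- ch$peptide_log2
  obs <- ch$peptide_matrix$values
  # row/col alignment between latent and observed matrices
  x <- x[rownames(obs), colnames(obs)]
  expect_lt(abs(mean(is.na(obs)) - 0.3), 0.06)
  dec <- cut(as.vector(x), stats::quantile(x, c(0, 0.1, 0.9, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "high"))
  miss <- tapply(as.vector(is.na(obs)), dec, mean)
  expect_gt(miss[["low"]], miss[["high"]])

  # missing_rate = 0 gives a complete matrix
  cfg0 <- tiny_config(seed = 31, missing_rate = 0)
  ch0 <- simulate_cohort(cfg0, b)
  expect_false(anyNA(ch0$peptide_matrix$values))
})

test_that("planted log2FC is recovered across Monte-Carlo replicates", {
  # one planted protein, log2FC = 2, sigma = 0.5, n = 15/15
  diffs <- vapply(1:100, function(r) {
    cfg <- sim_config(n_per_group = 15, n_human_peptides = 6,
                      n_bacterial_peptides = 4, n_phyla = 1,
                      genera_per_phylum = 1, species_per_genus = 1,
                      proteins_per_species = 3, missing_rate = 0,
                      feature_sd = 0.5,
                      planted_protein_effects = data.frame(
                        feature = "HUM_0001", log2fc = 2),
                      planted_genus_effects = data.frame(
                        genus = character(), log2fc = numeric()),
                      seed = 1000 + r)
    b <- make_reference_bundle(make_taxonomy(cfg), 3, seed = 1000 + r)
    ch <- simulate_cohort(cfg, b)
    pep <- ch$peptide_map$peptide[ch$peptide_map$protein_ids == "HUM_0001"][1]
    v <- log2(ch$peptide_matrix$values[pep, ])
    g <- ch$traits$group
    mean(v[g == "T2D"]) - mean(v[g == "HC"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2), 3 * se + 1e-12)
})

test_that("feature means span the configured dynamic range", {
  cfg <- sim_config(seed = 5)
  b <- make_reference_bundle(make_taxonomy(cfg), cfg$proteins_per_species, seed = 5)
  ch <- simulate_cohort(cfg, b)
  hc <- ch$traits$sample_id[ch$traits$group == "HC"]
  means <- rowMeans(ch$peptide_log2[, hc])
  span_decades <- diff(range(means)) / log2(10)
  expect_equal(span_decades, 4.5, tolerance = 0.1)
})

test_that("cohort files round-trip through write_cohort", {
  cfg <- tiny_config(seed = 41)
  b <- make_reference_bundle(make_taxonomy(cfg), cfg$proteins_per_species, seed = 41)
  ch <- simulate_cohort(cfg, b)
  dir <- withr::local_tempdir()
  write_cohort(ch, b, dir)
  expect_true(file.exists(file.path(dir, "quant_report.tsv")))
  qr <- read_quant_report(file.path(dir, "quant_report.tsv"))
  expect_equal(qr$peptides$values, ch$peptide_matrix$values)
  tr2 <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tr2$nodes, b$tree$nodes)
  pm <- read_protein_map(file.path(dir, "protein_map.tsv"))
  expect_setequal(pm$protein_id, b$proteins$protein_id)
  expect_true(file.exists(file.path(dir, "asv",
                                    paste0(ch$traits$sample_id[1], ".fasta"))))
})
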