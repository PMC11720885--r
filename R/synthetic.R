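#' Synthetic study-input generator
#'
#' Generates a complete synthetic case-control cohort with the statistical
#' structure the downstream analysis assumes: a rank-labelled oral-bacteria
#' taxonomy, a reference bundle (per-species 16S sequences plus
#' taxon-to-protein records with SEQFxxxx_yyyyy identifiers), a long-format
#' peptide quantification report whose log2 intensities span several decades
#' with left-censored (intensity-dependent) missingness, per-participant
#' amplicon (ASV) FASTA, a genus-level 16S count table, clinical traits, and
#' functional annotations. Planted group, genus and trait effects are recorded
#' in a truth table so recovery can be tested.
#'
#' @name synthetic_data
NULL

# guard against sample()'s length-1 surprise
resample <- function(x, n, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: two groups
#' of 15 participants, 7 phyla x 5 genera x 3 species, human and bacterial
#' peptides with feature means spread over 4.5 decades, 25% missing values
#' concentrated at low intensities.
#'
#' @param n_per_group participants per group (HC and T2D).
#' @param n_human_peptides,n_bacterial_peptides peptide counts.
#' @param n_phyla,genera_per_phylum,species_per_genus taxonomy shape.
#' @param proteins_per_species reference proteins per species.
#' @param dynamic_range_log10 spread of feature mean intensities, in decades.
#' @param feature_sd per-feature biological SD in log2 units.
#' @param missing_rate overall fraction of missing peptide cells.
#' @param censoring_strength logistic slope of missingness on z-scored log2
#'   intensity; 0 gives missing-completely-at-random.
#' @param planted_protein_effects data.frame (`feature`, `log2fc`) of group
#'   effects on proteins, or `NULL` for the built-in default panel.
#' @param planted_genus_effects data.frame (`genus`, `log2fc`) or `NULL`.
#' @param trait_effects data.frame (`peptide`, `trait`, `slope`) of planted
#'   peptide-trait slopes on the ln-trait scale, or `NULL`.
#' @param seed master seed; all stages derive sub-streams from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = 15,
                       n_human_peptides = 600,
                       n_bacterial_peptides = 450,
                       n_phyla = 7,
                       genera_per_phylum = 5,
                       species_per_genus = 3,
                       proteins_per_species = 20,
                       dynamic_range_log10 = 4.5,
                       feature_sd = 0.5,
                       missing_rate = 0.25,
                       censoring_strength = 1.5,
                       planted_protein_effects = NULL,
                       planted_genus_effects = NULL,
                       trait_effects = NULL,
                       seed = 1L) {
  counts <- c(n_per_group = n_per_group, n_human_peptides = n_human_peptides,
              n_bacterial_peptides = n_bacterial_peptides, n_phyla = n_phyla,
              genera_per_phylum = genera_per_phylum,
              species_per_genus = species_per_genus,
              proteins_per_species = proteins_per_species)
  if (any(counts < 1)) {
    stop("invalid config: count fields must be >= 1 (",
         paste(names(counts)[counts < 1], collapse = ", "), ")")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid config: missing_rate must be in [0, 1)")
  if (censoring_strength < 0) stop("invalid config: censoring_strength must be >= 0")
  if (dynamic_range_log10 <= 0 || feature_sd <= 0) {
    stop("invalid config: dynamic_range_log10 and feature_sd must be > 0")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a rank-labelled taxonomy for the synthetic cohort
#'
#' Builds a root -> phylum -> genus -> species tree with
#' `n_phyla * genera_per_phylum` genera and `species_per_genus` leaves per
#' genus (the defaults mirror the scale of an oral microbiome profile:
#' 35 genera across 7 phyla).
#'
#' @param config a [sim_config()].
#' @return a [taxonomy_tree()].
#' @export
make_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list(data.frame(taxon_id = "root", parent_id = "ROOT",
                          rank = "root", name = "root",
                          stringsAsFactors = FALSE))
  for (p in seq_len(config$n_phyla)) {
    pid <- sprintf("p%02d", p)
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = pid, parent_id = "root", rank = "phylum",
      name = sprintf("Phylum_%02d", p), stringsAsFactors = FALSE)
    for (g in seq_len(config$genera_per_phylum)) {
      gid <- sprintf("%s_g%02d", pid, g)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = gid, parent_id = pid, rank = "genus",
        name = sprintf("Genus_%02d_%02d", p, g), stringsAsFactors = FALSE)
      for (s in seq_len(config$species_per_genus)) {
        sid <- sprintf("%s_s%02d", gid, s)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = sid, parent_id = gid, rank = "species",
          name = sprintf("Species_%02d_%02d_%02d", p, g, s),
          stringsAsFactors = FALSE)
      }
    }
  }
  taxonomy_tree(do.call(rbind, rows))
}

mutate_positions <- function(seq_chars, pos) {
  bases <- c("A", "C", "G", "T")
  for (i in pos) {
    seq_chars[i] <- resample(setdiff(bases, seq_chars[i]), 1L)
  }
  seq_chars
}

#' Generate a reference bundle: per-species 16S sequences and protein records
#'
#' One V4-like reference 16S sequence (250 nt) per species, produced by a
#' hierarchical block-mutation scheme (phylum-, genus- and species-level
#' substitutions of a shared ancestral sequence) so that 16S identity within a
#' genus exceeds identity across phyla. Each species carries
#' `proteins_per_species` protein records with identifiers of the form
#' `SEQF<4 digits>_<5 digits>`.
#'
#' @param tree a [taxonomy_tree()].
#' @param proteins_per_species proteins per species.
#' @param seed integer seed.
#' @param seq_length 16S reference length in nt.
#' @return a `reference_bundle`: list with `ref16s` (seq_id, taxon_id,
#'   sequence), `proteins` (protein_id, taxon_id, sequence) and `tree`.
#' @export
make_reference_bundle <- function(tree, proteins_per_species = 20, seed = 1L,
                                  seq_length = 250L) {
  stopifnot(inherits(tree, "taxonomy"), proteins_per_species >= 1)
  set.seed(stage_seed(seed, "reference_bundle"))
  bases <- c("A", "C", "G", "T")
  anc <- resample(bases, seq_length, replace = TRUE)
  species <- tree$nodes$taxon_id[tree$nodes$rank == "species"]

  # per-clade substitution loads: ~25% phylum, ~8% genus, ~2% species
  phy_seq <- list(); gen_seq <- list()
  ref <- vector("list", length(species))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot_rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[[i]]
    gen <- tree$parent[[sp]]
    phy <- ancestor_at_rank(tree, sp, "phylum")
    if (is.null(phy_seq[[phy]])) {
      phy_seq[[phy]] <- mutate_positions(anc, resample(seq_len(seq_length),
                                                       round(0.25 * seq_length)))
    }
    if (is.null(gen_seq[[gen]])) {
      gen_seq[[gen]] <- mutate_positions(phy_seq[[phy]],
                                         resample(seq_len(seq_length),
                                                  round(0.08 * seq_length)))
    }
    ref[[i]] <- paste(mutate_positions(gen_seq[[gen]],
                                       resample(seq_len(seq_length),
                                                round(0.02 * seq_length))),
                      collapse = "")
    prot_rows[[i]] <- data.frame(
      protein_id = sprintf("SEQF%04d_%05d", 1000L + i, seq_len(proteins_per_species)),
      taxon_id = sp,
      sequence = vapply(seq_len(proteins_per_species), function(j) {
        paste(resample(aa, 120L + (j * 7L) %% 80L, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(
    ref16s = data.frame(seq_id = paste0("ref_", species), taxon_id = species,
                        sequence = unlist(ref), stringsAsFactors = FALSE),
    proteins = do.call(rbind, prot_rows),
    tree = tree), class = "reference_bundle")
}

default_protein_effects <- function(human_proteins, bact_proteins) {
  up_h <- human_proteins[seq_len(min(12L, length(human_proteins)))]
  dn_h <- human_proteins[seq_len(min(3L, max(0L, length(human_proteins) - 12L))) + 12L]
  up_b <- bact_proteins[seq_len(min(3L, length(bact_proteins)))]
  dn_b <- bact_proteins[seq_len(min(2L, max(0L, length(bact_proteins) - 3L))) + 3L]
  data.frame(feature = c(up_h, dn_h, up_b, dn_b),
             log2fc = c(rep(2, length(up_h)), rep(-2, length(dn_h)),
                        rep(2, length(up_b)), rep(-2, length(dn_b))),
             stringsAsFactors = FALSE)
}

solve_missing_offset <- function(z, k, rate) {
  f <- function(b) mean(stats::plogis(-k * z + b)) - rate
  stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
}

#' Simulate a complete synthetic cohort
#'
#' Log2 peptide intensities are drawn per feature as
#' Normal(feature mean, `feature_sd`) with feature means spread uniformly over
#' `dynamic_range_log10 * log2(10)` units; planted log2 fold changes are added
#' to the T2D samples; missingness follows a left-censored (MNAR) logistic
#' model in the z-scored log2 intensity, with the intercept solved numerically
#' so the overall missing fraction equals `missing_rate`. Per-participant ASV
#' sequences derive from the species 16S references with per-base error, and
#' genus 16S counts follow a Dirichlet-multinomial whose proportions track the
#' simulated bacterial biomass.
#'
#' @param config a [sim_config()].
#' @param bundle a [make_reference_bundle()] result.
#' @return a `synthetic_cohort` list: `quant_report`, `peptide_log2` (latent
#'   complete matrix), `peptide_matrix` and `protein_matrix` (raw-space
#'   [quant_matrix()] with missing cells), `peptide_map`, `asv`,
#'   `s16_counts`, `traits`, `annotations`, `truth`, `tree`.
#' @export
simulate_cohort <- function(config, bundle) {
  stopifnot(inherits(config, "sim_config"), inherits(bundle, "reference_bundle"))
  tree <- bundle$tree
  n <- config$n_per_group
  samples <- c(sprintf("HC%02d", seq_len(n)), sprintf("T2D%02d", seq_len(n)))
  group <- rep(c("HC", "T2D"), each = n)

  ## ---- peptide -> protein mapping -------------------------------------
  set.seed(stage_seed(config$seed, "mapping"))
  n_h <- config$n_human_peptides
  n_b <- config$n_bacterial_peptides
  n_h_prot <- ceiling(n_h / 3)
  human_prot <- sprintf("HUM_%04d", seq_len(n_h_prot))
  h_map <- data.frame(peptide = sprintf("HPEP_%05d", seq_len(n_h)),
                      protein_ids = human_prot[((seq_len(n_h) - 1L) %% n_h_prot) + 1L],
                      proteotypic = 1L, origin = "human",
                      stringsAsFactors = FALSE)

  species <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
  prot_by_taxon <- split(bundle$proteins$protein_id, bundle$proteins$taxon_id)
  b_pep <- sprintf("BPEP_%05d", seq_len(n_b))
  b_prot_ids <- character(n_b)
  kind <- sample(c("species", "genus", "phylum"), n_b, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  for (i in seq_len(n_b)) {
    if (kind[[i]] == "species") {
      sp <- resample(species, 1L)
      b_prot_ids[[i]] <- paste(resample(prot_by_taxon[[sp]],
                                        resample(1:2, 1L)), collapse = ";")
    } else if (kind[[i]] == "genus") {
      gen <- resample(unique(tree$parent[species]), 1L)
      sps <- species[tree$parent[species] == gen]
      picks <- resample(sps, min(2L, length(sps)))
      b_prot_ids[[i]] <- paste(vapply(picks, function(s)
        resample(prot_by_taxon[[s]], 1L), character(1)), collapse = ";")
    } else {
      phys <- vapply(species, function(s) ancestor_at_rank(tree, s, "phylum"),
                     character(1))
      two <- resample(unique(phys), min(2L, length(unique(phys))))
      picks <- vapply(two, function(p) resample(species[phys == p], 1L), character(1))
      b_prot_ids[[i]] <- paste(vapply(picks, function(s)
        resample(prot_by_taxon[[s]], 1L), character(1)), collapse = ";")
    }
  }
  b_map <- data.frame(peptide = b_pep, protein_ids = b_prot_ids,
                      proteotypic = ifelse(lengths(strsplit(b_prot_ids, ";")) == 1L, 1L, 0L),
                      origin = "bacterial", stringsAsFactors = FALSE)
  pep_map <- rbind(h_map, b_map)

  # genus of each bacterial peptide via LCA (NA when the LCA sits above genus)
  prot_tax <- stats::setNames(bundle$proteins$taxon_id, bundle$proteins$protein_id)
  pep_genus <- rep(NA_character_, nrow(pep_map))
  for (i in which(pep_map$origin == "bacterial")) {
    taxa <- unique(prot_tax[strsplit(pep_map$protein_ids[[i]], ";")[[1]]])
    pep_genus[[i]] <- ancestor_at_rank(tree, lca(tree, taxa), "genus")
  }

  ## ---- planted effects -------------------------------------------------
  bact_proteotypic_prot <- unique(unlist(strsplit(
    b_map$protein_ids[b_map$proteotypic == 1L], ";")))
  prot_eff <- config$planted_protein_effects %||%
    default_protein_effects(human_prot, bact_proteotypic_prot)
  all_prot <- c(human_prot, bundle$proteins$protein_id)
  unknown <- setdiff(prot_eff$feature, all_prot)
  if (length(unknown)) stop("planted effect on unknown feature(s): ",
                            paste(unknown, collapse = ", "))
  genera <- tree$nodes$taxon_id[tree$nodes$rank == "genus"]
  gen_eff <- config$planted_genus_effects %||% {
    k <- min(2L, length(genera))
    data.frame(genus = genera[seq_len(k)],
               log2fc = c(1.5, -1.5)[seq_len(k)], stringsAsFactors = FALSE)
  }
  unknown <- setdiff(gen_eff$genus, genera)
  if (length(unknown)) stop("planted effect on unknown genus/genera: ",
                            paste(unknown, collapse = ", "))

  ## ---- latent log2 intensities ----------------------------------------
  set.seed(stage_seed(config$seed, "intensity"))
  n_pep <- nrow(pep_map)
  span <- config$dynamic_range_log10 * log2(10)
  mu <- stats::runif(n_pep, 10, 10 + span)
  x <- matrix(stats::rnorm(n_pep * length(samples), mean = mu,
                           sd = config$feature_sd),
              nrow = n_pep, dimnames = list(pep_map$peptide, samples))
  is_t2d <- group == "T2D"
  # protein effects propagate to the protein's peptides
  for (j in seq_len(nrow(prot_eff))) {
    hit <- vapply(strsplit(pep_map$protein_ids, ";"),
                  function(p) prot_eff$feature[[j]] %in% p, logical(1))
    x[hit, is_t2d] <- x[hit, is_t2d] + prot_eff$log2fc[[j]]
  }
  # genus effects on genus-specific peptides
  for (j in seq_len(nrow(gen_eff))) {
    hit <- !is.na(pep_genus) & pep_genus == gen_eff$genus[[j]]
    x[hit, is_t2d] <- x[hit, is_t2d] + gen_eff$log2fc[[j]]
  }

  ## ---- left-censored missingness --------------------------------------
  set.seed(stage_seed(config$seed, "missingness"))
  x_obs <- x
  if (config$missing_rate > 0) {
    z <- (x - mean(x)) / stats::sd(x)
    k <- config$censoring_strength
    if (k == 0) {
      p_miss <- matrix(config$missing_rate, nrow(x), ncol(x))
    } else {
      b <- solve_missing_offset(as.vector(z), k, config$missing_rate)
      p_miss <- stats::plogis(-k * z + b)
    }
    x_obs[matrix(stats::runif(length(x)), nrow(x)) < p_miss] <- NA
  }

  ## ---- quantification report & matrices --------------------------------
  present <- which(!is.na(x_obs), arr.ind = TRUE)
  quant_report <- data.frame(
    peptide = rownames(x_obs)[present[, 1]],
    protein_ids = pep_map$protein_ids[present[, 1]],
    proteotypic = pep_map$proteotypic[present[, 1]],
    sample_id = colnames(x_obs)[present[, 2]],
    intensity = 2^x_obs[present],
    stringsAsFactors = FALSE)
  quant_report <- quant_report[order(match(quant_report$peptide, pep_map$peptide),
                                     match(quant_report$sample_id, samples)), ]
  rownames(quant_report) <- NULL
  mats <- read_quant_report(quant_report)

  ## ---- per-participant ASV FASTA ---------------------------------------
  set.seed(stage_seed(config$seed, "asv"))
  asv <- lapply(samples, function(s) {
    keep <- species[stats::runif(length(species)) < 0.85]
    if (!length(keep)) keep <- resample(species, 1L)
    seqs <- vapply(keep, function(sp) {
      chars <- strsplit(bundle$ref16s$sequence[bundle$ref16s$taxon_id == sp], "")[[1]]
      err <- which(stats::runif(length(chars)) < 0.005)
      if (length(err)) chars <- mutate_positions(chars, err)
      paste(chars, collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0(s, "_asv_", seq_along(keep), "_", keep))
  })
  names(asv) <- samples

  ## ---- genus-level 16S counts (Dirichlet-multinomial) -------------------
  set.seed(stage_seed(config$seed, "s16"))
  raw_pep <- mats$peptides$values
  genus_biomass <- matrix(0, length(genera), length(samples),
                          dimnames = list(genera, samples))
  for (g in genera) {
    hit <- !is.na(pep_genus) & pep_genus == g
    present <- intersect(pep_map$peptide[hit], rownames(raw_pep))
    if (length(present)) {
      cs <- colSums(raw_pep[present, , drop = FALSE], na.rm = TRUE)
      genus_biomass[g, names(cs)] <- cs
    }
  }
  conc <- 50
  s16_counts <- vapply(seq_along(samples), function(j) {
    prop <- genus_biomass[, j] + max(genus_biomass[, j]) * 1e-4 + 1e-12
    prop <- prop / sum(prop)
    a <- stats::rgamma(length(prop), shape = conc * prop, rate = 1)
    a <- a / sum(a)
    as.vector(stats::rmultinom(1, size = 30000L, prob = a))
  }, numeric(length(genera)))
  s16_counts <- matrix(s16_counts, nrow = length(genera))
  dimnames(s16_counts) <- list(genera, samples)

  ## ---- clinical traits --------------------------------------------------
  set.seed(stage_seed(config$seed, "traits"))
  traits <- data.frame(
    sample_id = samples, group = group,
    age = round(stats::rnorm(2 * n, 66.2, 4.5), 1),
    sex = {
      n_male <- max(1L, round(0.6 * n))
      pool_sex <- rep(c("male", "female"), c(n_male, n - n_male))
      c(resample(pool_sex, n), resample(pool_sex, n))
    },
    smoking = c(sample(c("current", "ex", "never"), n, TRUE, prob = c(2, 9, 4) / 15),
                sample(c("current", "ex", "never"), n, TRUE, prob = c(4, 7, 4) / 15)),
    bmi = round(c(stats::rnorm(n, 28.24, 2.58), stats::rnorm(n, 28.68, 3.18)), 1),
    glucose_t0 = round(c(stats::rnorm(n, 5.68, 0.23), stats::rnorm(n, 6.94, 0.81)), 2),
    hba1c = round(c(stats::rnorm(n, 5.62, 0.29), stats::rnorm(n, 5.99, 0.45)), 2),
    stringsAsFactors = FALSE)
  base_traits <- list(insulin_t30 = c(log(300), 0.35),
                      waist = c(log(100), 0.10),
                      fat_pct = c(log(30), 0.18))
  ln_traits <- lapply(base_traits, function(bt)
    stats::rnorm(2 * n, bt[[1]], bt[[2]]))
  bact_pep_planted <- if (nrow(gen_eff)) {
    pep_map$peptide[pep_map$origin == "bacterial" & !is.na(pep_genus) &
                      pep_genus == gen_eff$genus[[1]]]
  } else character(0)
  tr_eff <- config$trait_effects %||% {
    picks <- bact_pep_planted[seq_len(min(2L, length(bact_pep_planted)))]
    if (length(picks)) data.frame(peptide = picks, trait = "insulin_t30",
                                  slope = -0.5, stringsAsFactors = FALSE)
    else data.frame(peptide = character(), trait = character(),
                    slope = numeric(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(tr_eff$peptide, pep_map$peptide)
  if (length(unknown)) stop("trait effect on unknown peptide(s): ",
                            paste(unknown, collapse = ", "))
  for (j in seq_len(nrow(tr_eff))) {
    xv <- x[tr_eff$peptide[[j]], ]
    ln_traits[[tr_eff$trait[[j]]]] <- ln_traits[[tr_eff$trait[[j]]]] +
      tr_eff$slope[[j]] * (xv - mean(xv))
  }
  for (tn in names(ln_traits)) traits[[tn]] <- round(exp(ln_traits[[tn]]), 2)

  ## ---- annotations ------------------------------------------------------
  set.seed(stage_seed(config$seed, "annotations"))
  pool <- sprintf("TERM_%02d", seq_len(25))
  ann_feature <- character(); ann_term <- character()
  add_ann <- function(ids, terms) {
    ann_feature <<- c(ann_feature, rep(ids, lengths(terms)))
    ann_term <<- c(ann_term, unlist(terms))
  }
  add_ann(human_prot, lapply(human_prot, function(p) resample(pool, resample(1:3, 1L))))
  add_ann(bact_proteotypic_prot,
          lapply(bact_proteotypic_prot, function(p) resample(pool, resample(1:2, 1L))))
  # planted proteins share marker terms so enrichment has signal to find
  up_h <- prot_eff$feature[prot_eff$log2fc > 0 & grepl("^HUM_", prot_eff$feature)]
  up_b <- prot_eff$feature[prot_eff$log2fc > 0 & !grepl("^HUM_", prot_eff$feature)]
  add_ann(up_h, lapply(up_h, function(p) "TERM_IMMUNE"))
  add_ann(up_b, lapply(up_b, function(p) "TERM_GLYCOLYSIS"))
  b_ids <- pep_map$peptide[pep_map$origin == "bacterial"]
  add_ann(b_ids, lapply(b_ids, function(p) resample(pool, resample(1:2, 1L))))
  planted_pep <- pep_map$peptide[!is.na(pep_genus) & pep_genus %in%
                                   gen_eff$genus[gen_eff$log2fc != 0]]
  add_ann(planted_pep, lapply(planted_pep, function(p) "TERM_GLYCOLYSIS"))
  annotations <- unique(data.frame(feature_id = ann_feature, term = ann_term,
                                   stringsAsFactors = FALSE))
  rownames(annotations) <- NULL

  pep_map$genus <- pep_genus
  structure(list(
    quant_report = quant_report,
    peptide_log2 = x,
    peptide_matrix = mats$peptides,
    protein_matrix = mats$proteins,
    peptide_map = pep_map,
    asv = asv,
    s16_counts = s16_counts,
    traits = traits,
    annotations = annotations,
    truth = list(protein_effects = prot_eff, genus_effects = gen_eff,
                 trait_effects = tr_eff),
    tree = tree), class = "synthetic_cohort")
}

write_fasta <- function(seqs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Write all synthetic cohort inputs to disk
#'
#' Emits the external file formats the pipeline consumes: per-participant ASV
#' FASTA, reference 16S FASTA, taxonomy TSV, protein map TSV, reference
#' protein FASTA, long-format quant report TSV, genus count TSV, traits TSV,
#' annotations TSV and a truth JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param bundle the [make_reference_bundle()] it was simulated from.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$asv)) {
    write_fasta(cohort$asv[[s]], file.path(dir, "asv", paste0(s, ".fasta")))
  }
  write_fasta(stats::setNames(bundle$ref16s$sequence, bundle$ref16s$seq_id),
              file.path(dir, "reference_16s.fasta"))
  write_fasta(stats::setNames(bundle$proteins$sequence, bundle$proteins$protein_id),
              file.path(dir, "reference_proteins.fasta"))
  write_taxonomy(bundle$tree, file.path(dir, "taxonomy.tsv"))
  write_tsv(bundle$ref16s[, c("seq_id", "taxon_id")],
            file.path(dir, "reference_16s_map.tsv"))
  write_tsv(bundle$proteins[, c("protein_id", "taxon_id")],
            file.path(dir, "protein_map.tsv"))
  write_tsv(cohort$quant_report, file.path(dir, "quant_report.tsv"))
  write_matrix_tsv(cohort$s16_counts, file.path(dir, "s16_counts.tsv"),
                   id_col = "genus")
  write_tsv(cohort$traits, file.path(dir, "traits.tsv"))
  write_tsv(cohort$annotations, file.path(dir, "annotations.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reconstruct a reference bundle from files written by [write_cohort()]
#'
#' @param dir the directory `write_cohort()` wrote to.
#' @return a `reference_bundle`.
#' @export
read_reference_bundle <- function(dir) {
  ref_seqs <- Biostrings::readDNAStringSet(file.path(dir, "reference_16s.fasta"))
  ref_map <- read_tsv_strict(file.path(dir, "reference_16s_map.tsv"),
                             c("seq_id", "taxon_id"))
  prot_seqs <- Biostrings::readAAStringSet(file.path(dir, "reference_proteins.fasta"))
  prot_map <- read_protein_map(file.path(dir, "protein_map.tsv"))
  structure(list(
    ref16s = data.frame(seq_id = ref_map$seq_id,
                        taxon_id = ref_map$taxon_id,
                        sequence = as.character(ref_seqs[ref_map$seq_id]),
                        stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = prot_map$protein_id,
                          taxon_id = prot_map$taxon_id,
                          sequence = as.character(prot_seqs[prot_map$protein_id]),
                          stringsAsFactors = FALSE),
    tree = read_taxonomy(file.path(dir, "taxonomy.tsv"))),
    class = "reference_bundle")
}
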