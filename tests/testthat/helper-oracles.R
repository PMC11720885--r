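# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (quadratic DP, exhaustive
# enumeration, full lineage intersection) and never call the implementation
# they check.

# Smith-Waterman local alignment with affine gaps (Gotoh), gap of length L
# costing gap_open + L * gap_extend; N mismatches everything including N.
oracle_sw <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                      gap_extend = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
    s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Benjamini-Hochberg step-up by its definition: q_(i) = min_{j>=i} m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

# LCA as the deepest node in the intersection of full lineages
oracle_lca <- function(tree, taxa) {
  lins <- lapply(taxa, function(t) lineage(tree, t))
  common <- Reduce(intersect, lins)
  common[which.max(tree$depth[common])]
}

# two-sided Fisher exact p by enumerating all tables with fixed margins and
# summing point probabilities <= that of the observed table
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  point <- function(x) stats::dhyper(x, m, n, k)
  p_obs <- point(a)
  xs <- max(0, k - n):min(k, m)
  sum(point(xs)[point(xs) <= p_obs * (1 + 1e-7)])
}

# naive average-linkage agglomeration returning merge heights
oracle_average_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# OLS coefficients via the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# small handmade taxonomy: 2 phyla; phylum A has genera g1 (2 species),
# g2 (1 species); phylum B has genus g3 (2 species)
tiny_tree <- function() {
  taxonomy_tree(data.frame(
    taxon_id = c("root", "pA", "pB", "g1", "g2", "g3",
                 "s1a", "s1b", "s2a", "s3a", "s3b"),
    parent_id = c("ROOT", "root", "root", "pA", "pA", "pB",
                  "g1", "g1", "g2", "g3", "g3"),
    rank = c("root", "phylum", "phylum", "genus", "genus", "genus",
             rep("species", 5)),
    name = c("root", "A", "B", "G1", "G2", "G3",
             "S1a", "S1b", "S2a", "S3a", "S3b"),
    stringsAsFactors = FALSE))
}

tiny_config <- function(seed = 11, ...) {
  sim_config(n_per_group = 5, n_human_peptides = 30, n_bacterial_peptides = 30,
             n_phyla = 2, genera_per_phylum = 2, species_per_genus = 2,
             proteins_per_species = 4, seed = seed, ...)
}

# quant matrix from a plain matrix with default dimnames
qm <- function(values, space = "log2") {
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  quant_matrix(values, space)
}

two_group_design <- function(n_per_group, prefix = c("HC", "T2D")) {
  data.frame(sample_id = c(sprintf("%s%02d", prefix[1], seq_len(n_per_group)),
                           sprintf("%s%02d", prefix[2], seq_len(n_per_group))),
             group = rep(prefix, each = n_per_group),
             stringsAsFactors = FALSE)
}
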