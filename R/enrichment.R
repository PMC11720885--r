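#' Rank-based annotation enrichment, clustering and Fisher tests
#'
#' 1D enrichment scores each annotation term by where its members sit in the
#' ranking of a per-feature value (e.g. log2 fold change): a two-sided
#' Mann-Whitney comparison of members vs non-members, reported with the
#' rank-biserial score s = 2 * U_in / (n_in * n_out) - 1, bounded in [-1, 1]
#' (+1: members occupy all top ranks). 2D enrichment scores each term in two
#' value dimensions jointly (e.g. per-group mean intensities). Hierarchical
#' clustering of z-scored features and per-cluster Fisher exact enrichment
#' complete the functional analysis.
#'
#' @name enrichment
NULL

# rank-biserial score, tie-corrected z and MWU p for members vs the rest
mwu_term <- function(values, member) {
  n1 <- sum(member); n2 <- sum(!member)
  r <- rank(values)                      # average ranks for ties
  u_in <- sum(r[member]) - n1 * (n1 + 1) / 2
  s <- 2 * u_in / (n1 * n2) - 1
  n <- n1 + n2
  ties <- table(values)
  var_u <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (var_u > 0) (u_in - n1 * n2 / 2) / sqrt(var_u) else 0
  p <- suppressWarnings(
    stats::wilcox.test(values[member], values[!member])$p.value)
  list(s = s, z = z, p = p, u = u_in)
}

prepare_terms <- function(features, annotations, min_size) {
  req <- c("feature_id", "term")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) stop("annotations lack column(s): ", paste(miss, collapse = ", "))
  ann <- annotations[annotations$feature_id %in% features, ]
  members <- split(unique(ann)$feature_id, unique(ann)$term)
  keep <- lengths(members) >= min_size
  full <- lengths(members) == length(features)
  if (any(full)) {
    warning("term(s) covering all features skipped (no out-group): ",
            paste(names(members)[full], collapse = ", "))
  }
  members[keep & !full]
}

#' 1D annotation enrichment
#'
#' @param values named numeric vector (feature -> value, e.g. log2fc); every
#'   annotated feature must have a value.
#' @param annotations data.frame (`feature_id`, `term`).
#' @param min_size smallest term size tested.
#' @param alpha BH FDR threshold reported alongside.
#' @return data.frame: term, n_members, s, p, q, significant.
#' @export
enrich_1d <- function(values, annotations, min_size = 2, alpha = 0.02) {
  stopifnot(!is.null(names(values)))
  members <- prepare_terms(names(values), annotations, min_size)
  if (!length(members)) {
    return(data.frame(term = character(), n_members = integer(), s = numeric(),
                      p = numeric(), q = numeric(), significant = logical()))
  }
  rows <- lapply(names(members), function(tm) {
    memb <- names(values) %in% members[[tm]]
    st <- mwu_term(values, memb)
    data.frame(term = tm, n_members = sum(memb), s = st$s, p = st$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}

#' 2D annotation enrichment
#'
#' Scores each term in two value dimensions over the same features (e.g. mean
#' log2 peptide intensity in each patient group); s_x and s_y are the per-
#' dimension rank-biserial scores and the joint p-value refers
#' z_x^2 + z_y^2 to a chi-square distribution with 2 df (z from the tie-
#' corrected normal approximation of the Mann-Whitney statistic).
#'
#' @param values_x,values_y named numeric vectors over the same features.
#' @inheritParams enrich_1d
#' @return data.frame: term, n_members, s_x, s_y, p, q, significant.
#' @export
enrich_2d <- function(values_x, values_y, annotations, min_size = 2,
                      alpha = 0.02) {
  stopifnot(!is.null(names(values_x)), !is.null(names(values_y)))
  if (!setequal(names(values_x), names(values_y))) {
    stop("values_x and values_y must cover the same features")
  }
  values_y <- values_y[names(values_x)]
  members <- prepare_terms(names(values_x), annotations, min_size)
  if (!length(members)) {
    return(data.frame(term = character(), n_members = integer(),
                      s_x = numeric(), s_y = numeric(), p = numeric(),
                      q = numeric(), significant = logical()))
  }
  rows <- lapply(names(members), function(tm) {
    memb <- names(values_x) %in% members[[tm]]
    sx <- mwu_term(values_x, memb)
    sy <- mwu_term(values_y, memb)
    data.frame(term = tm, n_members = sum(memb), s_x = sx$s, s_y = sy$s,
               p = stats::pchisq(sx$z^2 + sy$z^2, df = 2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}

#' Hierarchical clustering of features
#'
#' Rows are z-scored first (constant rows map to 0), then agglomeratively
#' clustered on the chosen distance metric and linkage. Cutting at `k`
#' clusters (or height `h`) yields the labels passed to [fisher_cluster()].
#'
#' @param m numeric matrix (features x samples) or log2 [quant_matrix()].
#' @param metric distance metric for [stats::dist()].
#' @param linkage linkage for [stats::hclust()] (`"average"`, `"complete"`,
#'   `"ward.D2"`, ...).
#' @param k number of clusters (or give `h`).
#' @param h cut height.
#' @param zscore z-score rows first.
#' @return list: `labels` (named integer), `tree` (hclust), `heights`.
#' @export
hcluster <- function(m, metric = "euclidean", linkage = "average",
                     k = NULL, h = NULL, zscore = TRUE) {
  v <- if (inherits(m, "quant_matrix")) m$values else as.matrix(m)
  if (nrow(v) < 2) stop("need >= 2 features to cluster")
  if (!is.null(k) && k > nrow(v)) stop("k exceeds the number of features")
  if (zscore) {
    v <- t(apply(v, 1, function(r) {
      s <- stats::sd(r)
      if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
  }
  tree <- stats::hclust(stats::dist(v, method = metric), method = linkage)
  labels <- if (!is.null(k) || !is.null(h)) {
    stats::cutree(tree, k = k, h = h)
  } else {
    stats::cutree(tree, k = min(2L, nrow(v)))
  }
  list(labels = labels, tree = tree, heights = tree$height)
}

#' Per-cluster Fisher exact enrichment
#'
#' For every (cluster, term) pair builds the 2x2 table (in cluster & in term,
#' in cluster & not, out & in term, out & not) and reports the two-sided
#' Fisher exact p (point-probability method) with BH adjustment within each
#' cluster.
#'
#' @param labels named cluster labels over features (from [hcluster()]).
#' @param annotations data.frame (`feature_id`, `term`).
#' @param alpha BH FDR threshold.
#' @param min_size smallest in-cluster term count tested.
#' @return data.frame: cluster_id, term, a, b, c, d, odds_ratio, p, q,
#'   significant.
#' @export
fisher_cluster <- function(labels, annotations, alpha = 0.02, min_size = 1) {
  stopifnot(!is.null(names(labels)))
  feats <- names(labels)
  ann <- unique(annotations[annotations$feature_id %in% feats,
                            c("feature_id", "term")])
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- feats[labels == cl]
    if (!length(in_cl)) next
    rows <- list()
    for (tm in unique(ann$term)) {
      in_tm <- ann$feature_id[ann$term == tm]
      a <- sum(in_cl %in% in_tm)
      if (a < min_size) next
      b <- length(in_cl) - a
      c_ <- sum(!(in_tm %in% in_cl) & in_tm %in% feats)
      d <- length(feats) - a - b - c_
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl, term = tm, a = a, b = b, c = c_, d = d,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df$q <- bh_adjust(df$p)
    df$significant <- df$q < alpha
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) {
    return(data.frame(cluster_id = integer(), term = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      significant = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
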