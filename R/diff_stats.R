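#' Differential-abundance statistics and PCA
#'
#' Two-sample t statistics (pooled by default, Welch available), the same test
#' from printed summary statistics, Benjamini-Hochberg adjustment, a per-
#' feature differential table, and PCA with per-feature contribution
#' percentages for identifying separation drivers.
#'
#' @name diff_stats
NULL

t_core <- function(m1, s1, n1, m2, s2, n2, variant) {
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  d <- m1 - m2
  if (se == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1))
    warning("zero variance with unequal means; p -> 0 limit")
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  t <- d / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample t test
#'
#' Pooled-variance Student form by default: t = (mean(x) - mean(y)) /
#' (s_p * sqrt(1/n1 + 1/n2)) on n1 + n2 - 2 degrees of freedom, two-sided;
#' `variant = "welch"` uses the Welch-Satterthwaite form. Zero variance in
#' both groups with equal means yields t = 0, p = 1.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  t_core(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y),
         variant)
}

#' Two-sample t test from summary statistics
#'
#' Identical to [two_sample_t()] applied to data with exactly these summaries;
#' used to recompute published group comparisons that report only means and
#' SDs.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`sd >= 0`, `n >= 2`).
#' @inheritParams two_sample_t
#' @return list with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd1 < 0 || sd2 < 0) stop("sds must be >= 0")
  if (n1 < 2 || n2 < 2) stop("ns must be >= 2")
  t_core(mean1, sd1, n1, mean2, sd2, n2, variant)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of m * p_(j) / j, clipped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

group_split <- function(m, design, groups) {
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(m), design$sample_id)
  if (length(absent)) stop("design does not cover sample(s): ",
                           paste(absent, collapse = ", "))
  g <- design$group[match(colnames(m), design$sample_id)]
  lapply(groups, function(gr) which(g == gr))
}

#' Per-feature differential table
#'
#' Pooled two-sample t test per feature of an imputed log2 matrix, BH
#' adjustment across all features, direction called from the sign of the
#' log2 fold change (group2 mean minus group1 mean) at q < alpha.
#'
#' @param m a complete log2 [quant_matrix()].
#' @param design data.frame with `sample_id`, `group`.
#' @param groups length-2 character: reference group first (fold changes are
#'   `groups[2]` minus `groups[1]`).
#' @param alpha FDR threshold for the `direction` call.
#' @param origin optional named character vector (feature -> origin class,
#'   e.g. human/bacterial), carried into the output.
#' @param variant t-test variant.
#' @return data.frame: feature_id, origin, log2fc, t, p, q, direction.
#' @export
differential_table <- function(m, design, groups = c("HC", "T2D"),
                               alpha = 0.05, origin = NULL,
                               variant = "pooled") {
  stopifnot(inherits(m, "quant_matrix"))
  if (anyNA(m$values)) stop("differential_table expects an imputed (complete) matrix")
  idx <- group_split(m$values, design, groups)
  if (any(lengths(idx) < 2)) stop("each group needs >= 2 samples")
  res <- t(apply(m$values, 1, function(v) {
    ts <- two_sample_t(v[idx[[2]]], v[idx[[1]]], variant = variant)
    c(log2fc = mean(v[idx[[2]]]) - mean(v[idx[[1]]]), t = ts$t, p = ts$p)
  }))
  q <- bh_adjust(res[, "p"])
  out <- data.frame(
    feature_id = rownames(m$values),
    origin = if (is.null(origin)) NA_character_ else unname(origin[rownames(m$values)]),
    log2fc = res[, "log2fc"], t = res[, "t"], p = res[, "p"], q = q,
    direction = ifelse(q < alpha, ifelse(res[, "log2fc"] > 0, "up", "down"), "ns"),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' PCA with variance-explained and feature contributions
#'
#' SVD-based PCA of the samples x features matrix (features centred by
#' default, unscaled, the usual convention for log2 proteomics intensities).
#' Per component: var_explained_k = 100 * lambda_k / sum(lambda);
#' contribution of feature j to component k = 100 * loading_jk^2 /
#' sum_j loading_jk^2, so contributions per PC sum to 100. The top
#' contributors of a chosen PC are its separation drivers.
#'
#' @param m a complete log2 [quant_matrix()].
#' @param center,scale. passed to the decomposition.
#' @return list: `scores` (samples x PC), `loadings` (features x PC),
#'   `var_explained` (%), `contributions` (features x PC, %).
#' @export
pca_quant <- function(m, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(m, "quant_matrix"))
  if (anyNA(m$values)) stop("pca_quant expects an imputed (complete) matrix")
  x <- t(m$values)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("constant matrix: PCA undefined")
  if (scale. && any(sds == 0)) stop("cannot scale zero-variance features")
  fit <- stats::prcomp(x, center = center, scale. = scale.)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  contrib <- 100 * sweep(fit$rotation^2, 2, colSums(fit$rotation^2), "/")
  list(scores = fit$x, loadings = fit$rotation,
       var_explained = ve, contributions = contrib)
}

#' Top driver features of a principal component
#'
#' @param pca a [pca_quant()] result.
#' @param pc component index.
#' @param n number of drivers.
#' @return data.frame: feature_id, contribution (%).
#' @export
pca_drivers <- function(pca, pc = 1L, n = 25L) {
  cc <- pca$contributions[, pc]
  ord <- order(cc, decreasing = TRUE)[seq_len(min(n, length(cc)))]
  data.frame(feature_id = rownames(pca$contributions)[ord],
             contribution = unname(cc[ord]), stringsAsFactors = FALSE)
}
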