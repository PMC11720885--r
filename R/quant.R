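#' Quantification matrices and preprocessing
#'
#' A `quant_matrix` is a features x samples intensity matrix with missing
#' cells encoded as `NA` and an explicit `space` flag (`"raw"` or `"log2"`).
#' Preprocessing follows the standard label-free workflow: log2 transform,
#' valid-value filtering (features present in at least 70% of samples by
#' default), then imputation — downshifted-normal for left-censored protein
#' data, iterative random-forest for peptide data.
#'
#' @name quant_preprocess
NULL

#' Construct a quantification matrix
#'
#' @param values numeric matrix (features x samples) with `NA` for missing;
#'   must have row and column names.
#' @param space `"raw"` or `"log2"`.
#' @return a `quant_matrix`.
#' @export
quant_matrix <- function(values, space = c("raw", "log2")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry feature (row) and sample (column) names")
  }
  storage.mode(values) <- "double"
  if (space == "raw" && any(values <= 0, na.rm = TRUE)) {
    stop("raw-space intensities must be positive")
  }
  structure(list(values = values, space = space), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s]: %d features x %d samples, %.1f%% missing\n",
              x$space, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Read a long-format quantification report
#'
#' Expects columns `peptide`, `protein_ids` (semicolon-joined), `proteotypic`
#' (0/1), `sample_id`, `intensity`. Protein intensities are rolled up from
#' proteotypic peptides only (non-proteotypic peptides stay in the peptide
#' matrix but never contribute to protein quantification); the rollup rule is
#' configurable.
#'
#' @param x path to a TSV or an equivalent data.frame.
#' @param rollup how proteotypic peptide intensities form a protein value.
#' @return list with `peptides` and `proteins` raw-space [quant_matrix()]
#'   objects, plus `peptide_info` (peptide, protein_ids, proteotypic).
#' @export
read_quant_report <- function(x, rollup = c("sum", "median", "top3")) {
  rollup <- match.arg(rollup)
  req <- c("peptide", "protein_ids", "proteotypic", "sample_id", "intensity")
  df <- if (is.character(x)) read_tsv_strict(x, req) else as.data.frame(x)
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("quant report lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$intensity)) stop("intensity column must be numeric")
  if (any(is.na(df$intensity)) || any(df$intensity <= 0)) {
    stop("quant report intensities must be positive and non-missing; ",
         "absent measurements are absent rows")
  }
  df <- df[df$protein_ids != "" & !is.na(df$protein_ids), ]

  peptides <- unique(df$peptide)
  samples <- unique(df$sample_id)
  pmat <- matrix(NA_real_, length(peptides), length(samples),
                 dimnames = list(peptides, samples))
  # duplicate (peptide, sample) rows sum, as fragmented reports do
  agg <- stats::aggregate(intensity ~ peptide + sample_id, df, sum)
  pmat[cbind(match(agg$peptide, peptides), match(agg$sample_id, samples))] <-
    agg$intensity

  info <- unique(df[, c("peptide", "protein_ids", "proteotypic")])
  if (anyDuplicated(info$peptide)) {
    stop("peptide(s) with inconsistent protein_ids/proteotypic annotation")
  }
  pt <- info[info$proteotypic == 1L, ]
  if (any(grepl(";", pt$protein_ids))) {
    stop("proteotypic peptides must map to a single protein")
  }
  prot_ids <- unique(pt$protein_ids)
  rmat <- matrix(NA_real_, length(prot_ids), length(samples),
                 dimnames = list(prot_ids, samples))
  roll_fun <- switch(rollup,
                     sum = function(v) sum(v),
                     median = function(v) stats::median(v),
                     top3 = function(v) mean(sort(v, decreasing = TRUE)[seq_len(min(3, length(v)))]))
  for (pid in prot_ids) {
    rows <- pmat[pt$peptide[pt$protein_ids == pid], , drop = FALSE]
    rmat[pid, ] <- apply(rows, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else roll_fun(v)
    })
  }
  list(peptides = quant_matrix(pmat, "raw"),
       proteins = quant_matrix(rmat, "raw"),
       peptide_info = info)
}

#' Log2 transform / back-transform a quantification matrix
#'
#' Exact inverse pair on present values; missing cells stay missing; the
#' `space` flag is updated and transforming a matrix already in the target
#' space is an error.
#'
#' @param m a [quant_matrix()].
#' @return a [quant_matrix()] in the other space.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$space != "raw") stop("matrix is already in log2 space")
  quant_matrix(log2(m$values), "log2")
}

#' @rdname log2_transform
#' @export
back_transform <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$space != "log2") stop("matrix is not in log2 space")
  quant_matrix(2^m$values, "raw")
}

#' Filter features on valid-value fraction
#'
#' Keeps a feature iff its present fraction across all samples is at least
#' `min_frac` (default 0.7: features with less than 70% present values are
#' omitted, the boundary itself is kept).
#'
#' @param m a [quant_matrix()].
#' @param min_frac minimum present fraction in (0, 1].
#' @return a filtered [quant_matrix()].
#' @export
filter_valid <- function(m, min_frac = 0.7) {
  stopifnot(inherits(m, "quant_matrix"))
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  keep <- rowMeans(!is.na(m$values)) >= min_frac
  quant_matrix(m$values[keep, , drop = FALSE], m$space)
}

#' Downshift-imputation parameters
#'
#' Defaults reproduce the left-censored convention: imputed values are drawn
#' from a normal distribution with mean downshifted by 1.8 feature-SDs and SD
#' scaled to 0.3 feature-SDs, relative to the observed distribution of the
#' corresponding feature across all samples.
#'
#' @param shift downshift in feature-SD units (>= 0).
#' @param width imputed-SD scale in feature-SD units (> 0).
#' @param seed integer seed.
#' @return an `impute_params` list.
#' @export
impute_params <- function(shift = 1.8, width = 0.3, seed = 1L) {
  if (width <= 0) stop("width must be > 0")
  if (shift < 0) stop("shift must be >= 0")
  structure(list(shift = shift, width = width, seed = as.integer(seed)),
            class = "impute_params")
}

#' Impute missing cells from a downshifted normal distribution
#'
#' For feature f with observed mean mu_f and SD sigma_f, missing cells are
#' drawn i.i.d. from Normal(mu_f - shift * sigma_f, (width * sigma_f)^2).
#' Observed cells are untouched; the draw is seed-deterministic. Intended for
#' log2-space protein matrices whose missingness is left-censored.
#'
#' @param m a log2-space [quant_matrix()]; every feature needs >= 2 present
#'   values (guaranteed after [filter_valid()]).
#' @param params an [impute_params()].
#' @return a complete [quant_matrix()].
#' @export
impute_downshift <- function(m, params = impute_params()) {
  stopifnot(inherits(m, "quant_matrix"), inherits(params, "impute_params"))
  if (m$space != "log2") stop("impute_downshift expects a log2-space matrix")
  v <- m$values
  n_present <- rowSums(!is.na(v))
  if (any(n_present < 2)) {
    stop("feature(s) with < 2 present values: ",
         paste(utils::head(rownames(v)[n_present < 2]), collapse = ", "))
  }
  set.seed(params$seed)
  for (i in seq_len(nrow(v))) {
    miss <- which(is.na(v[i, ]))
    if (!length(miss)) next
    obs <- v[i, !is.na(v[i, ])]
    mu <- mean(obs); sg <- stats::sd(obs)
    if (sg == 0) {
      warning("feature ", rownames(v)[i], " has zero observed SD; imputing at its mean")
    }
    v[i, miss] <- stats::rnorm(length(miss), mu - params$shift * sg,
                               params$width * sg)
  }
  quant_matrix(v, "log2")
}

#' Iterative random-forest imputation of a peptide matrix
#'
#' Chained nonparametric imputation in the style of forest-based imputers:
#' missing cells are initialised at feature means, then each incomplete
#' feature is repeatedly re-predicted from all other features (samples as
#' observations, a random-forest regressor via \pkg{ranger}) until the
#' relative Frobenius change of the imputed cells falls below `tol` or
#' `max_iter` is reached. Observed cells are untouched; the run is
#' seed-deterministic (single-threaded forests).
#'
#' @param m a log2-space [quant_matrix()].
#' @param seed integer seed.
#' @param max_iter maximum sweeps over the features.
#' @param num_trees trees per forest.
#' @param tol relative-change convergence threshold.
#' @return a complete [quant_matrix()].
#' @export
impute_iterative <- function(m, seed = 1L, max_iter = 10L, num_trees = 100L,
                             tol = 1e-3) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$space != "log2") stop("impute_iterative expects a log2-space matrix")
  v <- t(m$values)                       # samples x features
  all_missing <- colSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("all-missing feature(s): ",
         paste(colnames(v)[all_missing], collapse = ", "),
         " (filter upstream)")
  }
  miss_idx <- which(is.na(v), arr.ind = TRUE)
  if (!nrow(miss_idx)) return(m)
  # init at feature means
  for (j in unique(miss_idx[, 2])) {
    v[is.na(v[, j]), j] <- mean(v[, j], na.rm = TRUE)
  }
  obs_mask <- !is.na(t(m$values))        # features x samples, original
  # visit features by ascending missingness
  n_miss <- table(factor(miss_idx[, 2], levels = seq_len(ncol(v))))
  order_feats <- order(as.integer(n_miss), decreasing = FALSE)
  order_feats <- order_feats[as.integer(n_miss)[order_feats] > 0]
  set.seed(seed)
  prev <- v[miss_idx]
  for (it in seq_len(max_iter)) {
    for (j in order_feats) {
      hole <- is.na(m$values[j, ])       # logical over samples (columns of m)
      df_x <- as.data.frame(v[, -j, drop = FALSE])
      names(df_x) <- paste0("f", seq_len(ncol(df_x)))
      fit <- ranger::ranger(x = df_x[!hole, , drop = FALSE],
                            y = v[!hole, j],
                            num.trees = num_trees,
                            seed = stage_seed(seed, paste0("rf", it, "_", j)),
                            num.threads = 1)
      v[hole, j] <- stats::predict(fit, df_x[hole, , drop = FALSE],
                                   num.threads = 1)$predictions
    }
    cur <- v[miss_idx]
    delta <- sqrt(sum((cur - prev)^2)) / max(sqrt(sum(cur^2)), .Machine$double.eps)
    prev <- cur
    if (delta < tol) break
  }
  quant_matrix(t(v), "log2")
}

#' Write / read a quant matrix as TSV with explicit NA
#'
#' @param m a [quant_matrix()].
#' @param path file path.
#' @param space space flag to assign on read.
#' @return the path / a [quant_matrix()].
#' @export
write_quant_matrix <- function(m, path) {
  stopifnot(inherits(m, "quant_matrix"))
  write_matrix_tsv(m$values, path)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(path, space = c("raw", "log2")) {
  quant_matrix(read_matrix_tsv(path), match.arg(space))
}
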