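#' Covariate-adjusted peptide-trait association models
#'
#' Ordinary least squares of a clinical trait (ln-transformed, then z-scaled)
#' on peptide log2 abundance, controlling for age, sex, smoking and glycemic
#' status, plus an interaction model testing whether glycemic status modifies
#' the association. FDR is controlled jointly across all peptide x trait
#' pairs; associations are significant at q < 0.05 and suggestive at
#' p < 0.05 pre-adjustment.
#'
#' @name association
NULL

prep_trait <- function(trait) {
  if (any(is.na(trait))) stop("trait contains missing values")
  if (any(trait <= 0)) stop("trait has non-positive values; cannot ln-transform")
  y <- log(trait)
  as.numeric(scale(y))
}

build_covariates <- function(covariates) {
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if ("sex" %in% names(cv) && !is.numeric(cv$sex)) {
    cv$sex <- as.integer(cv$sex == "male")
  }
  if ("smoking" %in% names(cv) && !is.numeric(cv$smoking)) {
    cv$smoking_current <- as.integer(cv$smoking == "current")
    cv$smoking_ex <- as.integer(cv$smoking == "ex")
    cv$smoking <- NULL
  }
  if ("group" %in% names(cv) && !is.numeric(cv$group)) {
    cv$group <- as.integer(cv$group == "T2D")
  }
  cv
}

# drop constant and linearly redundant covariate columns (small cohorts can
# leave an indicator empty or complementary); warns when anything is dropped
sanitize_covariates <- function(covariates) {
  cv <- build_covariates(covariates)
  keep <- vapply(cv, function(col) stats::sd(col) > 0, logical(1))
  if (any(!keep)) {
    warning("constant covariate column(s) dropped: ",
            paste(names(cv)[!keep], collapse = ", "))
    cv <- cv[, keep, drop = FALSE]
  }
  if (!ncol(cv)) return(cv)
  mm <- cbind(1, as.matrix(cv))
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    warning("collinear covariate column(s) dropped: ",
            paste(aliased, collapse = ", "))
    cv <- cv[, setdiff(names(cv), aliased), drop = FALSE]
  }
  cv
}

check_design <- function(mm) {
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
}

#' Fit a covariate-adjusted trait model for one peptide
#'
#' trait -> ln -> z-scale, then OLS of the scaled trait on
#' [1, peptide log2 abundance, covariates]; the reported effect is the
#' peptide coefficient (per log2 unit, on the scaled-ln-trait scale), with a
#' two-sided p from the t distribution on n - k df.
#'
#' @param trait positive numeric vector (one value per sample).
#' @param peptide numeric vector of log2 abundances.
#' @param covariates data.frame of covariates (columns such as `age`,
#'   `sex` ("male"/"female"), `smoking` ("current"/"ex"/"never"), `group`
#'   ("HC"/"T2D" glycemic status); factors are coded to indicators).
#' @return list: `beta`, `se`, `p`, `fit` (the `lm` object).
#' @export
fit_trait_model <- function(trait, peptide, covariates) {
  if (stats::sd(peptide) == 0) stop("peptide has zero variance")
  y <- prep_trait(trait)
  dat <- cbind(data.frame(y = y, peptide = peptide),
               build_covariates(covariates))
  if (nrow(dat) <= ncol(dat) + 1) stop("too few samples for the model")
  mm <- stats::model.matrix(y ~ ., dat)
  check_design(mm)
  fit <- stats::lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients["peptide", ]
  list(beta = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       p = unname(cf["Pr(>|t|)"]), fit = fit)
}

#' Fit the glycemic-status interaction model
#'
#' OLS of the scaled ln trait on peptide, group, peptide x group and the
#' remaining covariates; the reported term is the peptide x group
#' coefficient, i.e. the difference in peptide slope between glycemic-status
#' groups.
#'
#' @param trait positive numeric vector.
#' @param peptide numeric vector of log2 abundances.
#' @param group character/factor with two levels (HC/T2D).
#' @param covariates covariates other than group.
#' @return list: `beta` (peptide main effect), `interaction_beta`,
#'   `interaction_se`, `interaction_p`, `fit`.
#' @export
fit_interaction <- function(trait, peptide, group, covariates) {
  g <- as.integer(group == "T2D")
  if (length(unique(g)) < 2) stop("both glycemic-status groups must be present")
  if (stats::sd(peptide) == 0) stop("peptide has zero variance")
  y <- prep_trait(trait)
  dat <- cbind(data.frame(y = y, peptide = peptide, group = g),
               build_covariates(covariates))
  mm <- stats::model.matrix(y ~ peptide * group + ., dat)
  check_design(mm)
  fit <- stats::lm(y ~ peptide * group + ., data = dat)
  cf <- summary(fit)$coefficients
  list(beta = cf["peptide", "Estimate"],
       interaction_beta = cf["peptide:group", "Estimate"],
       interaction_se = cf["peptide:group", "Std. Error"],
       interaction_p = cf["peptide:group", "Pr(>|t|)"],
       fit = fit)
}

#' Associate selected peptides with clinical traits
#'
#' Fits [fit_trait_model()] and [fit_interaction()] for every peptide x trait
#' pair, BH-adjusts across all pairs jointly (a per-trait family is available
#' via `family = "per_trait"`), and flags significant (q < alpha) and
#' suggestive (p < alpha pre-adjustment) associations. Traits with
#' non-positive values are skipped with a warning.
#'
#' @param m a complete log2 peptide [quant_matrix()] restricted to the
#'   peptides of interest.
#' @param traits data.frame with `sample_id`, `group`, covariate columns and
#'   the numeric trait columns.
#' @param trait_cols names of the trait columns to test.
#' @param covariate_cols covariate columns (default age, sex, smoking; group
#'   is always included as glycemic status).
#' @param alpha significance threshold.
#' @param family FDR family.
#' @return data.frame: peptide, trait, beta, se, p, q, significant,
#'   suggestive, interaction_beta, interaction_p.
#' @export
associate_all <- function(m, traits, trait_cols,
                          covariate_cols = c("age", "sex", "smoking"),
                          alpha = 0.05, family = c("joint", "per_trait")) {
  stopifnot(inherits(m, "quant_matrix"))
  family <- match.arg(family)
  if (anyNA(m$values)) stop("associate_all expects an imputed matrix")
  ord <- match(colnames(m$values), traits$sample_id)
  if (anyNA(ord)) stop("traits table does not cover all samples")
  traits <- traits[ord, , drop = FALSE]
  covs <- sanitize_covariates(traits[, covariate_cols, drop = FALSE])
  covs_main <- sanitize_covariates(cbind(covs, group = traits$group))
  rows <- list()
  for (tn in trait_cols) {
    tv <- traits[[tn]]
    if (any(is.na(tv)) || any(tv <= 0)) {
      warning("trait ", tn, " skipped (non-positive or missing values)")
      next
    }
    for (pep in rownames(m$values)) {
      x <- m$values[pep, ]
      main <- fit_trait_model(tv, x, covs_main)
      inter <- fit_interaction(tv, x, traits$group, covs)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, trait = tn, beta = main$beta, se = main$se,
        p = main$p, interaction_beta = inter$interaction_beta,
        interaction_p = inter$interaction_p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), trait = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      q = numeric(), significant = logical(),
                      suggestive = logical(), interaction_beta = numeric(),
                      interaction_p = numeric()))
  }
  out <- do.call(rbind, rows)
  out$q <- if (family == "joint") {
    bh_adjust(out$p)
  } else {
    stats::ave(out$p, out$trait, FUN = bh_adjust)
  }
  out$significant <- out$q < alpha
  out$suggestive <- out$p < alpha
  out[, c("peptide", "trait", "beta", "se", "p", "q", "significant",
          "suggestive", "interaction_beta", "interaction_p")]
}
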