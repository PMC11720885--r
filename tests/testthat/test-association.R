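make_covs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 66, 4),
             sex = sample(c("male", "female"), n, TRUE),
             smoking = sample(c("current", "ex", "never"), n, TRUE),
             group = rep(c("HC", "T2D"), length.out = n),
             stringsAsFactors = FALSE)
}

test_that("trait model equals the normal-equations oracle", {
  set.seed(40)
  n <- 40
  covs <- make_covs(n)
  pep <- rnorm(n, 20, 1)
  trait <- exp(0.3 * pep + 0.02 * covs$age + rnorm(n, 4, 0.2))
  fit <- fit_trait_model(trait, pep, covs)
  y <- as.numeric(scale(log(trait)))
  X <- cbind(1, pep, covs$age, as.integer(covs$sex == "male"),
             as.integer(covs$group == "T2D"),
             as.integer(covs$smoking == "current"),
             as.integer(covs$smoking == "ex"))
  beta_oracle <- unname(oracle_ols(X, y)[2])
  expect_equal(fit$beta, beta_oracle, tolerance = 1e-8)

  # exact linear trait without noise: p -> 0 and the slope matches
  trait0 <- exp(0.5 * pep)
  fit0 <- fit_trait_model(trait0, pep, covs["age"])
  expect_lt(fit0$p, 1e-12)
  expect_equal(fit0$beta, 0.5 / sd(log(trait0)), tolerance = 1e-8)

  expect_error(fit_trait_model(trait, rep(2, n), covs), "zero variance")
  expect_error(fit_trait_model(-trait, pep, covs), "non-positive")
  covs_bad <- covs
  covs_bad$age2 <- covs_bad$age * 2
  expect_error(fit_trait_model(trait, pep, covs_bad), "collinear")
})

test_that("permuted peptides give uniform p; covariate-only signal nulls beta", {
  set.seed(41)
  n <- 30
  covs <- make_covs(n, 41)
  trait <- exp(rnorm(n, 4, 0.3) + 0.05 * covs$age)
  ps <- replicate(200, fit_trait_model(trait, rnorm(n, 20, 1), covs)$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.045)
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)

  # trait depends on age only -> adjusted peptide effect is null on average
  betas <- replicate(100, fit_trait_model(trait, rnorm(n, 20, 1), covs)$beta)
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(100))
})

test_that("scaling a trait by a positive constant changes nothing", {
  set.seed(42)
  n <- 30
  covs <- make_covs(n, 42)
  pep <- rnorm(n, 18, 1)
  trait <- exp(0.2 * pep + rnorm(n, 3, 0.3))
  f1 <- fit_trait_model(trait, pep, covs)
  f2 <- fit_trait_model(trait * 1000, pep, covs)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("interaction model recovers planted slope differences", {
  set.seed(43)
  n <- 60
  group <- rep(c("HC", "T2D"), each = n / 2)
  covs <- data.frame(age = rnorm(n, 66, 4))
  pep <- rnorm(n, 20, 1.5)
  slope <- ifelse(group == "T2D", 0.6, 0.2)  # difference 0.4 on ln scale
  ln_tr <- 2 + slope * (pep - 20) + rnorm(n, 0, 0.2)
  fit <- fit_interaction(exp(ln_tr), pep, group, covs)
  sd_y <- sd(ln_tr)
  expect_lt(abs(fit$interaction_beta - 0.4 / sd_y), 3 * fit$interaction_se)
  expect_lt(fit$interaction_p, 0.05)

  # identical slopes in both groups -> interaction null
  ln0 <- 2 + 0.4 * (pep - 20) + rnorm(n, 0, 0.2)
  fit0 <- fit_interaction(exp(ln0), pep, group, covs)
  expect_lt(abs(fit0$interaction_beta), 4 * fit0$interaction_se)

  # dropping the interaction reproduces the pooled-model coefficient
  pooled <- fit_trait_model(exp(ln0), pep, cbind(covs, group = group))
  ref <- lm(scale(ln0) ~ pep + as.integer(group == "T2D") + covs$age)
  expect_equal(pooled$beta, unname(coef(ref)[2]), tolerance = 1e-10)

  expect_error(fit_interaction(exp(ln0), pep, rep("HC", n), covs), "both")
})

test_that("associate_all controls FDR jointly and flags tiers", {
  set.seed(44)
  n <- 30
  design_traits <- cbind(
    data.frame(sample_id = sprintf("s%02d", 1:n)),
    make_covs(n, 44))
  design_traits$insulin_t30 <- exp(rnorm(n, 5.7, 0.3))
  design_traits$waist <- exp(rnorm(n, 4.6, 0.1))
  v <- matrix(rnorm(8 * n, 20, 1), 8, n,
              dimnames = list(paste0("pep", 1:8), design_traits$sample_id))
  res <- associate_all(quant_matrix(v, "log2"), design_traits,
                       trait_cols = c("insulin_t30", "waist"))
  expect_equal(nrow(res), 16L)
  expect_equal(res$q, bh_adjust(res$p))
  expect_true(all(res$suggestive == (res$p < 0.05)))

  # single pair: q = p
  one <- associate_all(quant_matrix(v[1, , drop = FALSE], "log2"),
                       design_traits, trait_cols = "waist")
  expect_equal(one$q, one$p)

  # non-positive trait skipped with a warning
  design_traits$bad <- c(-1, design_traits$waist[-1])
  expect_warning(res2 <- associate_all(quant_matrix(v[1:2, ], "log2"),
                                       design_traits,
                                       trait_cols = c("bad", "waist")),
                 "skipped")
  expect_setequal(unique(res2$trait), "waist")

  # all-null simulation: expected fraction q < 0.05 stays at or below 0.05
  frac <- vapply(1:40, function(r) {
    vv <- matrix(rnorm(6 * n, 20, 1), 6, n,
                 dimnames = list(paste0("p", 1:6), design_traits$sample_id))
    rr <- associate_all(quant_matrix(vv, "log2"), design_traits,
                        trait_cols = c("insulin_t30", "waist"))
    mean(rr$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("planted negative peptide-insulin association recovers its sign", {
  hits <- vapply(1:60, function(r) {
    set.seed(600 + r)
    n <- 30
    covs <- make_covs(n, 600 + r)
    covs$sample_id <- sprintf("s%02d", 1:n)
    pep <- rnorm(n, 20, 1)
    covs$insulin_t30 <- exp(5.7 - 0.4 * (pep - 20) + rnorm(n, 0, 0.25))
    v <- matrix(pep, 1, n, dimnames = list("pep1", covs$sample_id))
    res <- associate_all(quant_matrix(v, "log2"), covs,
                         trait_cols = "insulin_t30")
    res$beta < 0
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})
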