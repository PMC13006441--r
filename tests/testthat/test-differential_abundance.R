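test_that("group coefficient equals difference of group means without covariates", {
  ds <- generate_dataset(null_config(seed = 1, n_proteins = 40))
  fits <- fit_covariate_model(ds$matrix, ds$metadata, covariates = character(0))
  lv <- log2(ds$matrix$values)
  gme <- ds$metadata$group == "ME"
  expect_equal(unname(fits$log2fc),
               unname(colMeans(lv[gme, ]) - colMeans(lv[!gme, ])),
               tolerance = 1e-10)
})

test_that("planted effects are recovered without bias", {
  est <- vapply(1:30, function(s) {
    cfg <- generator_config(seed = s, n_me = 40, n_hc = 40, n_proteins = 20,
                            duplication_rate = 0, noise_sd = 0.1,
                            effect_model = list(intracellular = c(0.5, 0),
                                                membrane = c(0.5, 0),
                                                membrane_secreted = c(0.5, 0),
                                                secreted = c(0.5, 0),
                                                unannotated = c(0.5, 0)),
                            covariate_effects = c(sex = 0, age = 0, bmi = 0,
                                                  fasting = 0))
    ds <- generate_dataset(cfg)
    mean(fit_covariate_model(ds$matrix, ds$metadata)$log2fc)
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.02)
})

test_that("duplicated group column triggers a rank error naming the column", {
  ds <- generate_dataset(null_config(seed = 2, n_proteins = 10))
  ds$metadata$gcopy <- as.numeric(ds$metadata$group == "ME")
  expect_error(fit_covariate_model(ds$matrix, ds$metadata,
                                   covariates = c("sex", "gcopy")),
               "rank deficient.*gcopy")
})

test_that("per-aptamer OLS matches lm() and d0 = 0 reproduces the OLS t", {
  ds <- generate_dataset(small_config(seed = 3, n_proteins = 8))
  fits <- fit_covariate_model(ds$matrix, ds$metadata)
  res <- moderate_statistics(fits, prior = list(d0 = 0, s02 = 1))
  meta <- ds$metadata
  lv <- log2(ds$matrix$values)
  for (j in c(1, 4, 8)) {
    fit <- lm(lv[, j] ~ I(meta$group == "ME") + I(meta$sex == "F") +
                meta$age + meta$bmi + meta$fasting)
    sm <- summary(fit)$coefficients
    expect_equal(res$log2fc[j], unname(sm[2, 1]), tolerance = 1e-8)
    expect_equal(res$t[j], unname(sm[2, 3]), tolerance = 1e-8)
    expect_equal(res$p[j], unname(sm[2, 4]), tolerance = 1e-8)
  }
})

test_that("equal residual variances give moderated t == OLS t with larger df", {
  # identical variances: prior estimation reports d0 = Inf, s02 = common s2
  fits <- structure(list(aptamer_id = paste0("a", 1:5),
                         log2fc = c(0.2, -0.1, 0.3, 0, 0.15),
                         sigma2 = rep(0.04, 5), df = 70,
                         se_unscaled = 0.23, n = 75),
                    class = "aptamer_fits")
  pr <- estimate_moderation_prior(fits$sigma2, fits$df)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s02, 0.04, tolerance = 1e-6)
  res <- moderate_statistics(fits, pr)
  ols <- fits$log2fc / (sqrt(fits$sigma2) * fits$se_unscaled)
  expect_equal(res$t, ols, tolerance = 1e-6)
  expect_true(all(is.infinite(res$df_total)))
})

test_that("moderation prior is recovered from the scaled chi-square model", {
  set.seed(42)
  d0 <- 4; s02 <- 1; d <- 20; m <- 2000
  true_var <- d0 * s02 / rchisq(m, d0)
  s2 <- true_var * rchisq(m, d) / d
  pr <- estimate_moderation_prior(s2, d)
  expect_gt(pr$d0, 3); expect_lt(pr$d0, 5)
  expect_gt(pr$s02, 0.9); expect_lt(pr$s02, 1.1)

  # independent oracle: limma's squeezeVar on the same draws
  skip_if_not_installed("limma")
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(pr$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(pr$s02, sq$var.prior, tolerance = 0.01)
  post <- (pr$d0 * pr$s02 + d * s2) / (pr$d0 + d)
  expect_equal(post, sq$var.post, tolerance = 0.01)
})

test_that("moderated p converges to OLS as d0 -> 0 and to z-based as d0 -> Inf", {
  fits <- structure(list(aptamer_id = paste0("a", 1:3),
                         log2fc = c(0.3, -0.2, 0.1),
                         sigma2 = c(0.05, 0.02, 0.08), df = 30,
                         se_unscaled = 0.25, n = 35),
                    class = "aptamer_fits")
  p_small <- moderate_statistics(fits, list(d0 = 1e-9, s02 = 0.04))$p
  p_ols <- moderate_statistics(fits, list(d0 = 0, s02 = 1))$p
  expect_equal(p_small, p_ols, tolerance = 1e-5)

  res_inf <- moderate_statistics(fits, list(d0 = Inf, s02 = 0.04))
  z <- fits$log2fc / (sqrt(0.04) * 0.25)
  expect_equal(res_inf$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("BH step-up matches the hand example and p.adjust, order-invariant", {
  # step-up by hand: sorted (0.01,0.03,0.04,0.5) -> raw m*p/j =
  # (0.04, 0.06, 0.05333, 0.5) -> running min from the top
  # (0.04, 0.05333, 0.05333, 0.5), mapped back to input order
  expect_equal(adjust_fdr_bh(c(0.01, 0.04, 0.03, 0.5)),
               c(0.04, 0.16 / 3, 0.16 / 3, 0.5))
  expect_equal(adjust_fdr_bh(rep(0.2, 10)), rep(0.2, 10))
  expect_equal(adjust_fdr_bh(0.07), 0.07)
  expect_error(adjust_fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(adjust_fdr_bh(p), p.adjust(p, "BH"))
    perm <- sample(50)
    expect_equal(adjust_fdr_bh(p[perm]), adjust_fdr_bh(p)[perm])
  }
  expect_true(all(adjust_fdr_bh(runif(100)) <= 1))
})

test_that("welch test matches t.test and its permutation distribution", {
  set.seed(6)
  x <- rnorm(8); y <- rnorm(12, 1)
  w <- welch_test(x, y)
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)

  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(welch_test(c(1, 2, 3), c(11, 12, 13))$p, 0.01)
  expect_equal(welch_test(c(2, 2), c(2, 2))$p, 1)

  # permutation oracle at n = 10 + 10
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  obs <- abs(welch_test(x, y)$t)
  pool <- c(x, y)
  perm <- replicate(2000, {
    idx <- sample(20, 10)
    abs(welch_test(pool[idx], pool[-idx])$t)
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(welch_test(x, y)$p - p_perm), 0.04)
})

test_that("rank classifier metrics: separation, tie handling, null AUC", {
  m <- rank_classifier_metrics(c(5, 6, 7, 1, 2, 3),
                               c("ME", "ME", "ME", "HC", "HC", "HC"))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # ME = [2,3], HC = [1,2]: pairs (2>1)+(2==2)/2+(3>1)+(3>2) = 3.5 of 4
  m2 <- rank_classifier_metrics(c(2, 3, 1, 2), c("ME", "ME", "HC", "HC"))
  expect_equal(m2$auc, 0.875)

  expect_error(rank_classifier_metrics(1:3, rep("ME", 3)), "both classes")

  set.seed(8)
  aucs <- replicate(300, {
    labs <- sample(c(rep("ME", 50), rep("HC", 29)))
    rank_classifier_metrics(rnorm(79), labs)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
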