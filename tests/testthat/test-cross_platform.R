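test_that("low-abundance filter uses a strict > rule and reproduces 77->54", {
  set.seed(1)
  n <- 100
  v <- 2^matrix(rnorm(n * 77, 5, 1), n, 77,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("an%02d", 1:77)))
  mask <- matrix("observed", n, 77, dimnames = dimnames(v))
  # 23 analytes with 51% missing; one exactly at 50%
  for (j in 1:23) mask[1:51, j] <- "masked"
  mask[1:50, 24] <- "masked"
  m <- intensity_matrix(v, mask)
  out <- low_abundance_filter(m, max_missing = 0.5)
  expect_length(out$dropped, 23)
  expect_equal(ncol(out$matrix$values), 54)
  expect_true("an24" %in% colnames(out$matrix$values))
})

test_that("concordance classes follow the mixed-first rule", {
  apt <- make_diff(c("a1", "a2", "b1", "c1"),
                   log2fc = c(0.5, 0.3, -0.4, 0.2),
                   p = c(0.01, 0.02, 0.01, 0.03))
  imm <- data.frame(protein_id = c("PA", "PB", "PC"),
                    log2fc = c(0.6, 0.5, -0.3), stringsAsFactors = FALSE)
  map <- data.frame(protein_id = c("PA", "PB", "PC"),
                    aptamer_ids = c("a1;a2", "b1", "c1"),
                    stringsAsFactors = FALSE)
  cc <- classify_concordance(apt, imm, map)
  expect_identical(cc$class, c("concordant", "discordant", "discordant"))

  # internally divergent aptamers are mixed regardless of the immunoassay
  apt2 <- make_diff(c("a1", "a2"), log2fc = c(0.5, -0.3), p = c(0.01, 0.02))
  cc2 <- classify_concordance(apt2, imm[1, , drop = FALSE],
                              map[1, , drop = FALSE])
  expect_identical(cc2$class, "mixed")

  # classes partition the shared proteins
  expect_equal(nrow(cc), 3)
  expect_true(all(cc$class %in% c("concordant", "mixed", "discordant")))

  # missing on one platform -> excluded
  map3 <- rbind(map, data.frame(protein_id = "PD", aptamer_ids = "zz"))
  cc3 <- classify_concordance(apt, imm, map3)
  expect_equal(nrow(cc3), 3)
  expect_equal(attr(cc3, "excluded"), 1L)
})

test_that("zero-noise replicate: all consistent, 100% concordant; flips degrade", {
  base <- function(flip, seed = 11) {
    null_cov <- c(sex = 0, age = 0, bmi = 0, fasting = 0)
    generator_config(seed = seed, n_proteins = 120, duplication_rate = 0,
                     covariate_effects = null_cov, platform_noise_sd = 0,
                     flip_fraction = flip)
  }
  ds <- generate_dataset(base(0))
  mapping <- data.frame(protein_id = ds$truth$protein_id,
                        analyte_id = paste0("an_", ds$truth$protein_id),
                        aptamer_ids = ds$truth$aptamer_id,
                        stringsAsFactors = FALSE)
  gme <- ds$metadata$group == "ME"
  la <- log2(ds$matrix$values)
  apt_diff <- make_diff(colnames(la),
                        log2fc = colMeans(la[gme, ]) - colMeans(la[!gme, ]),
                        p = rep(0.01, ncol(la)))

  frac_conc <- vapply(c(0, 0.25, 0.5), function(fl) {
    rep <- generate_cross_platform_replicate(ds$matrix, mapping, base(fl),
                                             group = ds$metadata$group)
    li <- log2(rep$matrix$values)
    imm_diff <- data.frame(
      protein_id = mapping$protein_id,
      log2fc = colMeans(li[gme, mapping$analyte_id]) -
        colMeans(li[!gme, mapping$analyte_id]),
      stringsAsFactors = FALSE)
    cc <- classify_concordance(apt_diff, imm_diff, mapping)
    mean(cc$class == "concordant")
  }, 0)
  expect_equal(frac_conc[1], 1)
  expect_true(all(diff(frac_conc) < 0))

  # zero-noise consistency: every pair r = 1, significant positive
  rep0 <- generate_cross_platform_replicate(ds$matrix, mapping, base(0))
  cons <- signal_consistency(ds$matrix, rep0$matrix, mapping)
  expect_equal(nrow(cons), 120)
  expect_true(all(cons$r > 1 - 1e-10))
  expect_true(all(cons$p < 0.05))
})

test_that("noise-dominated replicate yields near-chance positive calls", {
  ds <- generate_dataset(null_config(seed = 12, n_proteins = 150,
                                     duplication_rate = 0,
                                     platform_noise_sd = 100))
  mapping <- data.frame(protein_id = ds$truth$protein_id,
                        analyte_id = paste0("an_", ds$truth$protein_id),
                        aptamer_ids = ds$truth$aptamer_id,
                        stringsAsFactors = FALSE)
  rep <- generate_cross_platform_replicate(
    ds$matrix, mapping,
    null_config(seed = 12, platform_noise_sd = 100))
  cons <- signal_consistency(ds$matrix, rep$matrix, mapping)
  sig_pos <- mean(cons$r > 0 & cons$p < 0.05)
  expect_lt(sig_pos, 0.08)              # ~ alpha/2 under independence
})

test_that("stratified comparison gates post hoc tests on the ANOVA", {
  set.seed(13)
  n <- 60
  meta <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     group = rep(c("ME", "HC"), c(40, 20)),
                     metabotype = c(rep(c("M1", "M2", "M3"), length.out = 40),
                                    rep("none", 20)),
                     stringsAsFactors = FALSE)
  # all strata identical -> F ~ 0 gate closed
  vals <- rep(5, n)
  out <- suppressWarnings(
    stratified_group_comparison(vals + rnorm(n, 0, 1e-8), meta))
  expect_null(out$posthoc)

  # one metabotype shifted: ANOVA significant, its contrasts dominate
  vals2 <- rnorm(n)
  vals2[meta$metabotype == "M2"] <- vals2[meta$metabotype == "M2"] + 3
  out2 <- stratified_group_comparison(vals2, meta)
  expect_lt(out2$anova$p, 0.05)
  expect_false(is.null(out2$posthoc))
  ph <- out2$posthoc
  m2_rows <- ph$stratum_a == "M2" | ph$stratum_b == "M2"
  expect_true(all(ph$q[m2_rows] < 0.05))
  expect_true(all(ph$q[!m2_rows] > 0.05))

  # tiny stratum skipped with a record
  meta$metabotype[meta$metabotype == "M3"] <- "none"
  meta$metabotype[1] <- "M3"
  out3 <- stratified_group_comparison(vals2, meta)
  expect_true("M3" %in% out3$skipped)
})
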