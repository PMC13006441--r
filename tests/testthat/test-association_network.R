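test_that("semi-partial correlation: reduction, oracle, annihilation", {
  set.seed(1)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  plain <- semi_partial_correlation(x, y, NULL)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  # residual-regression oracle from the spec example
  x4 <- 1:4; y4 <- 1:4; z <- c(1, 1, 2, 2)
  res <- semi_partial_correlation(x4, y4, cbind(z))
  expect_equal(res$r, cor(x4, residuals(lm(y4 ~ z))), tolerance = 1e-12)
  expect_equal(res$r, 1 / sqrt(5), tolerance = 1e-10)

  # y a pure function of the covariates -> zero-variance residual
  z2 <- rnorm(20)
  expect_warning(out <- semi_partial_correlation(x, 2 * z2 + 1, cbind(z2)))
  expect_null(out)

  expect_error(semi_partial_correlation(1:3, 1:3, cbind(1:3)), "complete")
})

test_that("network communities and Venn counts partition the aptamers", {
  edges <- data.frame(
    aptamer_id = c("a1", "a2", "a2", "a3", "a3", "a3"),
    variable = c("ME", "ME", "SF36PF", "ME", "SF36PF", "metabotype"),
    r = 0.5, p = 0.01, sign = 1, stringsAsFactors = FALSE)
  net <- build_association_network(edges)
  expect_identical(net$communities$community[net$communities$aptamer_id == "a1"],
                   "ME")
  expect_identical(net$communities$community[net$communities$aptamer_id == "a2"],
                   "ME+SF36PF")
  expect_equal(sum(net$venn$n), 3)
  expect_lte(nrow(net$venn), 7)

  empty <- build_association_network(edges[0, ])
  expect_equal(nrow(empty$venn), 0)
})

test_that("planted ME-only associations land in the ME-exclusive region", {
  ds <- generate_dataset(null_config(seed = 2, n_me = 40, n_hc = 30,
                                     n_proteins = 60))
  v <- ds$matrix$values
  g <- as.numeric(ds$metadata$group == "ME")
  planted <- paste0(colnames(v)[1:20])
  set.seed(3)
  for (a in planted) v[, a] <- 2^(10 + 1.5 * g + rnorm(nrow(v), 0, 0.8))
  m <- intensity_matrix(v)
  # clinical variables mutually independent (the default metabotype/SF-36PF
  # codings correlate with diagnosis by construction of the cohort)
  vars <- list(ME = g,
               metabotype = rbinom(nrow(v), 1, 0.3),
               SF36PF = rnorm(nrow(v)))
  edges <- correlate_clinical_network(m, ds$metadata, variables = vars)
  net <- build_association_network(edges)
  comm <- net$communities
  hit <- comm$aptamer_id[comm$community == "ME"]
  expect_gte(mean(planted %in% hit), 0.9)
  # retained edges satisfy both cutoffs
  expect_true(all(abs(edges$r) > 0.3 & edges$p < 0.05))
})

test_that("hypergeometric ORA matches closed forms and brute force", {
  uni <- paste0("g", 1:20)
  expect_equal(ora_hypergeometric(uni[1:5], uni, uni)$p, 1)
  res <- ora_hypergeometric(uni[1:5], uni[1:5], uni)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(ora_hypergeometric(uni[6:10], uni[1:5], uni)$k, 0)
  expect_equal(ora_hypergeometric(uni[6:10], uni[1:5], uni)$p, 1)
  expect_error(ora_hypergeometric("a", "a", character(0)), "empty")

  # brute-force enumeration oracle for N <= 12
  N <- 11; K <- 4; n <- 5
  uni2 <- paste0("h", 1:N)
  gs <- uni2[1:K]
  sel <- uni2[c(1, 2, 5, 8, 9)]        # overlap k = 2
  k <- length(intersect(sel, gs))
  draws <- combn(N, n)
  brute <- mean(apply(draws, 2, function(idx)
    length(intersect(uni2[idx], gs)) >= k))
  expect_equal(ora_hypergeometric(sel, gs, uni2)$p, brute, tolerance = 1e-12)

  # BH across sets
  sets <- list(s1 = gs, s2 = uni2[5:8], s3 = uni2)
  tab <- ora_gene_sets(sel, sets, uni2)
  expect_equal(tab$q, adjust_fdr_bh(tab$p))
})

test_that("ligand-receptor concordance classifies pairs and categories", {
  pd <- data.frame(protein_id = c("L1", "R1", "L2", "R2", "L3", "R3"),
                   log2fc = c(0.5, 0.4, 0.6, -0.5, 0.2, 0.3),
                   p = c(0.01, 0.02, 0.01, 0.01, 0.5, 0.01),
                   stringsAsFactors = FALSE)
  pt <- data.frame(ligand = c("L1", "L2", "L3"),
                   receptor = c("R1", "R2", "R3"),
                   category = c("cytokine", "adhesion", "cytokine"),
                   stringsAsFactors = FALSE)
  out <- ligand_receptor_concordance(pd, pt)
  expect_identical(out$pairs$concordance,
                   c("concordant", "negative_concordant", NA))
  expect_identical(out$pairs$evaluable, c(TRUE, TRUE, FALSE))
  expect_true(all(c("cytokine", "adhesion") %in% out$categories$gene_set))
})

test_that("category enrichment p is uniform without planted pair coupling", {
  set.seed(4)
  ps <- replicate(100, {
    pd <- data.frame(protein_id = paste0("P", 1:40),
                     log2fc = rnorm(40), p = runif(40),
                     stringsAsFactors = FALSE)
    pt <- data.frame(ligand = paste0("P", 1:20),
                     receptor = paste0("P", 21:40),
                     category = rep(c("c1", "c2"), each = 10),
                     stringsAsFactors = FALSE)
    ligand_receptor_concordance(pd, pt)$categories$p[1]
  })
  # hypergeometric p under the null is stochastically >= uniform
  expect_gt(mean(ps > 0.5), 0.35)
})

test_that("activity correlation: construction gives fraction 1, null near alpha", {
  ds <- generate_dataset(null_config(seed = 5, n_proteins = 40))
  v <- ds$matrix$values
  steps <- ds$metadata$mean_steps
  ok <- is.finite(steps)
  set.seed(6)
  built <- colnames(v)[1:5]
  for (a in built)
    v[ok, a] <- 2^(10 + 0.002 * steps[ok] + rnorm(sum(ok), 0, 0.5))
  m <- intensity_matrix(v)
  comm <- data.frame(aptamer_id = colnames(v),
                     community = rep(c("steps", "null"),
                                     c(5, ncol(v) - 5)),
                     stringsAsFactors = FALSE)
  act <- activity_correlation(m, ds$metadata, comm)
  built_frac <- act$fraction_passing[act$community == "steps" &
                                       act$variable == "mean_steps"]
  null_frac <- act$fraction_passing[act$community == "null" &
                                      act$variable == "mean_steps"]
  expect_equal(built_frac, 1)
  expect_lt(null_frac, 0.3)
  expect_true(all(act$fraction_passing >= 0 & act$fraction_passing <= 1))
})
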