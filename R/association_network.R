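#' Semi-partial Pearson correlation
#'
#' Correlation of a clinical variable `x` with the residual of the aptamer
#' variable `y` after regressing out the covariates (covariates removed from
#' the aptamer side only). The p-value uses the t transform with
#' `n - n_covariates - 2` degrees of freedom. With no covariates this is the
#' plain Pearson correlation.
#'
#' @param x clinical variable values
#' @param y aptamer values
#' @param covariates numeric matrix of covariates (or `NULL`)
#' @return list with `r` and `p`, or `NULL` (with a warning) when the
#'   residual has zero variance
#' @export
semi_partial_correlation <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & apply(is.finite(covariates), 1, all)
  }
  n <- sum(ok)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= ncov + 2) stop("need n > n_covariates + 2 complete observations")
  xx <- x[ok]; yy <- y[ok]
  sdy0 <- stats::sd(yy)
  if (ncov > 0) {
    fit <- stats::lm.fit(cbind(1, covariates[ok, , drop = FALSE]), yy)
    yy <- fit$residuals
  }
  # residual annihilated by the covariates (up to floating noise)
  if (stats::sd(yy) <= 1e-9 * max(sdy0, 1) || stats::sd(xx) == 0) {
    warning("zero-variance residual; correlation undefined")
    return(NULL)
  }
  r <- stats::cor(xx, yy)
  df <- n - ncov - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df))
}

#' Aptamer-clinical edge table by semi-partial correlation
#'
#' Correlates every aptamer (log2 scale) with each clinical variable,
#' adjusting the aptamer side for the covariates, and retains edges with
#' `|r| > r_cut` and `p < alpha`.
#'
#' @param matrix an [intensity_matrix()]
#' @param metadata sample metadata
#' @param variables named list mapping clinical-variable name to a numeric
#'   per-sample vector (aligned to the matrix rows); defaults to ME
#'   indicator, metabotype-M1 indicator and SF-36PF from the metadata
#' @param covariates adjustment covariate names (default sex/age/bmi/fasting)
#' @param r_cut,alpha edge filters (defaults 0.3 / 0.05)
#' @return data.frame of class `edge_record`: `aptamer_id`, `variable`,
#'   `r`, `p`, `sign`
#' @export
correlate_clinical_network <- function(matrix, metadata, variables = NULL,
                                       covariates = c("sex", "age", "bmi",
                                                      "fasting"),
                                       r_cut = 0.3, alpha = 0.05) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  lv <- log2_values(matrix)
  meta <- metadata[match(rownames(lv), metadata$sample_id), , drop = FALSE]
  if (is.null(variables)) {
    variables <- list(ME = as.numeric(meta$group == "ME"),
                      metabotype = as.numeric(meta$metabotype == "M1"),
                      SF36PF = as.numeric(meta$sf36pf))
  }
  Z <- .build_design(meta, covariates)[, -(1:2), drop = FALSE]
  rows <- list()
  for (vn in names(variables)) {
    v <- variables[[vn]]
    for (a in colnames(lv)) {
      res <- tryCatch(semi_partial_correlation(v, lv[, a], Z),
                      warning = function(w) NULL, error = function(e) NULL)
      if (is.null(res)) next
      if (is.finite(res$r) && abs(res$r) > r_cut && res$p < alpha) {
        rows[[length(rows) + 1L]] <-
          data.frame(aptamer_id = a, variable = vn, r = res$r, p = res$p,
                     sign = sign(res$r), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(aptamer_id = character(0), variable = character(0),
                      r = numeric(0), p = numeric(0), sign = numeric(0),
                      stringsAsFactors = FALSE)
  class(out) <- c("edge_record", "data.frame")
  out
}

#' Bipartite aptamer-clinical network with Venn communities
#'
#' Each aptamer's community label is the sorted set of clinical variables it
#' connects to; Venn counts tally aptamers per label combination and sum to
#' the number of network aptamers.
#'
#' @param edges an `edge_record` table (already filtered)
#' @return list with `communities` (data.frame: `aptamer_id`, `community`)
#'   and `venn` (data.frame: `community`, `n`)
#' @export
build_association_network <- function(edges) {
  if (nrow(edges) == 0)
    return(list(communities = data.frame(aptamer_id = character(0),
                                         community = character(0),
                                         stringsAsFactors = FALSE),
                venn = data.frame(community = character(0), n = integer(0),
                                  stringsAsFactors = FALSE)))
  sp <- split(edges$variable, edges$aptamer_id)
  comm <- vapply(sp, function(v) paste(sort(unique(v)), collapse = "+"), "")
  communities <- data.frame(aptamer_id = names(comm), community = unname(comm),
                            stringsAsFactors = FALSE)
  tab <- table(communities$community)
  venn <- data.frame(community = names(tab), n = as.integer(tab),
                     stringsAsFactors = FALSE)
  list(communities = communities, venn = venn)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of the overlap `k` between a selected
#' set of size `n` and a gene set of size `K` drawn from a universe of size
#' `N`.
#'
#' @param selected character vector of selected ids
#' @param gene_set character vector of gene-set ids (subset of universe)
#' @param universe character vector, the universe (non-empty)
#' @param set_name label
#' @return one-row data.frame of class `ora_result`: `gene_set`, `k`, `K`,
#'   `n`, `N`, `p`
#' @export
ora_hypergeometric <- function(selected, gene_set, universe,
                               set_name = "set") {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(selected, gene_set))
  K <- length(gene_set); n <- length(selected); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(gene_set = set_name, k = k, K = K, n = n, N = N, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("ora_result", "data.frame")
  out
}

#' ORA across a collection of gene sets with BH adjustment
#'
#' @param selected selected ids
#' @param gene_sets named list of gene-set id vectors
#' @param universe the universe
#' @return data.frame with one row per set and a BH `q` column
#' @export
ora_gene_sets <- function(selected, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm)
    ora_hypergeometric(selected, gene_sets[[nm]], universe, nm))
  out <- do.call(rbind, rows)
  out$q <- adjust_fdr_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Ligand-receptor concordance analysis
#'
#' A pair is evaluable when both members are significant (`p < alpha`) in
#' the protein-level results; concordant pairs change with the same sign,
#' negative-concordant with opposite signs. Per-category enrichment of
#' evaluable pairs against all pairs uses the hypergeometric test.
#'
#' @param protein_diff protein-level results with `protein_id`, `log2fc`,
#'   `p`
#' @param pair_table data.frame with `ligand`, `receptor`, `category`
#' @param alpha significance threshold (default 0.05)
#' @return list with `pairs` (per-pair table: `ligand`, `receptor`,
#'   `category`, `evaluable`, `concordance`) and `categories` (ORA table)
#' @export
ligand_receptor_concordance <- function(protein_diff, pair_table,
                                        alpha = 0.05) {
  idx <- match(pair_table$ligand, protein_diff$protein_id)
  jdx <- match(pair_table$receptor, protein_diff$protein_id)
  lp <- protein_diff$p[idx]; rp <- protein_diff$p[jdx]
  lf <- protein_diff$log2fc[idx]; rf <- protein_diff$log2fc[jdx]
  evaluable <- !is.na(lp) & !is.na(rp) & lp < alpha & rp < alpha
  concordance <- rep(NA_character_, nrow(pair_table))
  concordance[evaluable & sign(lf) == sign(rf)] <- "concordant"
  concordance[evaluable & sign(lf) != sign(rf)] <- "negative_concordant"
  pairs <- data.frame(pair_table, evaluable = evaluable,
                      concordance = concordance, stringsAsFactors = FALSE)
  pair_ids <- paste(pair_table$ligand, pair_table$receptor, sep = "~")
  sets <- split(pair_ids, pair_table$category)
  categories <- ora_gene_sets(pair_ids[evaluable], sets, pair_ids)
  list(pairs = pairs, categories = categories)
}

#' Activity correlations within network communities
#'
#' Plain Pearson correlation of each community member (log2 intensity) with
#' each activity variable (SF-36PF, mean 24-h steps); reports the fraction
#' of members passing `|r| > r_cut` and `p < alpha` per community.
#'
#' @param matrix an [intensity_matrix()]
#' @param metadata sample metadata with `sf36pf` and `mean_steps`
#' @param communities the `communities` table from
#'   [build_association_network()]
#' @param r_cut,alpha pass thresholds (defaults 0.3 / 0.05)
#' @param min_samples minimum non-missing samples per variable (default 10)
#' @return data.frame: `community`, `variable`, `n_aptamers`,
#'   `fraction_passing`
#' @export
activity_correlation <- function(matrix, metadata, communities,
                                 r_cut = 0.3, alpha = 0.05,
                                 min_samples = 10) {
  lv <- log2_values(matrix)
  meta <- metadata[match(rownames(lv), metadata$sample_id), , drop = FALSE]
  acts <- list(sf36pf = as.numeric(meta$sf36pf),
               mean_steps = as.numeric(meta$mean_steps))
  rows <- list()
  for (vn in names(acts)) {
    v <- acts[[vn]]
    if (sum(is.finite(v)) < min_samples) next
    for (cm in unique(communities$community)) {
      apts <- intersect(communities$aptamer_id[communities$community == cm],
                        colnames(lv))
      if (length(apts) == 0) next
      pass <- vapply(apts, function(a) {
        res <- tryCatch(semi_partial_correlation(v, lv[, a], NULL),
                        warning = function(w) NULL, error = function(e) NULL)
        !is.null(res) && abs(res$r) > r_cut && res$p < alpha
      }, TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(community = cm, variable = vn, n_aptamers = length(apts),
                   fraction_passing = mean(pass), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(community = character(0), variable = character(0),
                      n_aptamers = integer(0), fraction_passing = numeric(0),
                      stringsAsFactors = FALSE)
  out
}
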