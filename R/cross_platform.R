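#' Drop low-abundance immunoassay analytes
#'
#' Removes analytes whose missing (masked) fraction strictly exceeds
#' `max_missing`; an analyte at exactly the threshold is retained.
#'
#' @param matrix an immunoassay [intensity_matrix()]
#' @param max_missing maximum tolerated missing fraction (default 0.5)
#' @return list with `matrix` (filtered) and `dropped` analyte ids
#' @export
low_abundance_filter <- function(matrix, max_missing = 0.5) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  frac <- colMeans(matrix$mask == "masked")
  drop <- names(frac)[frac > max_missing]
  keep <- setdiff(colnames(matrix$values), drop)
  list(matrix = subset_matrix(matrix, aptamers = keep), dropped = drop)
}

#' Cross-platform directional concordance classes
#'
#' Per shared protein: `mixed` when the protein's aptamers disagree in sign
#' among themselves (regardless of the immunoassay); otherwise `concordant`
#' when the shared aptamer sign equals the immunoassay sign, else
#' `discordant`. Directions are the covariate-adjusted log2FC signs on each
#' platform; set `significant_only = TRUE` to restrict aptamer directions
#' to nominally significant aptamers.
#'
#' @param aptamer_diff per-aptamer `diff_result`
#' @param immuno_diff per-analyte results with `protein_id`, `log2fc`
#'   (and `p`)
#' @param mapping data.frame with `protein_id` and `aptamer_ids`
#'   (`;`-separated)
#' @param significant_only use only `p < alpha` aptamers for the aptamer
#'   direction (default FALSE)
#' @param alpha threshold for `significant_only`
#' @return data.frame of class `concordance_record`: `protein_id`,
#'   `n_aptamers`, `aptamer_direction`, `immuno_direction`, `class`
#' @export
classify_concordance <- function(aptamer_diff, immuno_diff, mapping,
                                 significant_only = FALSE, alpha = 0.05) {
  rows <- list(); excluded <- 0L
  for (i in seq_len(nrow(mapping))) {
    pid <- mapping$protein_id[i]
    apts <- strsplit(as.character(mapping$aptamer_ids[i]), ";",
                     fixed = TRUE)[[1]]
    ad <- aptamer_diff[aptamer_diff$aptamer_id %in% apts, , drop = FALSE]
    im <- immuno_diff[immuno_diff$protein_id == pid, , drop = FALSE]
    if (nrow(ad) == 0 || nrow(im) == 0) {
      excluded <- excluded + 1L
      next
    }
    if (significant_only) {
      sig <- ad[!is.na(ad$p) & ad$p < alpha, , drop = FALSE]
      if (nrow(sig) > 0) ad <- sig
    }
    signs <- unique(sign(ad$log2fc[ad$log2fc != 0]))
    imsign <- sign(im$log2fc[1])
    cls <- if (length(signs) > 1) "mixed"
           else if (length(signs) == 1 && signs == imsign) "concordant"
           else "discordant"
    rows[[length(rows) + 1L]] <-
      data.frame(protein_id = pid, n_aptamers = nrow(ad),
                 aptamer_direction = if (length(signs) == 1) signs
                                     else NA_real_,
                 immuno_direction = imsign, class = cls,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), n_aptamers = integer(0),
                      aptamer_direction = numeric(0),
                      immuno_direction = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (excluded > 0)
    attr(out, "excluded") <- excluded
  class(out) <- c("concordance_record", "data.frame")
  out
}

#' Per protein-aptamer cross-platform signal consistency
#'
#' Pearson correlation on log2 values across shared samples for every
#' (aptamer, analyte) pair of each mapped protein, with the two-sided
#' t-transform p-value. Pairs with fewer than 3 shared samples are skipped.
#'
#' @param aptamer_matrix,immuno_matrix [intensity_matrix()] objects
#' @param mapping data.frame with `protein_id`, `analyte_id`, `aptamer_ids`
#'   (`;`-separated)
#' @return data.frame: `protein_id`, `aptamer_id`, `analyte_id`, `n`, `r`,
#'   `p`
#' @export
signal_consistency <- function(aptamer_matrix, immuno_matrix, mapping) {
  la <- log2_values(aptamer_matrix)
  li <- log2_values(immuno_matrix)
  shared <- intersect(rownames(la), rownames(li))
  rows <- list()
  for (i in seq_len(nrow(mapping))) {
    analyte <- as.character(mapping$analyte_id[i])
    if (!analyte %in% colnames(li)) next
    apts <- intersect(strsplit(as.character(mapping$aptamer_ids[i]), ";",
                               fixed = TRUE)[[1]], colnames(la))
    for (a in apts) {
      x <- la[shared, a]; y <- li[shared, analyte]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      r <- stats::cor(x[ok], y[ok])
      df <- sum(ok) - 2
      tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = mapping$protein_id[i], aptamer_id = a,
                   analyte_id = analyte, n = sum(ok), r = r,
                   p = 2 * stats::pt(-abs(tstat), df),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), aptamer_id = character(0),
                      analyte_id = character(0), n = integer(0),
                      r = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Group and metabotype-stratified comparison of one analyte
#'
#' ME vs HC Welch t test (BH-adjusted across analytes by the caller), plus
#' a one-way ANOVA across metabotype strata (M1/M2/M3 and HC) gating
#' post hoc pairwise Welch tests with BH adjustment: post hoc rows exist
#' only when the ANOVA p is below `anova_alpha`.
#'
#' @param values per-sample analyte values (aligned to metadata rows)
#' @param metadata sample metadata with `group` and `metabotype`
#' @param anova_alpha post hoc gate (default 0.05)
#' @return list with `group_test` (`t`, `df`, `p`), `anova`
#'   (`f`, `df1`, `df2`, `p`), `posthoc` (data.frame or NULL), `skipped`
#'   (character vector of strata skipped for size)
#' @export
stratified_group_comparison <- function(values, metadata,
                                        anova_alpha = 0.05) {
  g <- metadata$group
  x <- values[g == "ME"]; y <- values[g == "HC"]
  group_test <- if (sum(is.finite(x)) >= 2 && sum(is.finite(y)) >= 2)
    welch_test(x, y) else NULL
  strata <- ifelse(g == "HC", "HC", as.character(metadata$metabotype))
  keepable <- c("HC", "M1", "M2", "M3")
  strata[!strata %in% keepable] <- NA
  ok <- !is.na(strata) & is.finite(values)
  tab <- table(strata[ok])
  skipped <- names(tab)[tab < 2]
  use <- ok & strata %in% names(tab)[tab >= 2]
  anova <- NULL; posthoc <- NULL
  if (length(unique(strata[use])) >= 2) {
    fit <- stats::lm(values[use] ~ factor(strata[use]))
    an <- stats::anova(fit)
    anova <- list(f = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                  p = an$`Pr(>F)`[1])
    if (is.finite(anova$f) && anova$p < anova_alpha) {
      lev <- sort(unique(strata[use]))
      cmb <- utils::combn(lev, 2)
      ph <- lapply(seq_len(ncol(cmb)), function(i) {
        a <- values[use & strata == cmb[1, i]]
        b <- values[use & strata == cmb[2, i]]
        wt <- welch_test(a, b)
        data.frame(stratum_a = cmb[1, i], stratum_b = cmb[2, i],
                   t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
      })
      posthoc <- do.call(rbind, ph)
      posthoc$q <- adjust_fdr_bh(posthoc$p)
    } else if (is.finite(anova$f) && anova$f == 0) {
      anova$p <- 1
    }
  }
  list(group_test = group_test, anova = anova, posthoc = posthoc,
       skipped = skipped)
}
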