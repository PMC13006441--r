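# Correlation categories for duplicate-aptamer consistency. Boundaries at
# 0.3 / 0.5 / 0.8 with the lower bound inclusive for the upper class.
.correlation_category <- function(r) {
  a <- abs(r)
  ifelse(a < 0.3, "weak",
         ifelse(a < 0.5, "moderate",
                ifelse(a < 0.8, "strong", "very_strong")))
}

#' Pairwise signal consistency of duplicate aptamers
#'
#' For each protein (gene symbol) targeted by two or more aptamers, Pearson
#' correlations of all unordered aptamer pairs on the log2 scale, with the
#' category bands weak (<0.3), moderate (0.3-0.5), strong (0.5-0.8),
#' very strong (>=0.8). Pairs involving a zero-variance aptamer are skipped
#' with a warning.
#'
#' @param matrix an [intensity_matrix()]
#' @param annotations annotation table ([load_annotations()] /
#'   [generate_annotation_panels()]); aptamers without a gene symbol are
#'   never paired
#' @return data.frame: `protein_id`, `aptamer_a`, `aptamer_b`, `r`,
#'   `category`
#' @export
correlate_aptamer_pairs <- function(matrix, annotations) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  lv <- log2_values(matrix)
  if (nrow(lv) < 3) stop("need at least 3 samples for correlation")
  sym <- annotations$gene_symbol
  names(sym) <- annotations$aptamer_id
  apts <- intersect(colnames(lv), annotations$aptamer_id)
  grp <- split(apts, sym[apts])
  grp <- grp[!is.na(names(grp)) & names(grp) != "" &
               lengths(grp) >= 2]
  rows <- list(); skipped <- 0L
  for (g in names(grp)) {
    a <- sort(grp[[g]])
    cmb <- utils::combn(a, 2)
    for (i in seq_len(ncol(cmb))) {
      x <- lv[, cmb[1, i]]; y <- lv[, cmb[2, i]]
      ok <- is.finite(x) & is.finite(y)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        skipped <- skipped + 1L
        next
      }
      r <- stats::cor(x[ok], y[ok])
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = g, aptamer_a = cmb[1, i],
                   aptamer_b = cmb[2, i], r = r,
                   category = .correlation_category(r),
                   stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " pair(s) skipped (zero-variance aptamer)")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), aptamer_a = character(0),
                      aptamer_b = character(0), r = numeric(0),
                      category = character(0), stringsAsFactors = FALSE)
  out
}

#' Directional consensus per multi-aptamer protein
#'
#' Per protein, the fraction of its aptamers sharing the majority sign of
#' the group log2 fold change; consensus is true iff the fraction is at
#' least 0.8 (inclusive). Zero log2FCs count toward neither sign.
#'
#' @param diff per-aptamer results with `aptamer_id` and `log2fc` (and
#'   optionally `p`)
#' @param annotations annotation table providing the aptamer-to-gene map
#' @return data.frame: `protein_id`, `n_aptamers`, `n_up`, `n_down`,
#'   `consensus_fraction`, `consensus`
#' @export
assess_directional_consensus <- function(diff, annotations) {
  sym <- annotations$gene_symbol
  names(sym) <- annotations$aptamer_id
  d <- diff[diff$aptamer_id %in% annotations$aptamer_id, , drop = FALSE]
  d$protein_id <- sym[d$aptamer_id]
  d <- d[!is.na(d$protein_id) & d$protein_id != "", , drop = FALSE]
  sp <- split(d, d$protein_id)
  sp <- sp[vapply(sp, nrow, 0L) >= 2]
  rows <- lapply(names(sp), function(g) {
    fc <- sp[[g]]$log2fc
    up <- sum(fc > 0); down <- sum(fc < 0)
    signed <- up + down
    frac <- if (signed == 0) NA_real_ else max(up, down) / signed
    data.frame(protein_id = g, n_aptamers = length(fc), n_up = up,
               n_down = down, consensus_fraction = frac,
               consensus = !is.na(frac) && frac >= 0.8,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), n_aptamers = integer(0),
                      n_up = integer(0), n_down = integer(0),
                      consensus_fraction = numeric(0), consensus = logical(0),
                      stringsAsFactors = FALSE)
  out
}

# deterministic pick: smallest p, ties by larger |log2fc|, then id
.pick_min_p <- function(d) {
  ord <- order(d$p, -abs(d$log2fc), d$aptamer_id)
  d[ord[1], , drop = FALSE]
}

#' Resolve duplicate aptamers to protein-level records
#'
#' Five-branch decision tree prioritizing significance (p < `alpha`) and
#' directionality: (1) single aptamer keeps itself; (2) directional
#' consensus: minimum-p aptamer among the majority-sign aptamers;
#' (3) no consensus, exactly one significant aptamer: that aptamer;
#' (4) no consensus, several significant all same sign: minimum-p among
#' them; (5) no consensus, significant aptamers of opposite sign: overall
#' minimum-p aptamer with the `mixed` flag set. Ties on p break by larger
#' absolute log2FC, then lexicographic aptamer id. Aptamers without a gene
#' symbol pass through unmerged.
#'
#' @param diff per-aptamer results with `aptamer_id`, `log2fc`, `p` (and
#'   optionally `q`)
#' @param annotations annotation table providing the aptamer-to-gene map
#' @param alpha significance threshold in the tree (default 0.05)
#' @return data.frame of protein records: `protein_id`,
#'   `representative_aptamer`, `log2fc`, `p`, `q`, `n_aptamers`,
#'   `resolution_path` (1-5), `mixed`
#' @export
resolve_duplicates <- function(diff, annotations, alpha = 0.05) {
  sym <- annotations$gene_symbol
  names(sym) <- annotations$aptamer_id
  d <- as.data.frame(diff, stringsAsFactors = FALSE)
  if (!"q" %in% names(d)) d$q <- NA_real_
  d$protein_id <- sym[d$aptamer_id]
  nosym <- is.na(d$protein_id) | d$protein_id == ""
  d$protein_id[nosym] <- d$aptamer_id[nosym]
  sp <- split(d, d$protein_id)
  rows <- lapply(sp, function(dd) {
    if (nrow(dd) == 1) {
      path <- 1L; mixed <- FALSE; rep <- dd
    } else {
      up <- sum(dd$log2fc > 0); down <- sum(dd$log2fc < 0)
      signed <- up + down
      consensus <- signed > 0 && max(up, down) / signed >= 0.8
      if (consensus) {
        maj <- if (up >= down) dd$log2fc > 0 else dd$log2fc < 0
        rep <- .pick_min_p(dd[maj, , drop = FALSE])
        path <- 2L; mixed <- FALSE
      } else {
        sig <- dd[dd$p < alpha, , drop = FALSE]
        if (nrow(sig) == 1) {
          rep <- sig; path <- 3L; mixed <- FALSE
        } else if (nrow(sig) > 1 &&
                   (all(sig$log2fc > 0) || all(sig$log2fc < 0))) {
          rep <- .pick_min_p(sig); path <- 4L; mixed <- FALSE
        } else if (nrow(sig) > 1) {
          rep <- .pick_min_p(dd); path <- 5L; mixed <- TRUE
        } else {
          # no significant aptamer and no consensus: overall min-p,
          # not mixed (no conflicting significant evidence)
          rep <- .pick_min_p(dd); path <- 3L; mixed <- FALSE
        }
      }
    }
    data.frame(protein_id = dd$protein_id[1],
               representative_aptamer = rep$aptamer_id,
               log2fc = rep$log2fc, p = rep$p, q = rep$q,
               n_aptamers = nrow(dd), resolution_path = path,
               mixed = mixed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
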