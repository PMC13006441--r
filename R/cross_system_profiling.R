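# half-up rounding to `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Partition aptamers into the four reported subcellular groups
#'
#' `intracellular`, `membrane` (= membrane + membrane-and-secreted),
#' `secreted`, and `non-assigned` (unannotated). Every aptamer falls in
#' exactly one group.
#'
#' @param annotations annotation table
#' @return named character vector (aptamer_id -> reported group)
#' @export
classify_subcellular <- function(annotations) {
  cls <- annotations$subcellular_class
  grp <- ifelse(cls %in% c("membrane", "membrane_secreted"), "membrane",
                ifelse(cls == "unannotated", "non-assigned", cls))
  stats::setNames(grp, annotations$aptamer_id)
}

#' Panel counts, directions and percentages
#'
#' For one panel (a set of aptamer ids): total members, affected members at
#' `p < alpha` and at `q < alpha_q`, the up/down split among affected (sign
#' of log2FC), and the corresponding percentages rounded half-up to one
#' decimal. Affected shares use the panel total as denominator; directional
#' shares use the affected count.
#'
#' @param diff a `diff_result` (or data.frame with `aptamer_id`, `log2fc`,
#'   `p`, `q`)
#' @param panel character vector of aptamer ids (non-empty)
#' @param panel_name label for the output row
#' @param alpha,alpha_q significance thresholds (defaults 0.05)
#' @return one-row data.frame of class `profile_summary`: `panel`,
#'   `n_total`, `n_affected`, `n_affected_q`, `n_up`, `n_down`,
#'   `pct_affected`, `pct_affected_q`, `pct_up`, `pct_down`
#' @export
summarize_panel_proportions <- function(diff, panel, panel_name = "panel",
                                        alpha = 0.05, alpha_q = 0.05) {
  if (length(panel) == 0) stop("empty panel")
  d <- diff[diff$aptamer_id %in% panel, , drop = FALSE]
  n_total <- length(unique(panel))
  aff <- d[!is.na(d$p) & d$p < alpha, , drop = FALSE]
  n_affected <- nrow(aff)
  n_affected_q <- if ("q" %in% names(d))
    sum(!is.na(d$q) & d$q < alpha_q) else NA_integer_
  n_up <- sum(aff$log2fc > 0)
  n_down <- sum(aff$log2fc < 0)
  pct <- function(num, den) {
    if (is.na(num) || den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  out <- data.frame(panel = panel_name, n_total = n_total,
                    n_affected = n_affected, n_affected_q = n_affected_q,
                    n_up = n_up, n_down = n_down,
                    pct_affected = pct(n_affected, n_total),
                    pct_affected_q = pct(n_affected_q, n_total),
                    pct_up = pct(n_up, n_affected),
                    pct_down = pct(n_down, n_affected),
                    stringsAsFactors = FALSE)
  class(out) <- c("profile_summary", "data.frame")
  out
}

# asymptotic Kolmogorov upper-tail probability Q(lambda)
.kolmogorov_q <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov shift test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution at
#' `sqrt(n_eff) * D` with effective size `n_eff = nx*ny/(nx+ny)`.
#'
#' @param x,y numeric vectors (each of length >= 2)
#' @return list with `D` and `p`
#' @export
ks_shift_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each side needs >= 2 values")
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(t) mean(x <= t), 0)
  fy <- vapply(grid, function(t) mean(y <= t), 0)
  D <- max(abs(fx - fy))
  n_eff <- nx * ny / (nx + ny)
  list(D = D, p = .kolmogorov_q(sqrt(n_eff) * D))
}

#' Hodges-Lehmann location shift with confidence interval
#'
#' The shift estimate is the median of all pairwise differences
#' `x_i - y_j`; the confidence interval takes symmetric order statistics of
#' the sorted pairwise-difference set at ranks given by the normal
#' approximation to the Mann-Whitney statistic
#' (`k = floor(nm/2 - z * sqrt(n*m*(n+m+1)/12))`, bounds `D_(k)` and
#' `D_(nm+1-k)`).
#'
#' @param x,y numeric vectors (each of length >= 1)
#' @param ci_level confidence level (default 0.95)
#' @return list with `shift`, `ci_low`, `ci_high`
#' @export
hodges_lehmann <- function(x, y, ci_level = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) stop("each side needs >= 1 value")
  d <- sort(as.vector(outer(x, y, "-")))
  nm <- length(d)
  shift <- stats::median(d)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  halfw <- z * sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)
  k <- floor(nm / 2 - halfw)
  k <- max(1, min(k, floor(nm / 2)))
  list(shift = shift, ci_low = d[k], ci_high = d[nm + 1 - k])
}

#' Directional-skew profile of one aptamer class
#'
#' Combines panel proportions with the class-vs-complement KS test and
#' Hodges-Lehmann shift on the covariate-adjusted log2 fold changes.
#'
#' @param diff a `diff_result` covering all assigned aptamers
#' @param class_ids aptamer ids in the class
#' @param complement_ids aptamer ids in the comparison population (all other
#'   assigned aptamers)
#' @param panel_name label
#' @param alpha,alpha_q significance thresholds
#' @return one-row data.frame: panel proportions plus `ks_D`, `ks_p`,
#'   `hl_shift`, `hl_ci_low`, `hl_ci_high`
#' @export
profile_class_skew <- function(diff, class_ids, complement_ids,
                               panel_name = "class", alpha = 0.05,
                               alpha_q = 0.05) {
  summ <- summarize_panel_proportions(diff, class_ids, panel_name, alpha,
                                      alpha_q)
  fc_in <- diff$log2fc[diff$aptamer_id %in% class_ids]
  fc_out <- diff$log2fc[diff$aptamer_id %in% complement_ids]
  ks <- ks_shift_test(fc_in, fc_out)
  hl <- hodges_lehmann(fc_in, fc_out)
  summ$ks_D <- ks$D
  summ$ks_p <- ks$p
  summ$hl_shift <- hl$shift
  summ$hl_ci_low <- hl$ci_low
  summ$hl_ci_high <- hl$ci_high
  summ
}

#' Full cross-system footprint profile
#'
#' Subcellular classes (class vs complement-of-assigned KS/HL skew), tissue
#' and immune panels, secretome locations and functions, mitochondrial and
#' neutrophil-release sets, each summarized by
#' [summarize_panel_proportions()]; the three assigned subcellular classes
#' additionally carry skew statistics. Set `protein_level = TRUE` to run on
#' post-dedup protein records (representative aptamer statistics).
#'
#' @param diff a `diff_result`
#' @param annotations annotation table
#' @param alpha,alpha_q significance thresholds
#' @param protein_level aggregate at protein level first (via
#'   [resolve_duplicates()])
#' @return data.frame, one row per panel, with skew columns where defined
#' @export
profile_all_panels <- function(diff, annotations, alpha = 0.05,
                               alpha_q = 0.05, protein_level = FALSE) {
  if (protein_level) {
    pr <- resolve_duplicates(diff, annotations, alpha)
    diff <- data.frame(aptamer_id = pr$representative_aptamer,
                       log2fc = pr$log2fc, p = pr$p, q = pr$q,
                       stringsAsFactors = FALSE)
  }
  grp <- classify_subcellular(annotations)
  assigned <- names(grp)[grp != "non-assigned"]
  rows <- list()
  for (g in c("intracellular", "membrane", "secreted")) {
    ids <- names(grp)[grp == g]
    if (length(ids) < 2 || length(setdiff(assigned, ids)) < 2) next
    rows[[paste0("subcellular:", g)]] <-
      profile_class_skew(diff, ids, setdiff(assigned, ids),
                         paste0("subcellular:", g), alpha, alpha_q)
  }
  na_ids <- names(grp)[grp == "non-assigned"]
  if (length(na_ids) > 0)
    rows[["subcellular:non-assigned"]] <-
      .pad_skew(summarize_panel_proportions(diff, na_ids,
                                            "subcellular:non-assigned",
                                            alpha, alpha_q))
  add_set <- function(ids, name) {
    if (length(ids) > 0)
      rows[[name]] <<- .pad_skew(
        summarize_panel_proportions(diff, ids, name, alpha, alpha_q))
  }
  for (p in unique(unlist(annotations$tissue_panels)))
    add_set(annotations$aptamer_id[vapply(annotations$tissue_panels,
                                          function(v) p %in% v, TRUE)],
            paste0("tissue:", p))
  for (p in unique(unlist(annotations$immune_panels)))
    add_set(annotations$aptamer_id[vapply(annotations$immune_panels,
                                          function(v) p %in% v, TRUE)],
            paste0("immune:", p))
  for (p in setdiff(unique(annotations$secretome_location), "none"))
    add_set(annotations$aptamer_id[annotations$secretome_location == p],
            paste0("secretome_location:", p))
  for (p in setdiff(unique(annotations$secretome_function), "none"))
    add_set(annotations$aptamer_id[annotations$secretome_function == p],
            paste0("secretome_function:", p))
  add_set(annotations$aptamer_id[annotations$mito], "mito")
  add_set(annotations$aptamer_id[annotations$neutrophil_release],
          "neutrophil_release")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.pad_skew <- function(summ) {
  summ$ks_D <- NA_real_; summ$ks_p <- NA_real_
  summ$hl_shift <- NA_real_; summ$hl_ci_low <- NA_real_
  summ$hl_ci_high <- NA_real_
  summ
}
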