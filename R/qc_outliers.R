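#' Detect sample outliers in principal-component space
#'
#' Intensities are log10-transformed and column-centered; samples are
#' projected onto the first k principal components, with k the smallest
#' number explaining at least `variance_target` of total variance (capped at
#' n-2). Squared Mahalanobis distance in that score space (per-component
#' sample variances, n-1 denominator) is referred to a chi-square
#' distribution with k degrees of freedom; samples with upper-tail p below
#' `alpha` are flagged.
#'
#' @param matrix an [intensity_matrix()] of positive intensities
#' @param alpha flagging significance level (default 0.1)
#' @param variance_target fraction of variance the retained components must
#'   explain (default 0.9)
#' @return a list of class `qc_report` with `samples` (data.frame:
#'   `sample_id`, `d2`, `p`, `flagged`), `flagged` ids, `k`, and
#'   `explained` variance fractions
#' @export
detect_sample_outliers <- function(matrix, alpha = 0.1,
                                   variance_target = 0.9) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  v <- matrix$values
  if (nrow(v) < 5) stop("need at least 5 samples")
  if (any(!is.finite(v) | v <= 0))
    stop("all values must be positive for log10 transform")
  lv <- log10(v)
  cv <- scale(lv, center = TRUE, scale = FALSE)
  sv <- svd(cv)
  n <- nrow(cv)
  vars <- sv$d^2 / (n - 1)
  if (sum(vars) < .Machine$double.eps)
    stop("constant matrix: no variance to analyze")
  expl <- vars / sum(vars)
  k <- which(cumsum(expl) >= variance_target)[1]
  if (is.na(k)) k <- length(expl)
  k <- max(1L, min(k, n - 2L))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  compvar <- vars[seq_len(k)]
  d2 <- rowSums(sweep(scores^2, 2, compvar, "/"))
  p <- stats::pchisq(d2, df = k, lower.tail = FALSE)
  samples <- data.frame(sample_id = rownames(v), d2 = d2, p = p,
                        flagged = p < alpha, stringsAsFactors = FALSE)
  structure(list(samples = samples,
                 flagged = samples$sample_id[samples$flagged],
                 k = k, explained = expl),
            class = "qc_report")
}

#' Mask and impute high-leverage values (column z-scores on raw intensities)
#'
#' Per aptamer (column), cells with |z| above `z_cut` (sample mean/sd, raw
#' intensities) are masked; low-side cells are imputed with the column
#' minimum over the remaining cells and high-side cells with the column
#' maximum, and their mask flags set to `imputed`. Zero-variance columns are
#' left untouched. The output contains no missing values.
#'
#' @param matrix an [intensity_matrix()] (outlier samples already removed)
#' @param z_cut z-score threshold (default 1.8)
#' @return list with `matrix` (imputed [intensity_matrix()]) and `report`
#'   (class `qc_report`): `cells` data.frame (`sample_id`, `aptamer_id`,
#'   `original`, `replacement`, `side`), `masked_per_aptamer` counts
#' @export
mask_and_impute_leverage_points <- function(matrix, z_cut = 1.8) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  v <- matrix$values
  mask <- matrix$mask
  logs <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    keep <- mask[, j] != "masked" & is.finite(x)
    if (sum(keep) < 2) next
    mu <- mean(x[keep]); sdv <- stats::sd(x[keep])
    if (!is.finite(sdv) || sdv == 0) next
    z <- (x - mu) / sdv
    hit <- keep & abs(z) > z_cut
    if (!any(hit)) next
    remaining <- x[keep & !hit]
    if (length(remaining) == 0) next  # degenerate: nothing to impute from
    lo <- min(remaining); hi <- max(remaining)
    side <- ifelse(z[hit] < 0, "low", "high")
    repl <- ifelse(side == "low", lo, hi)
    logs[[j]] <- data.frame(sample_id = rownames(v)[hit],
                            aptamer_id = colnames(v)[j],
                            original = x[hit], replacement = repl,
                            side = side, stringsAsFactors = FALSE)
    v[hit, j] <- repl
    mask[hit, j] <- "imputed"
  }
  cells <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  if (is.null(cells))
    cells <- data.frame(sample_id = character(0), aptamer_id = character(0),
                        original = numeric(0), replacement = numeric(0),
                        side = character(0), stringsAsFactors = FALSE)
  counts <- table(factor(cells$aptamer_id, levels = colnames(v)))
  report <- structure(list(cells = cells,
                           masked_per_aptamer = as.integer(counts)),
                      class = "qc_report")
  names(report$masked_per_aptamer) <- colnames(v)
  list(matrix = intensity_matrix(v, mask), report = report)
}
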