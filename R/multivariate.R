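#' Principal component analysis of the sample space
#'
#' Covariance PCA: singular value decomposition of the per-aptamer centered
#' (not scaled) log2 matrix. The sign of each component is fixed by making
#' its largest-magnitude loading positive.
#'
#' @param matrix an [intensity_matrix()]
#' @param k number of components (must not exceed `min(n - 1, m)`)
#' @param scale. also divide each aptamer by its sd (off by default)
#' @return list of class `pca_result`: `scores` (n x k), `loadings`
#'   (m x k), `explained` (all variance fractions), `k`
#' @export
pca_project <- function(matrix, k = 2, scale. = FALSE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  lv <- log2_values(matrix)
  if (anyNA(lv)) stop("matrix contains masked cells; impute first")
  n <- nrow(lv); m <- ncol(lv)
  if (k > min(n - 1, m)) stop("k exceeds min(n - 1, m)")
  cv <- scale(lv, center = TRUE, scale = scale.)
  sv <- svd(cv)
  expl <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  loadings <- loadings[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(rownames(lv), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(lv), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings, explained = expl,
                 k = k), class = "pca_result")
}

# group-decomposition pseudo-F from a squared-distance matrix
.permanova_f <- function(d2, labels) {
  n <- length(labels)
  g <- unique(labels)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in g) {
    idx <- which(labels == lv)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (length(g) - 1)) / (ss_within / (n - length(g)))
  c(f = f, r2 = ss_between / ss_total)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Euclidean distances on the log2 matrix (or a supplied distance matrix).
#' `SS_total = sum_{i<j} d2_ij / n`, `SS_within` summed per group with its
#' own size, pseudo-`F = (SS_between/(g-1)) / (SS_within/(n-g))`,
#' `R^2 = SS_between/SS_total`. The p-value is `(1 + #{F_perm >= F_obs}) /
#' (B + 1)` over random label permutations, or the exact fraction over
#' complete enumeration when `exact = TRUE` (two groups only).
#'
#' @param x an [intensity_matrix()] or a `dist`/square distance matrix
#' @param labels group labels (>= 2 groups, each with >= 2 members)
#' @param B number of permutations (default 999)
#' @param seed integer seed for the permutations
#' @param exact enumerate all distinct label assignments instead of sampling
#' @return list of class `permanova_result`: `f`, `r2`, `p`, `B`
#' @export
permanova <- function(x, labels, B = 999, seed = 1L, exact = FALSE) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 members")
  if (inherits(x, "intensity_matrix")) {
    lv <- log2_values(x)
    if (anyNA(lv)) stop("matrix contains masked cells; impute first")
    d2 <- as.matrix(stats::dist(lv))^2
  } else {
    d2 <- as.matrix(x)^2
  }
  if (nrow(d2) != length(labels)) stop("labels do not match samples")
  obs <- .permanova_f(d2, labels)
  if (exact) {
    if (length(tab) != 2) stop("exact enumeration implemented for 2 groups")
    lv1 <- names(tab)[1]
    idx_all <- utils::combn(length(labels), tab[[1]])
    fperm <- apply(idx_all, 2, function(idx) {
      lab <- rep(names(tab)[2], length(labels))
      lab[idx] <- lv1
      .permanova_f(d2, lab)[["f"]]
    })
    p <- mean(fperm >= obs[["f"]] - 1e-12)
    B_used <- ncol(idx_all)
  } else {
    set.seed(as.integer(seed))
    count <- 0L
    for (b in seq_len(B)) {
      fp <- .permanova_f(d2, sample(labels))[["f"]]
      if (fp >= obs[["f"]] - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (B + 1)
    B_used <- B
  }
  structure(list(f = obs[["f"]], r2 = obs[["r2"]], p = p, B = B_used),
            class = "permanova_result")
}

#' Project covariates onto PC coordinates (envfit-style)
#'
#' Per covariate, least-squares regression of the (numeric-coded) covariate
#' on the PC1/PC2 scores; the fitted coefficient vector, normalized to unit
#' length, gives the direction cosines, and the regression `r^2` its
#' strength. Significance by permuting the covariate.
#'
#' @param pca a `pca_result` with `k >= 2`
#' @param metadata sample metadata aligned to the score rows
#' @param covariates names of metadata columns (binary ones are 0/1 coded)
#' @param B permutations (default 999)
#' @param seed integer seed
#' @return data.frame of class `envfit_result`: `covariate`, `pc1`, `pc2`,
#'   `r2`, `p`
#' @export
envfit_covariates <- function(pca, metadata,
                              covariates = c("sex", "age", "bmi", "fasting"),
                              B = 999, seed = 1L) {
  stopifnot(inherits(pca, "pca_result"), pca$k >= 2)
  S <- pca$scores[, 1:2]
  meta <- metadata[match(rownames(S), metadata$sample_id), , drop = FALSE]
  set.seed(as.integer(seed))
  rows <- list()
  for (cv in covariates) {
    v <- switch(cv,
                sex = as.numeric(meta$sex == "F"),
                fasting = as.numeric(meta$fasting),
                as.numeric(meta[[cv]]))
    ok <- is.finite(v)
    if (stats::sd(v[ok]) == 0) {
      warning("constant covariate skipped: ", cv)
      next
    }
    fit_r2 <- function(vv, keep) {
      f <- stats::lm.fit(cbind(1, S[keep, , drop = FALSE]), vv)
      1 - sum(f$residuals^2) / sum((vv - mean(vv))^2)
    }
    f <- stats::lm.fit(cbind(1, S[ok, , drop = FALSE]), v[ok])
    b <- f$coefficients[-1]
    dir <- b / sqrt(sum(b^2))
    r2 <- 1 - sum(f$residuals^2) / sum((v[ok] - mean(v[ok]))^2)
    count <- 0L
    for (bb in seq_len(B)) {
      if (fit_r2(sample(v[ok]), ok) >= r2 - 1e-12) count <- count + 1L
    }
    rows[[cv]] <- data.frame(covariate = cv, pc1 = dir[1], pc2 = dir[2],
                             r2 = r2, p = (1 + count) / (B + 1),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(covariate = character(0), pc1 = numeric(0),
                      pc2 = numeric(0), r2 = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("envfit_result", "data.frame")
  out
}

#' Per-aptamer variance partitioning (drop-one semi-partial R^2)
#'
#' For each aptamer, the variance fraction attributed to each model variable
#' is the squared semi-partial correlation `R2_full - R2_without_that
#' variable`; the residual fraction is `1 - R2_full`. Fractions are reported
#' as computed (they need not sum to 1 when variables are correlated).
#'
#' @param matrix an [intensity_matrix()]
#' @param metadata sample metadata
#' @param covariates adjustment covariates; the group indicator (`ME`) is
#'   always included as the first variable
#' @return data.frame: `aptamer_id`, one fraction column per variable
#'   (`ME`, covariates...), `residual`
#' @export
variance_partition <- function(matrix, metadata,
                               covariates = c("sex", "age", "bmi",
                                              "fasting")) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  meta <- metadata[match(rownames(matrix$values), metadata$sample_id), ,
                   drop = FALSE]
  Y <- log2_values(matrix)
  if (anyNA(Y)) stop("matrix contains masked cells; impute first")
  X <- .build_design(meta, covariates)   # errors on rank deficiency
  vars <- c("group", covariates)
  r2_of <- function(Xs) {
    q <- qr(Xs)
    fitted <- qr.fitted(q, Y)
    res <- Y - fitted
    1 - colSums(res^2) / colSums(scale(Y, scale = FALSE)^2)
  }
  r2_full <- r2_of(X)
  out <- data.frame(aptamer_id = colnames(Y), stringsAsFactors = FALSE)
  for (v in vars) {
    Xd <- X[, setdiff(colnames(X), v), drop = FALSE]
    frac <- r2_full - r2_of(Xd)
    out[[if (v == "group") "ME" else v]] <- pmax(0, frac)
  }
  out$residual <- 1 - r2_full
  rownames(out) <- NULL
  out
}
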