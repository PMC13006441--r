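# Build the design matrix [intercept, group, covariates] with the documented
# codings: group ME=1/HC=0, sex F=1/M=0, fasting TRUE=1, age/BMI unscaled.
.build_design <- function(metadata, covariates) {
  n <- nrow(metadata)
  X <- cbind(intercept = rep(1, n),
             group = as.numeric(metadata$group == "ME"))
  for (cv in covariates) {
    col <- switch(cv,
                  sex = as.numeric(metadata$sex == "F"),
                  fasting = as.numeric(metadata$fasting),
                  age = as.numeric(metadata$age),
                  bmi = as.numeric(metadata$bmi),
                  as.numeric(metadata[[cv]]))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    kept <- qrX$pivot[seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), kept)], collapse = ", "))
  }
  X
}

#' Per-aptamer covariate-adjusted linear model
#'
#' Ordinary least squares of log2 intensity on
#' `[intercept, group, covariates]` fitted to every aptamer at once. The
#' group coefficient (ME minus HC, covariate-adjusted) is the log2 fold
#' change; residual variance has `n - rank(design)` degrees of freedom.
#'
#' @param matrix an [intensity_matrix()] (raw intensities; log2 taken
#'   internally)
#' @param metadata sample metadata aligned by `sample_id`
#' @param covariates character vector of adjustment covariates (default
#'   `c("sex", "age", "bmi", "fasting")`)
#' @param group_col metadata column holding the two-level group label
#'   (default `"group"`, levels ME/HC); alternative binary labelings (e.g.
#'   responder status) may be supplied as a 0/1 or two-level column
#' @return list of class `aptamer_fits`: `aptamer_id`, `log2fc`, `coef`
#'   (matrix), `sigma2`, `df`, `se_unscaled` (design-based unscaled standard
#'   error of the group coefficient), `n`
#' @export
fit_covariate_model <- function(matrix, metadata,
                                covariates = c("sex", "age", "bmi", "fasting"),
                                group_col = "group") {
  stopifnot(inherits(matrix, "intensity_matrix"))
  meta <- metadata[match(rownames(matrix$values), metadata$sample_id), ,
                   drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("metadata missing for sample(s): ",
         paste(setdiff(rownames(matrix$values), metadata$sample_id),
               collapse = ", "))
  if (group_col != "group") meta$group <- .as_me_hc(meta[[group_col]])
  Y <- log2_values(matrix)
  X <- .build_design(meta, covariates)
  n <- nrow(X); rk <- ncol(X)
  if (n <= rk) stop("more model terms than samples")
  qrX <- qr(X)
  coef <- t(qr.coef(qrX, Y))              # aptamers x terms
  res <- Y - X %*% t(coef)
  df <- n - rk
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrX))
  se_unscaled <- sqrt(xtxinv[2, 2])
  structure(list(aptamer_id = colnames(Y), log2fc = coef[, "group"],
                 coef = coef, sigma2 = sigma2, df = df,
                 se_unscaled = se_unscaled, n = n),
            class = "aptamer_fits")
}

.as_me_hc <- function(x) {
  if (is.numeric(x)) return(ifelse(x == max(x), "ME", "HC"))
  lv <- sort(unique(as.character(x)))
  if (length(lv) != 2) stop("group column must have exactly two levels")
  ifelse(as.character(x) == lv[2], "ME", "HC")
}

# Newton inversion of the trigamma function (for the moderation prior).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Estimate the variance-moderation prior by moment matching
#'
#' Fits a scaled inverse-chi-square prior (`d0`, `s0^2`) to the observed
#' residual variances by matching the mean and variance of `log(s^2)` to
#' their digamma/trigamma expressions under the scaled-F sampling model.
#' When the observed spread of `log(s^2)` does not exceed its sampling
#' component, `d0` is reported infinite.
#'
#' @param sigma2 per-aptamer residual variances
#' @param df their degrees of freedom (scalar or vector)
#' @return list of class `moderation_prior`: `d0`, `s02`
#' @export
estimate_moderation_prior <- function(sigma2, df) {
  ok <- is.finite(sigma2) & sigma2 > 0
  if (sum(ok) < 2) stop("need at least 2 positive variances")
  s2 <- sigma2[ok]
  d <- rep_len(df, length(sigma2))[ok]
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: infinite prior df; the pooled
    # variance is the fixed point (identical s^2 give s2_post == s^2)
    d0 <- Inf
    s02 <- mean(s2)
  }
  structure(list(d0 = d0, s02 = s02), class = "moderation_prior")
}

#' Moderated t statistics (empirical-Bayes variance shrinkage)
#'
#' Posterior variances `(d0*s0^2 + d*s^2) / (d0 + d)` shrink each aptamer's
#' residual variance toward the prior; the moderated t statistic
#' `log2FC / (s_post * c)` is referred to a t distribution with `d0 + d`
#' degrees of freedom. `d0 = 0` reproduces the ordinary OLS t; `d0 = Inf`
#' uses the common prior variance for every aptamer.
#'
#' @param fits an `aptamer_fits` object from [fit_covariate_model()]
#' @param prior `"estimate"` (default; moment-matched via
#'   [estimate_moderation_prior()]), or a list/`moderation_prior` with `d0`
#'   and `s02` (use `d0 = 0` to switch moderation off)
#' @return data.frame of class `diff_result`: `aptamer_id`, `log2fc`,
#'   `sigma2`, `df`, `s2_post`, `t`, `df_total`, `p`, `q`, plus attributes
#'   `d0`, `s02`
#' @export
moderate_statistics <- function(fits, prior = "estimate") {
  stopifnot(inherits(fits, "aptamer_fits"))
  if (identical(prior, "estimate")) {
    prior <- estimate_moderation_prior(fits$sigma2, fits$df)
  }
  d0 <- prior$d0; s02 <- prior$s02
  if (is.null(d0) || is.null(s02)) stop("prior must supply d0 and s02")
  d <- rep_len(fits$df, length(fits$sigma2))
  if (is.infinite(d0)) {
    s2_post <- rep_len(s02, length(fits$sigma2))
    df_total <- rep_len(Inf, length(fits$sigma2))
  } else if (d0 == 0) {
    s2_post <- fits$sigma2
    df_total <- d
  } else {
    s2_post <- (d0 * s02 + d * fits$sigma2) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- fits$log2fc / (sqrt(s2_post) * fits$se_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(aptamer_id = fits$aptamer_id, log2fc = fits$log2fc,
                    sigma2 = fits$sigma2, df = d, s2_post = s2_post,
                    t = tstat, df_total = df_total, p = p,
                    q = adjust_fdr_bh(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to input
#' order. Input order never affects the result.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return vector of q-values
#' @export
adjust_fdr_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  ord <- ok[order(p[ok])]
  raw <- p[ord] * m / seq_len(m)
  q[ord] <- pmin(1, rev(cummin(rev(raw))))
  q
}

#' Welch's two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. When both groups have zero variance and equal means,
#' `t = 0`, `p = 1`.
#'
#' @param x,y numeric vectors (each of length >= 2)
#' @return list with `t`, `df`, `p`
#' @export
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p = 0))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Rank-based univariate classifier metrics
#'
#' AUC equals the Mann-Whitney statistic `U / (n1 * n0)` with ties counted
#' one half (identical to the ROC area of any monotone score, e.g. a
#' univariate logistic regression). The operating point maximizes Youden's
#' J = sensitivity + specificity - 1 over thresholds of the form
#' "score >= c predicts case"; ties on J break toward higher specificity.
#'
#' @param scores per-sample numeric scores (higher = more case-like)
#' @param labels group labels; `positive` marks the case level
#' @param positive the positive-class label (default `"ME"`)
#' @return list with `auc`, `threshold`, `sensitivity`, `specificity`
#' @export
rank_classifier_metrics <- function(scores, labels, positive = "ME") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  best <- list(j = -Inf, threshold = NA_real_, sens = NA_real_,
               spec = NA_real_)
  for (cthr in thr) {
    pred <- scores >= cthr
    sens <- sum(pred & pos) / n1
    spec <- sum(!pred & !pos) / n0
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && !is.na(best$spec) && spec > best$spec)) {
      best <- list(j = j, threshold = cthr, sens = sens, spec = spec)
    }
  }
  list(auc = auc, threshold = best$threshold, sensitivity = best$sens,
       specificity = best$spec)
}

#' Covariate-adjusted differential abundance (one call)
#'
#' Convenience wrapper: [fit_covariate_model()] then [moderate_statistics()],
#' optionally appending per-aptamer univariate classifier metrics
#' ([rank_classifier_metrics()] on the log2 intensities).
#'
#' @inheritParams fit_covariate_model
#' @param moderation `"estimate"` or `"off"` (ordinary OLS t), or a prior
#'   list with `d0`/`s02`
#' @param classifier_metrics add `auc`/`sensitivity`/`specificity` columns
#' @return a `diff_result` data.frame
#' @export
differential_abundance <- function(matrix, metadata,
                                   covariates = c("sex", "age", "bmi",
                                                  "fasting"),
                                   group_col = "group",
                                   moderation = "estimate",
                                   classifier_metrics = FALSE) {
  fits <- fit_covariate_model(matrix, metadata, covariates, group_col)
  prior <- if (identical(moderation, "off")) list(d0 = 0, s02 = 1)
           else moderation
  res <- moderate_statistics(fits, prior)
  if (classifier_metrics) {
    lv <- log2_values(matrix)
    meta <- metadata[match(rownames(lv), metadata$sample_id), , drop = FALSE]
    labs <- if (group_col == "group") meta$group
            else .as_me_hc(meta[[group_col]])
    mets <- lapply(res$aptamer_id, function(a) {
      s <- lv[, a]
      # orient so higher score tracks the estimated direction of change
      if (res$log2fc[match(a, res$aptamer_id)] < 0) s <- -s
      rank_classifier_metrics(s, labs)
    })
    res$auc <- vapply(mets, `[[`, 0, "auc")
    res$sensitivity <- vapply(mets, `[[`, 0, "sensitivity")
    res$specificity <- vapply(mets, `[[`, 0, "specificity")
  }
  res
}
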