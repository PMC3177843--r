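#' One-sample t-test against a reference value
#'
#' Standard two-sided one-sample t, used to test whether a group's
#' interference indices differ from zero (absence of interference).
#'
#' @param values Numeric vector, n >= 2, nonzero variance.
#' @param mu0 Null value (default 0).
#' @return List with `t`, `df`, `p`, `mean` and `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 observations")
  if (stats::sd(values) == 0) stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values), n = length(values))
}

#' Percentile-bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `B` times, computes the mean of
#' each resample, and takes the empirical `(1 - level)/2` and
#' `1 - (1 - level)/2` quantiles as the interval.
#'
#' @param values Numeric vector, n >= 2 (NAs dropped).
#' @param B Bootstrap iterations (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return List with `mean`, `boot_mean` (mean of resampled means),
#'   `ci_low`, `ci_high`, `excludes_zero`, `B` and `seed`.
#' @export
bootstrap_mean_ci <- function(values, B = 2000, level = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 observations")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  bm <- colMeans(matrix(values[sample.int(n, n * B, replace = TRUE)], n, B))
  qs <- stats::quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(mean = mean(values), boot_mean = mean(bm),
       ci_low = qs[1L], ci_high = qs[2L],
       excludes_zero = qs[1L] > 0 || qs[2L] < 0,
       B = B, level = level, seed = seed)
}

#' Pearson correlation with a percentile-bootstrap CI
#'
#' Product-moment correlation with the parametric two-sided p-value, plus a
#' percentile-bootstrap confidence interval obtained by resampling the
#' (x, y) pairs jointly `B` times.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both nonconstant
#'   (pairs with NA dropped).
#' @param B Bootstrap iterations (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return List of class `cor_boot` with `r`, `n`, `p_parametric`, `ci_low`,
#'   `ci_high`, `excludes_zero`, `B` and `seed`.
#' @export
pearson_with_bootstrap_ci <- function(x, y, B = 2000, level = 0.95, seed = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(x, y)
  p <- stats::cor.test(x, y)$p.value
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  xb <- matrix(x[idx], n, B)
  yb <- matrix(y[idx], n, B)
  xc <- sweep(xb, 2L, colMeans(xb))
  yc <- sweep(yb, 2L, colMeans(yb))
  den <- sqrt(colSums(xc^2) * colSums(yc^2))
  rb <- ifelse(den > 0, colSums(xc * yc) / den, NA_real_)
  qs <- stats::quantile(rb, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  out <- list(r = r, n = n, p_parametric = p,
              ci_low = qs[1L], ci_high = qs[2L],
              excludes_zero = qs[1L] > 0 || qs[2L] < 0,
              B = B, level = level, seed = seed)
  class(out) <- "cor_boot"
  out
}

#' @export
print.cor_boot <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, parametric p = %.4g), %.0f%% bootstrap CI [%.3f, %.3f]\n",
              x$r, x$n, x$p_parametric, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Normality and variance-homogeneity checks for a cell layout
#'
#' Shapiro-Wilk W per group-by-condition cell and Levene's test (absolute
#' deviations from the group means) per condition between groups, with a
#' routing flag saying whether any check fails at `alpha` (in which case the
#' analysis should branch to the bootstrap F-null / bootstrap CIs).
#'
#' @param data Long data frame with `value`, `group`, `condition`.
#' @param alpha Flagging level (default 0.05).
#' @return List of class `assumption_checks`: `shapiro` (per-cell W and p;
#'   cells with n < 3 or zero variance are skipped with a warning),
#'   `levene` (per-condition F, dfs and p) and `bootstrap_recommended`.
#' @export
assumption_checks <- function(data, alpha = 0.05) {
  stopifnot(all(c("value", "group", "condition") %in% names(data)))
  data <- data[!is.na(data$value), ]
  cells <- unique(data[, c("group", "condition")])
  sw <- lapply(seq_len(nrow(cells)), function(i) {
    v <- data$value[data$group == cells$group[i] &
                    data$condition == cells$condition[i]]
    if (length(v) < 3L || stats::sd(v) == 0) {
      warning(sprintf("normality check skipped for cell %s:%s (n < 3 or constant)",
                      cells$group[i], cells$condition[i]))
      return(data.frame(cells[i, ], n = length(v), W = NA_real_, p = NA_real_))
    }
    s <- stats::shapiro.test(v)
    data.frame(cells[i, ], n = length(v),
               W = unname(s$statistic), p = s$p.value)
  })
  sw <- do.call(rbind, sw)
  rownames(sw) <- NULL
  conds <- unique(data$condition)
  lv <- lapply(conds, function(cn) {
    d <- data[data$condition == cn, ]
    if (length(unique(d$group)) < 2L)
      return(data.frame(condition = cn, F = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_))
    lt <- car::leveneTest(d$value, factor(d$group), center = "mean")
    data.frame(condition = cn, F = lt[1, "F value"],
               df1 = lt[1, "Df"], df2 = lt[2, "Df"],
               p = lt[1, "Pr(>F)"])
  })
  lv <- do.call(rbind, lv)
  rownames(lv) <- NULL
  flag <- any(sw$p < alpha, na.rm = TRUE) || any(lv$p < alpha, na.rm = TRUE)
  out <- list(shapiro = sw, levene = lv, alpha = alpha,
              bootstrap_recommended = flag)
  class(out) <- "assumption_checks"
  out
}

#' @export
print.assumption_checks <- function(x, ...) {
  cat("Shapiro-Wilk per cell:\n"); print(x$shapiro, row.names = FALSE)
  cat("Levene per condition (mean-centered):\n"); print(x$levene, row.names = FALSE)
  cat(sprintf("bootstrap branch recommended: %s\n", x$bootstrap_recommended))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Between-samples mode: mean difference divided by the pooled (n-1)
#' standard deviation. Paired mode: mean of the differences divided by the
#' SD of the differences.
#'
#' @param a,b Numeric samples (paired mode requires equal length).
#' @param mode `"pooled"` (default) or `"paired"`.
#' @return The signed effect size `d` (sign of `mean(a) - mean(b)`).
#' @export
cohens_d <- function(a, b, mode = c("pooled", "paired")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in both samples")
  if (mode == "paired") {
    if (length(a) != length(b)) stop("paired mode requires equal lengths")
    d <- a - b
    s <- stats::sd(d)
    if (s == 0) stop("zero variance of the differences")
    return(mean(d) / s)
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Correlation after removing regression-residual outliers
#'
#' Refits the Pearson correlation after excluding points whose absolute
#' standardized residual from the simple linear regression of `y` on `x`
#' exceeds `threshold`, a sensitivity check on correlation results.
#'
#' @param x,y Numeric vectors (pairs with NA dropped).
#' @param threshold Absolute standardized-residual cutoff (default 2.5).
#' @return List with the base `r`, the trimmed `r_trimmed`, `n_removed`,
#'   ids of removed indices, and `skipped` (TRUE when fewer than 4 points
#'   would remain, in which case `r_trimmed` is NA).
#' @export
residual_outlier_correlation <- function(x, y, threshold = 2.5) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  fit <- stats::lm(y ~ x)
  rs <- stats::rstandard(fit)
  keep <- abs(rs) <= threshold
  out <- list(r = stats::cor(x, y), n = length(x),
              n_removed = sum(!keep), removed = which(!keep),
              threshold = threshold, skipped = FALSE)
  if (sum(keep) < 4L) {
    warning("fewer than 4 points remain after outlier removal; skipped")
    out$skipped <- TRUE
    out$r_trimmed <- NA_real_
  } else {
    out$r_trimmed <- stats::cor(x[keep], y[keep])
  }
  out
}
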