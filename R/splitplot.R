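# fast split-plot sums of squares on a complete N x b response matrix;
# rows must be ordered by group, gsize gives the group sizes.
# Returns the three F statistics and all SS needed by the full interface.
.splitplot_core <- function(y, gsize) {
  N <- nrow(y); b <- ncol(y); a <- length(gsize)
  g <- rep.int(seq_len(a), gsize)
  grand <- mean(y)
  rmean <- rowMeans(y)
  cmean <- colMeans(y)
  gmean <- rowsum.default(rmean, g, reorder = FALSE) / gsize
  cellm <- rowsum.default(y, g, reorder = FALSE) / gsize
  ss_total <- sum((y - grand)^2)
  ss_rows <- b * sum((rmean - grand)^2)
  ss_group <- b * sum(gsize * (gmean - grand)^2)
  ss_subj <- ss_rows - ss_group
  ss_cond <- N * sum((cmean - grand)^2)
  ss_cells <- sum(gsize * (cellm - grand)^2)
  ss_int <- ss_cells - ss_group - ss_cond
  ss_res <- ss_total - ss_rows - ss_cond - ss_int
  df <- c(group = a - 1, subj = N - a, cond = b - 1,
          int = (a - 1) * (b - 1), res = (b - 1) * (N - a))
  ms_subj <- ss_subj / df[["subj"]]
  ms_res <- ss_res / df[["res"]]
  # an effect with zero SS carries no evidence: F = 0 by convention, even
  # when the matching error stratum is also degenerate
  .f <- function(ss_eff, df_eff, ms_err) {
    if (ss_eff <= 1e-12 * max(ss_total, 1)) 0 else (ss_eff / df_eff) / ms_err
  }
  list(ss = c(group = ss_group, subj = ss_subj, cond = ss_cond,
              int = ss_int, res = ss_res, total = ss_total),
       df = df,
       f = c(group = .f(ss_group, df[["group"]], ms_subj),
             cond = .f(ss_cond, df[["cond"]], ms_res),
             int = .f(ss_int, df[["int"]], ms_res)),
       cell_means = cellm, ms_subj = ms_subj, ms_res = ms_res)
}

# coerce long data (participant, group, condition, value) to the matrix form
.splitplot_matrix <- function(data, value = "value", group = "group",
                              condition = "condition",
                              participant = "participant_id") {
  wide <- stats::reshape(
    data[, c(participant, group, condition, value)],
    idvar = c(participant, group), timevar = condition, direction = "wide")
  ycols <- setdiff(names(wide), c(participant, group))
  conds <- sub(paste0("^", value, "\\."), "", ycols)
  y <- as.matrix(wide[, ycols, drop = FALSE])
  ok <- stats::complete.cases(y)
  wide <- wide[ok, , drop = FALSE]
  y <- y[ok, , drop = FALSE]
  colnames(y) <- conds
  g <- factor(wide[[group]])
  ord <- order(g)
  list(y = y[ord, , drop = FALSE], group = g[ord],
       participants = wide[[participant]][ord], conditions = conds)
}

#' Split-plot (mixed between/within) ANOVA
#'
#' Classical sums-of-squares decomposition for a design with one
#' between-subjects factor (group) and one within-subjects factor
#' (condition), complete within-subject data. The group effect is tested
#' against the subjects-within-group stratum; the condition and
#' group-by-condition effects against the condition-by-subject residual.
#' With one between factor and complete within data the design is
#' proportionally balanced, so the decomposition is orthogonal even with
#' unequal group sizes. Rows with any missing condition are dropped
#' (listwise deletion).
#'
#' @param data Either a numeric matrix (participants x conditions) or a long
#'   data frame with columns `participant_id`, `group`, `condition`, `value`.
#' @param group Factor of group labels, one per matrix row (matrix input
#'   only).
#' @return Object of class `splitplot_result`: a data frame `table` with SS,
#'   df, MS, F, parametric p and partial eta squared per effect, plus the
#'   error strata, cell means and error-term components for post-hoc tests.
#' @examples
#' y <- matrix(rnorm(24), 6, 4)
#' split_plot_anova(y, group = rep(c("a", "b"), each = 3))
#' @export
split_plot_anova <- function(data, group = NULL) {
  if (is.matrix(data)) {
    if (is.null(group) || length(group) != nrow(data))
      stop("matrix input needs a group label per row")
    g <- factor(group)
    ord <- order(g)
    y <- data[ord, , drop = FALSE]
    g <- g[ord]
    conds <- colnames(data)
    if (is.null(conds)) conds <- paste0("c", seq_len(ncol(data)))
    parts <- rownames(y)
  } else {
    m <- .splitplot_matrix(data)
    y <- m$y; g <- m$group; conds <- m$conditions; parts <- m$participants
  }
  if (anyNA(y)) {
    ok <- stats::complete.cases(y)
    y <- y[ok, , drop = FALSE]; g <- droplevels(g[ok]); parts <- parts[ok]
  }
  gsize <- as.integer(table(g))
  if (length(gsize) < 2L || any(gsize < 2L))
    stop("insufficient data: need at least 2 participants in each of 2+ groups")
  core <- .splitplot_core(y, gsize)
  ss <- core$ss; df <- core$df; f <- core$f
  p <- c(group = stats::pf(f[["group"]], df[["group"]], df[["subj"]], lower.tail = FALSE),
         cond = stats::pf(f[["cond"]], df[["cond"]], df[["res"]], lower.tail = FALSE),
         int = stats::pf(f[["int"]], df[["int"]], df[["res"]], lower.tail = FALSE))
  eta <- c(group = ss[["group"]] / (ss[["group"]] + ss[["subj"]]),
           cond = ss[["cond"]] / (ss[["cond"]] + ss[["res"]]),
           int = ss[["int"]] / (ss[["int"]] + ss[["res"]]))
  tab <- data.frame(
    effect = c("group", "condition", "group:condition",
               "subjects_within_group", "condition:subject"),
    ss = ss[c("group", "cond", "int", "subj", "res")],
    df = df[c("group", "cond", "int", "subj", "res")],
    stringsAsFactors = FALSE)
  tab$ms <- tab$ss / tab$df
  tab$F <- c(f[["group"]], f[["cond"]], f[["int"]], NA, NA)
  tab$p <- c(p[["group"]], p[["cond"]], p[["int"]], NA, NA)
  tab$partial_eta_sq <- c(eta[["group"]], eta[["cond"]], eta[["int"]], NA, NA)
  rownames(tab) <- NULL
  rownames(core$cell_means) <- levels(g)
  colnames(core$cell_means) <- conds
  out <- list(table = tab, ss_total = ss[["total"]],
              cell_means = core$cell_means,
              group_sizes = stats::setNames(gsize, levels(g)),
              conditions = conds, participants = parts,
              ms_subj = core$ms_subj, df_subj = df[["subj"]],
              ms_res = core$ms_res, df_res = df[["res"]],
              y = y, group = g)
  class(out) <- "splitplot_result"
  out
}

#' @export
print.splitplot_result <- function(x, ...) {
  cat("Split-plot ANOVA (between: group; within: condition)\n")
  tab <- x$table
  tab$ss <- round(tab$ss, 3); tab$ms <- round(tab$ms, 3)
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bootstrap null distribution of the split-plot F statistics
#'
#' Builds an empirical null for each effect by resampling: each iteration
#' pools all N x b observations, draws N x b values with replacement,
#' arranges them into the original design shape (same group sizes), and
#' recomputes the three F statistics. The bootstrap p-value for an effect is
#' the proportion of null draws at or above the observed F (plain `k/B` by
#' default; the `(k+1)/(B+1)` correction is available).
#'
#' The default resampling unit is the individual observation, which breaks
#' all design structure and so represents the full null for every effect.
#' `unit = "participant"` instead resamples whole participant rows within
#' the pooled sample (retaining within-subject covariance).
#'
#' @param data,group As in [split_plot_anova()].
#' @param B Number of bootstrap iterations (default 2000).
#' @param seed Optional integer seed.
#' @param unit `"observation"` (default) or `"participant"`.
#' @param correction `"plain"` (k/B) or `"add_one"` ((k+1)/(B+1)).
#' @return Object of class `bootstrap_f_null` with observed F, the B x 3
#'   matrix of null F draws and `p_boot` per effect.
#' @export
bootstrap_f_null <- function(data, group = NULL, B = 2000, seed = NULL,
                             unit = c("observation", "participant"),
                             correction = c("plain", "add_one")) {
  unit <- match.arg(unit)
  correction <- match.arg(correction)
  if (B < 1) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  fit <- if (inherits(data, "splitplot_result")) data
         else split_plot_anova(data, group)
  y <- fit$y
  gsize <- as.integer(fit$group_sizes)
  N <- nrow(y); b <- ncol(y)
  pool <- as.vector(y)
  nullF <- matrix(NA_real_, B, 3L,
                  dimnames = list(NULL, c("group", "condition", "group:condition")))
  for (i in seq_len(B)) {
    yb <- if (unit == "observation")
      matrix(pool[sample.int(N * b, N * b, replace = TRUE)], N, b)
    else y[sample.int(N, N, replace = TRUE), , drop = FALSE]
    nullF[i, ] <- .splitplot_core(yb, gsize)$f
  }
  obs <- stats::setNames(fit$table$F[1:3],
                         c("group", "condition", "group:condition"))
  k <- colSums(nullF >= rep(obs, each = B))
  p_boot <- if (correction == "plain") k / B else (k + 1) / (B + 1)
  out <- list(observed_F = obs, null_F = nullF, p_boot = p_boot,
              B = B, seed = seed, unit = unit, correction = correction)
  class(out) <- "bootstrap_f_null"
  out
}

#' @export
print.bootstrap_f_null <- function(x, ...) {
  cat(sprintf("Bootstrap F-null (B = %d, unit = %s)\n", x$B, x$unit))
  print(data.frame(effect = names(x$observed_F), F = round(x$observed_F, 3),
                   p_boot = x$p_boot, row.names = NULL))
  invisible(x)
}
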