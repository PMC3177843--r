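#' Duncan's multiple range test critical value
#'
#' The studentized-range quantile at Duncan's protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` for a span of `p` ordered means,
#' i.e. `qtukey((1 - alpha)^(p - 1), p, df)`.
#'
#' @param p Number of ordered means spanned (>= 2).
#' @param df Error degrees of freedom.
#' @param alpha Per-comparison protection base level (default 0.05).
#' @return The critical studentized range.
#' @export
duncan_critical_q <- function(p, df, alpha = 0.05) {
  stopifnot(p >= 2, df >= 1)
  stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

#' Duncan's multiple range test
#'
#' Stepwise post-hoc comparison of a set of means sharing an error term.
#' Means are ranked; a pair spanning `p` ordered means is significant when
#' its difference exceeds the critical range
#' `r_p = q(alpha_p, p, df) * sqrt(error_ms / n)`, with Duncan's protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)`. Following the multiple-range
#' convention, a pair contained inside a span already found non-significant
#' is declared non-significant without testing. With unequal cell sizes `n`
#' is replaced by the harmonic mean.
#'
#' @param means Named numeric vector of cell means (>= 2).
#' @param error_ms Error mean square for these means.
#' @param error_df Its degrees of freedom.
#' @param n Observations per mean (scalar, or vector -> harmonic mean).
#' @param alpha Base significance level (default 0.05).
#' @return Data frame of class `duncan_test`: one row per pair with the
#'   ranked span, difference, critical range and significance flag.
#' @export
duncan_posthoc <- function(means, error_ms, error_df, n, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2, error_df >= 1, all(n >= 1))
  if (is.null(names(means))) names(means) <- paste0("m", seq_len(k))
  n_h <- length(n) / sum(1 / n)
  degenerate <- error_ms <= 0
  if (degenerate)
    warning("zero error mean square: all unequal means reported significant")
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  rows <- list()
  nonsig_spans <- list()    # rank intervals declared non-significant
  for (p in k:2) {
    rp <- if (degenerate) 0 else
      duncan_critical_q(p, error_df, alpha) * sqrt(error_ms / n_h)
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      blocked <- any(vapply(nonsig_spans,
                            function(s) s[1L] <= i && j <= s[2L], logical(1)))
      diff <- ms[i] - ms[j]
      sig <- if (blocked) FALSE
             else if (degenerate) diff > 0
             else diff > rp
      if (!sig) nonsig_spans[[length(nonsig_spans) + 1L]] <- c(i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        mean_1 = names(ms)[i], mean_2 = names(ms)[j],
        value_1 = unname(ms[i]), value_2 = unname(ms[j]),
        difference = unname(diff), span = p,
        critical_range = rp, significant = sig,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "error_ms") <- error_ms
  attr(out, "error_df") <- error_df
  attr(out, "n_harmonic") <- n_h
  class(out) <- c("duncan_test", "data.frame")
  out
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %.2f, error df = %.0f)\n",
              attr(x, "alpha"), attr(x, "error_df")))
  y <- as.data.frame(x)
  y$value_1 <- round(y$value_1, 3); y$value_2 <- round(y$value_2, 3)
  y$difference <- round(y$difference, 3)
  y$critical_range <- round(y$critical_range, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
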