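test_that("split-plot ANOVA reproduces the hand-computed textbook decomposition", {
  fit <- split_plot_anova(textbook_y, textbook_group)
  tab <- fit$table
  expect_equal(tab$ss, c(24, 48, 0, 16, 4), tolerance = 1e-12)
  expect_equal(tab$df, c(1, 3, 3, 4, 12))
  expect_equal(tab$F[1:3], c(6, 48, 0), tolerance = 1e-12)
  expect_equal(tab$partial_eta_sq[1:3], c(24 / 40, 48 / 52, 0), tolerance = 1e-12)
  expect_equal(tab$p[1], pf(6, 1, 4, lower.tail = FALSE))
  expect_equal(fit$ss_total, 92)
})

test_that("split-plot ANOVA agrees with the aov projection oracle on random tables", {
  set.seed(41)
  for (i in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1); b <- sample(3:5, 1)
    y <- matrix(rnorm((n1 + n2) * b, sd = sample(1:3, 1)), n1 + n2, b)
    g <- rep(c("g1", "g2"), c(n1, n2))
    fit <- split_plot_anova(y, g)
    orc <- aov_splitplot_oracle(y, g)
    got <- fit$table$ss[c(1, 4, 2, 3, 5)]
    expect_equal(got, unname(orc$ss), tolerance = 1e-8)
    expect_equal(fit$table$F[1:3], unname(orc$F[c("group", "cond", "int")]),
                 tolerance = 1e-8)
    # decomposition: strata sum to the total
    expect_equal(sum(fit$table$ss), fit$ss_total, tolerance = 1e-8)
    expect_true(all(fit$table$ss >= -1e-10))
  }
})

test_that("split-plot F statistics are location invariant and handle degenerate columns", {
  set.seed(42)
  y <- matrix(rnorm(28), 7, 4)
  g <- rep(c("a", "b"), c(4, 3))
  f1 <- split_plot_anova(y, g)$table$F[1:3]
  f2 <- split_plot_anova(y + 17.5, g)$table$F[1:3]
  expect_equal(f1, f2, tolerance = 1e-10)
  # four identical columns per participant, group means differing
  yc <- matrix(rep(c(1, 2, 5, 6), 4), 4, 4)
  fit <- split_plot_anova(yc, c("a", "a", "b", "b"))
  expect_equal(fit$table$F[fit$table$effect == "condition"], 0)
  expect_gt(fit$table$F[fit$table$effect == "group"], 0)
})

test_that("split-plot ANOVA errors on undersized groups and drops incomplete rows", {
  y <- matrix(rnorm(8), 2, 4)
  expect_error(split_plot_anova(y, c("a", "b")), "insufficient")
  y2 <- matrix(rnorm(24), 6, 4)
  y2[1, 2] <- NA
  fit <- split_plot_anova(y2, rep(c("a", "b"), each = 3))
  expect_equal(sum(fit$group_sizes), 5)   # listwise deletion
})

test_that("bootstrap F-null is deterministic, well-calibrated in shape, and respects conventions", {
  set.seed(43)
  y <- matrix(rnorm(24), 6, 4)
  g <- rep(c("a", "b"), each = 3)
  b1 <- bootstrap_f_null(y, g, B = 200, seed = 99)
  b2 <- bootstrap_f_null(y, g, B = 200, seed = 99)
  expect_identical(b1$p_boot, b2$p_boot)
  expect_identical(b1$null_F, b2$null_F)
  expect_equal(nrow(b1$null_F), 200)
  # plain proportion vs add-one correction
  k <- colSums(b1$null_F >= rep(b1$observed_F, each = 200))
  expect_equal(unname(b1$p_boot), unname(k / 200))
  b3 <- bootstrap_f_null(y, g, B = 200, seed = 99, correction = "add_one")
  expect_equal(unname(b3$p_boot), unname((k + 1) / 201))
  # an effect so large that no null draw reaches it -> p_boot = 0
  ybig <- y; ybig[, 1] <- ybig[, 1] + 100
  bb <- bootstrap_f_null(ybig, g, B = 100, seed = 7)
  expect_equal(unname(bb$p_boot[["condition"]]), 0)
})

test_that("Duncan critical values reproduce published table entries", {
  # Duncan's significant-range table, alpha = .05, error df = 20
  expect_equal(duncan_critical_q(2, 20), 2.95, tolerance = 0.015 / 2.95)
  expect_equal(duncan_critical_q(3, 20), 3.10, tolerance = 0.015 / 3.10)
  expect_equal(duncan_critical_q(4, 20), 3.19, tolerance = 0.015 / 3.19)
  # alpha = .01, df = 20
  expect_equal(duncan_critical_q(2, 20, alpha = 0.01), 4.02, tolerance = 0.015 / 4.02)
})

test_that("Duncan with two means coincides with the studentized-range decision", {
  ms <- 5; df <- 10; n <- 5
  crit <- qtukey(0.95, 2, df) * sqrt(ms / n)
  just_over <- c(a = 0, b = crit * 1.01)
  just_under <- c(a = 0, b = crit * 0.99)
  expect_true(duncan_posthoc(just_over, ms, df, n)$significant)
  expect_false(duncan_posthoc(just_under, ms, df, n)$significant)
})

test_that("Duncan blocks inner pairs inside a non-significant span", {
  ms <- 5; df <- 10; n <- 5   # r2 = 3.151, r3 = 3.293 on this scale
  means <- c(lo = 0, mid = 3.2, hi = 3.25)
  res <- duncan_posthoc(means, ms, df, n)
  # outer span (hi vs lo) is below r3 -> everything non-significant,
  # including mid vs lo whose difference exceeds r2
  expect_false(any(res$significant))
  inner <- res[res$mean_1 == "mid" & res$mean_2 == "lo", ]
  expect_gt(inner$difference, inner$critical_range)
  # unblocked control: same structure but wide outer span
  res2 <- duncan_posthoc(c(lo = 0, mid = 3.3, hi = 6.6), ms, df, n)
  expect_true(all(res2$significant))
  # identical means: nothing significant
  expect_false(any(duncan_posthoc(c(a = 1, b = 1, c = 1), ms, df, n)$significant))
})

test_that("Duncan handles degenerate variance with a warning", {
  expect_warning(res <- duncan_posthoc(c(a = 1, b = 2), 0, 10, 5),
                 "zero error mean square")
  expect_true(res$significant)
})

test_that("one-sample t-test matches hand computation", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  sym <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(one_sample_t(rep(4, 5)), "zero variance")
  expect_error(one_sample_t(3), "at least 2")
})

test_that("bootstrap mean CI: degenerate, deterministic and near the normal approximation", {
  r <- bootstrap_mean_ci(rep(2.5, 10), B = 200, seed = 1)
  expect_equal(r$ci_low, 2.5); expect_equal(r$ci_high, 2.5)
  set.seed(5); x <- rnorm(15)
  expect_identical(bootstrap_mean_ci(x, B = 500, seed = 9),
                   bootstrap_mean_ci(x, B = 500, seed = 9))
  set.seed(44)
  v <- rnorm(13, 8, 10)
  ci <- bootstrap_mean_ci(v, B = 2000, seed = 3)
  approx_width <- 2 * qnorm(0.975) * sd(v) / sqrt(13)
  expect_equal(ci$ci_high - ci$ci_low, approx_width, tolerance = 0.3)
})

test_that("Pearson correlation with bootstrap CI: exact, invariant, calibrated tails", {
  x <- 1:10
  r <- pearson_with_bootstrap_ci(x, 2 * x + 1, B = 200, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$ci_low, 1); expect_equal(r$ci_high, 1)
  set.seed(45)
  a <- rnorm(40); b <- rnorm(40)
  base <- pearson_with_bootstrap_ci(a, b, B = 100, seed = 2)
  p <- sample(40)
  perm <- pearson_with_bootstrap_ci(a[p], b[p], B = 100, seed = 2)
  expect_equal(perm$r, base$r, tolerance = 1e-12)
  # independent variables, large n: r near 0 and CI straddles it
  set.seed(46)
  xx <- rnorm(500); yy <- rnorm(500)
  big <- pearson_with_bootstrap_ci(xx, yy, B = 500, seed = 3)
  expect_lt(abs(big$r), 0.15)
  expect_false(big$excludes_zero)
  expect_error(pearson_with_bootstrap_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("Cohen's d hand values and modes", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -sqrt(2), tolerance = 1e-12)
  # mean difference equal to the pooled SD -> d = 1
  expect_equal(cohens_d(c(0, 2) + sqrt(2), c(0, 2)), 1, tolerance = 1e-12)
  expect_equal(cohens_d(c(5, 7, 10), c(4, 5, 9), mode = "paired"),
               mean(c(1, 2, 1)) / sd(c(1, 2, 1)))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(cohens_d(c(1, 2, 3), c(0, 1, 2), mode = "paired"), "zero variance")
})

test_that("assumption checks flag non-normal cells and unequal variances", {
  set.seed(47)
  d <- rbind(
    data.frame(value = rnorm(20), group = "g1", condition = "A"),
    data.frame(value = rnorm(20), group = "g2", condition = "A"),
    data.frame(value = rlnorm(20, 0, 1.5), group = "g1", condition = "B"),
    data.frame(value = rnorm(20, 0, 6), group = "g2", condition = "B"))
  ch <- assumption_checks(d)
  expect_equal(nrow(ch$shapiro), 4)
  expect_equal(nrow(ch$levene), 2)
  sw_b <- ch$shapiro$p[ch$shapiro$group == "g1" & ch$shapiro$condition == "B"]
  expect_lt(sw_b, 0.05)        # strongly skewed cell
  expect_true(ch$bootstrap_recommended)
  # ideally normal, equal-variance cells (exact normal quantiles): no flag
  q <- qnorm(ppoints(30))
  ok <- rbind(
    data.frame(value = q, group = "g1", condition = "A"),
    data.frame(value = q * 1.02 + 0.1, group = "g2", condition = "A"))
  expect_false(assumption_checks(ok)$bootstrap_recommended)
  # constant cell skipped with a warning
  cst <- rbind(ok, data.frame(value = rep(1, 5), group = "g1", condition = "B"))
  expect_warning(assumption_checks(cst), "skipped")
})

test_that("residual-outlier trimmed correlation behaves at the edges", {
  set.seed(49)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.4)
  inf_thr <- residual_outlier_correlation(x, y, threshold = Inf)
  expect_equal(inf_thr$r_trimmed, inf_thr$r)
  expect_equal(inf_thr$n_removed, 0)
  # planted extreme residual point
  x2 <- c(x, 0); y2 <- c(y, 12)
  pl <- residual_outlier_correlation(x2, y2, threshold = 2.5)
  expect_equal(pl$n_removed, 1)
  expect_gt(pl$r_trimmed, pl$r)
  expect_warning(residual_outlier_correlation(rnorm(4), rnorm(4), threshold = 0),
                 "fewer than 4")
})
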