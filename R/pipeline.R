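#' Configure an end-to-end analysis run
#'
#' Bundles every tunable of the analysis pipeline: the data source (a
#' [cohort_config()] for synthetic data, or file paths / data frames for
#' user-supplied tables), the trial filters, the participant outlier rule,
#' resampling sizes and the bootstrap routing policy.
#'
#' @param cohort A [cohort_config()] used to simulate the dataset, ignored
#'   when `inputs` is given.
#' @param inputs Optional named list with `trials`, `ratings`,
#'   `character_ratings` (data frames, or CSV paths read with
#'   [utils::read.csv()]).
#' @param rt_bounds Kept-latency bounds in ms (default `c(100, 500)`).
#' @param min_amplitude_deg Saccade amplitude criterion in degrees, applied
#'   when trials are scored from raw traces.
#' @param k_sd Participant outlier rule: SDs from the group mean (default 3).
#' @param outlier_scope `"group"` or `"sample"` (see
#'   [exclude_outlier_participants()]).
#' @param B Bootstrap iterations for all resampling stages (default 2000).
#'   `B = 0` disables every stochastic stage (parametric-only report).
#' @param alpha Significance level (default 0.05); bootstrap CIs use level
#'   `1 - alpha`.
#' @param seed Master seed for the run.
#' @param bootstrap_policy When to run the bootstrap branch:
#'   `"on_assumption_failure"` (default; only when a Shapiro-Wilk or Levene
#'   check fails), `"always"`, or `"never"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cohort = cohort_config(),
                            inputs = NULL,
                            rt_bounds = c(100, 500),
                            min_amplitude_deg = 2,
                            k_sd = 3,
                            outlier_scope = "group",
                            B = 2000,
                            alpha = 0.05,
                            seed = 1L,
                            bootstrap_policy = c("on_assumption_failure",
                                                 "always", "never")) {
  bootstrap_policy <- match.arg(bootstrap_policy)
  if (rt_bounds[1L] > rt_bounds[2L]) stop("rt_bounds must be ordered")
  if (B < 0) stop("B must be nonnegative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cfg <- list(cohort = cohort, inputs = inputs, rt_bounds = rt_bounds,
              min_amplitude_deg = min_amplitude_deg, k_sd = k_sd,
              outlier_scope = outlier_scope, B = as.integer(B),
              alpha = alpha, seed = as.integer(seed),
              bootstrap_policy = bootstrap_policy)
  class(cfg) <- "analysis_config"
  cfg
}

.load_table <- function(x) if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x

# long (value, group, condition, participant_id) layout for one measure
.measure_long <- function(tbl, measure) {
  data.frame(participant_id = tbl$participant_id, group = tbl$group,
             condition = tbl$character, value = tbl[[measure]],
             stringsAsFactors = FALSE)
}

# between-group comparison at one within-subject condition, using the
# Satterthwaite-pooled error stratum (MS_subj + (b-1) MS_res) / b
.between_at_condition <- function(fit, alpha) {
  b <- length(fit$conditions)
  ms_w <- (fit$ms_subj + (b - 1) * fit$ms_res) / b
  df_w <- ms_w^2 / ((fit$ms_subj / b)^2 / fit$df_subj +
                    ((b - 1) * fit$ms_res / b)^2 / fit$df_res)
  gs <- fit$group_sizes
  n_h <- 2 / sum(1 / gs[1:2])
  rows <- lapply(fit$conditions, function(cn) {
    m <- fit$cell_means[, cn]
    diff <- m[1L] - m[2L]
    q <- abs(diff) / sqrt(ms_w / n_h)
    pcrit <- stats::ptukey(q, 2, df_w, lower.tail = FALSE)
    g1 <- fit$y[fit$group == levels(fit$group)[1L], cn]
    g2 <- fit$y[fit$group == levels(fit$group)[2L], cn]
    data.frame(condition = cn, diff = unname(diff), q = q, df = df_w,
               p = pcrit, cohens_d = cohens_d(g1, g2),
               significant = pcrit < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# full analysis block (ANOVA + checks + bootstrap + post-hocs + one-sample
# tests) for one interference measure
.analyse_measure <- function(tbl, measure, config) {
  long <- .measure_long(tbl, measure)
  long <- long[!is.na(long$value), ]
  checks <- assumption_checks(long, alpha = config$alpha)
  fit <- split_plot_anova(long[, c("participant_id", "group", "condition", "value")])
  boot <- NULL
  run_boot <- config$B > 0 && (config$bootstrap_policy == "always" ||
              (config$bootstrap_policy == "on_assumption_failure" &&
               checks$bootstrap_recommended))
  if (run_boot) boot <- bootstrap_f_null(fit, B = config$B)
  # Duncan within each group across conditions (the within-subject error)
  duncan <- lapply(levels(fit$group), function(g) {
    duncan_posthoc(fit$cell_means[g, ], fit$ms_res, fit$df_res,
                   n = fit$group_sizes[[g]], alpha = config$alpha)
  })
  names(duncan) <- levels(fit$group)
  between <- if (length(levels(fit$group)) == 2L)
    .between_at_condition(fit, config$alpha) else NULL
  # per-cell one-sample tests against 0, bootstrap CI where normality fails
  cells <- unique(long[, c("group", "condition")])
  one_sample <- lapply(seq_len(nrow(cells)), function(i) {
    v <- long$value[long$group == cells$group[i] &
                    long$condition == cells$condition[i]]
    swp <- checks$shapiro$p[checks$shapiro$group == cells$group[i] &
                            checks$shapiro$condition == cells$condition[i]]
    use_boot <- config$B > 0 && config$bootstrap_policy != "never" &&
      length(swp) == 1L && !is.na(swp) && swp < config$alpha
    base <- data.frame(group = cells$group[i], condition = cells$condition[i],
                       n = length(v), mean = mean(v), stringsAsFactors = FALSE)
    if (use_boot) {
      ci <- bootstrap_mean_ci(v, B = config$B, level = 1 - config$alpha)
      cbind(base, data.frame(method = "bootstrap_ci", t = NA_real_,
                             df = NA_real_, p = NA_real_,
                             ci_low = ci$ci_low, ci_high = ci$ci_high,
                             significant = ci$excludes_zero))
    } else {
      tt <- one_sample_t(v)
      cbind(base, data.frame(method = "t_test", t = tt$t, df = tt$df,
                             p = tt$p, ci_low = NA_real_, ci_high = NA_real_,
                             significant = tt$p < config$alpha))
    }
  })
  one_sample <- do.call(rbind, one_sample)
  rownames(one_sample) <- NULL
  list(measure = measure, anova = fit, assumptions = checks,
       bootstrap = boot, duncan_within_group = duncan,
       between_group_at_condition = between, one_sample = one_sample)
}

#' Run the full gaze-interference analysis pipeline
#'
#' Executes the stages in order: trial scoring and filtering, interference
#' indices, participant outlier exclusion, split-plot ANOVAs for the
#' accuracy and RT indices with assumption checks and (policy-driven)
#' bootstrap F-nulls, Duncan post-hoc comparisons, per-cell one-sample tests
#' against zero (bootstrap-CI fallback where normality fails), similarity
#' and emotion scoring with their own ANOVAs, and similarity-interference
#' correlations (perceived and objective, per character and pooled) with
#' percentile-bootstrap CIs and a residual-outlier sensitivity check.
#' The whole report is deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @return A list of class `gaze_report`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  if (is.null(config$inputs)) {
    cohort <- generate_cohort(config$cohort, seed = config$seed)
    trials <- cohort$trials
    ratings <- cohort$ratings
    char_ratings <- cohort$character_ratings
  } else {
    cohort <- NULL
    trials <- .load_table(config$inputs$trials)
    ratings <- .load_table(config$inputs$ratings)
    char_ratings <- .load_table(config$inputs$character_ratings)
  }

  scored <- score_trials(trials, rt_bounds = config$rt_bounds)
  filt <- filter_summary(scored)
  itab <- interference_table(scored)

  excl_acc <- exclude_outlier_participants(itab, k_sd = config$k_sd,
                                           measure = "acc_interference",
                                           scope = config$outlier_scope)
  excl_rt <- exclude_outlier_participants(itab, k_sd = config$k_sd,
                                          measure = "rt_interference",
                                          scope = config$outlier_scope)

  acc <- .analyse_measure(excl_acc$table, "acc_interference", config)
  rt <- .analyse_measure(excl_rt$table, "rt_interference", config)

  # questionnaire scores
  sim <- similarity_table(ratings, char_ratings)
  groups <- unique(itab[, c("participant_id", "group")])
  sim <- merge(sim, groups, by = "participant_id", sort = FALSE)
  sim_anova <- emo_anova <- NULL
  sim_long <- data.frame(participant_id = sim$participant_id, group = sim$group,
                         condition = sim$character, value = sim$perceived)
  if (nrow(sim_long) > 0L)
    sim_anova <- tryCatch(split_plot_anova(sim_long), error = function(e) NULL)
  if ("emotion_positivity" %in% names(sim)) {
    emo_long <- data.frame(participant_id = sim$participant_id, group = sim$group,
                           condition = sim$character, value = sim$emotion_positivity)
    emo_anova <- tryCatch(split_plot_anova(emo_long), error = function(e) NULL)
  }

  # similarity-interference correlations on the outlier-screened accuracy table
  cor_tbl <- merge(excl_acc$table, sim,
                   by = c("participant_id", "group", "character"), sort = FALSE)
  chars <- unique(cor_tbl$character)
  # with B = 0 the report is parametric-only and has no seed-dependent field
  cor_fun <- function(x, y) {
    if (config$B > 0)
      return(pearson_with_bootstrap_ci(x, y, B = config$B, level = 1 - config$alpha))
    ok <- stats::complete.cases(x, y)
    list(r = stats::cor(x[ok], y[ok]), n = sum(ok),
         p_parametric = stats::cor.test(x[ok], y[ok])$p.value,
         ci_low = NA_real_, ci_high = NA_real_, excludes_zero = NA)
  }
  cors <- list()
  for (mode in c("perceived", "objective")) {
    per_char <- lapply(chars, function(ch) {
      d <- cor_tbl[cor_tbl$character == ch, ]
      res <- tryCatch(cor_fun(d[[mode]], d$acc_interference),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(character = ch, mode = mode, r = res$r, n = res$n,
                 p_parametric = res$p_parametric, ci_low = res$ci_low,
                 ci_high = res$ci_high, excludes_zero = res$excludes_zero,
                 stringsAsFactors = FALSE)
    })
    cors[[mode]] <- do.call(rbind, per_char)
  }
  pooled <- tryCatch(cor_fun(cor_tbl$perceived, cor_tbl$acc_interference),
                     error = function(e) NULL)

  sensitivity <- lapply(chars, function(ch) {
    d <- cor_tbl[cor_tbl$character == ch, ]
    s <- residual_outlier_correlation(d$perceived, d$acc_interference)
    data.frame(character = ch, r = s$r, r_trimmed = s$r_trimmed,
               n_removed = s$n_removed, stringsAsFactors = FALSE)
  })
  sensitivity <- do.call(rbind, sensitivity)

  out <- list(
    filter_summary = filt,
    interference = itab,
    exclusions = list(accuracy = excl_acc$excluded, rt = excl_rt$excluded,
                      flags = excl_acc$flags),
    accuracy = acc,
    rt = rt,
    similarity = sim,
    similarity_anova = sim_anova,
    emotion_anova = emo_anova,
    correlations = cors,
    correlation_pooled = pooled,
    outlier_sensitivity = sensitivity,
    provenance = list(seed = config$seed, config = config,
                      version = as.character(utils::packageVersion("gazecue"))),
    cohort = cohort)
  class(out) <- "gaze_report"
  out
}

#' @export
print.gaze_report <- function(x, ...) {
  cat("== Gaze-interference analysis report ==\n\n")
  print(x$filter_summary)
  cat(sprintf("\nParticipants excluded (accuracy rule): %s\n",
              if (length(x$exclusions$accuracy)) paste(x$exclusions$accuracy, collapse = ", ")
              else "none"))
  cat("\n-- Accuracy interference (percentage points) --\n")
  print(x$accuracy$anova)
  if (!is.null(x$accuracy$bootstrap)) print(x$accuracy$bootstrap)
  cat("\n-- RT interference (ms) --\n")
  print(x$rt$anova)
  if (!is.null(x$correlations$perceived)) {
    cat("\n-- Perceived-similarity vs accuracy interference --\n")
    print(x$correlations$perceived, row.names = FALSE)
  }
  cat(sprintf("\nSeed: %d\n", x$provenance$seed))
  invisible(x)
}

#' Recompute correlations under alternative outlier thresholds
#'
#' Sensitivity analysis on a completed report: for each character, the
#' perceived-similarity vs accuracy-interference correlation is recomputed
#' after removing points whose absolute standardized regression residuals
#' exceed each threshold in `thresholds`.
#'
#' @param report A [run_pipeline()] result.
#' @param thresholds Residual cutoffs to try (default `c(2.5, 3)`).
#' @return Data frame: character x threshold with base and trimmed r.
#' @export
outlier_sensitivity <- function(report, thresholds = c(2.5, 3)) {
  stopifnot(inherits(report, "gaze_report"))
  tbl <- merge(report$interference, report$similarity,
               by = c("participant_id", "character"), sort = FALSE)
  tbl <- tbl[!tbl$participant_id %in% report$exclusions$accuracy, ]
  rows <- list()
  for (ch in unique(tbl$character)) {
    d <- tbl[tbl$character == ch & !is.na(tbl$acc_interference), ]
    for (th in thresholds) {
      s <- residual_outlier_correlation(d$perceived, d$acc_interference, th)
      rows[[length(rows) + 1L]] <- data.frame(
        character = ch, threshold = th, r = s$r, r_trimmed = s$r_trimmed,
        n_removed = s$n_removed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# flatten a splitplot_result (+ optional bootstrap) to a plain list
.report_block <- function(fit, boot = NULL) {
  if (is.null(fit)) return(NULL)
  eff <- fit$table[1:3, ]
  blk <- lapply(seq_len(3L), function(i) {
    b <- list(effect = eff$effect[i], ss = eff$ss[i], df = eff$df[i],
              F = eff$F[i], p_parametric = eff$p[i],
              partial_eta_sq = eff$partial_eta_sq[i])
    if (!is.null(boot)) b$p_boot <- unname(boot$p_boot[i])
    b
  })
  list(effects = blk,
       error_strata = list(
         subjects_within_group = list(ss = fit$table$ss[4L], df = fit$table$df[4L]),
         condition_by_subject = list(ss = fit$table$ss[5L], df = fit$table$df[5L])),
       cell_means = as.data.frame(fit$cell_means))
}

#' Serialise an analysis report to JSON
#'
#' Writes the machine-readable master report (effects, p-values, tables,
#' provenance) as JSON; side tables can be exported as CSV with the usual
#' `write.csv` on the report components.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "gaze_report"))
  cfg <- unclass(report$provenance$config)
  cfg$cohort <- if (!is.null(cfg$cohort)) {
    co <- unclass(cfg$cohort); co$err_prob <- as.vector(co$err_prob); co
  }
  obj <- list(
    filter_summary = report$filter_summary[c("table", "n_total", "pct_no_saccade",
                                             "pct_rejected_of_total",
                                             "pct_rejected_of_detected")],
    excluded_participants = report$exclusions[c("accuracy", "rt")],
    accuracy = .report_block(report$accuracy$anova, report$accuracy$bootstrap),
    rt = .report_block(report$rt$anova, report$rt$bootstrap),
    accuracy_one_sample = report$accuracy$one_sample,
    rt_one_sample = report$rt$one_sample,
    similarity_anova = .report_block(report$similarity_anova),
    emotion_anova = .report_block(report$emotion_anova),
    correlations = report$correlations,
    correlation_pooled = report$correlation_pooled[
      c("r", "n", "p_parametric", "ci_low", "ci_high", "excludes_zero")],
    outlier_sensitivity = report$outlier_sensitivity,
    provenance = list(seed = report$provenance$seed,
                      version = report$provenance$version,
                      config = cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                       dataframe = "rows", pretty = TRUE, null = "null")
  invisible(path)
}
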