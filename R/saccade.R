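#' Construct a horizontal gaze trace
#'
#' A gaze trace holds time-stamped horizontal eye-position samples for one
#' trial, together with the time of the imperative cue. Positions are in
#' degrees of visual angle, signed with rightward positive.
#'
#' @param t_ms Numeric vector of sample times in ms since trial start,
#'   strictly increasing, nominally equally spaced.
#' @param x_deg Numeric vector of horizontal positions (degrees), same length.
#' @param cue_onset_ms Time of the imperative cue, inside the trace span.
#' @return An object of class `gaze_trace` (a data frame with columns
#'   `t_ms`, `x_deg` and attribute `cue_onset_ms`).
#' @export
gaze_trace <- function(t_ms, x_deg, cue_onset_ms) {
  if (length(t_ms) != length(x_deg))
    stop("t_ms and x_deg must have the same length")
  if (length(t_ms) < 2L)
    stop("a gaze trace needs at least 2 samples")
  if (any(diff(t_ms) <= 0))
    stop("malformed trace: timestamps must be strictly increasing")
  if (!is.numeric(cue_onset_ms) || length(cue_onset_ms) != 1L ||
      cue_onset_ms < t_ms[1L] || cue_onset_ms > t_ms[length(t_ms)])
    stop("cue_onset_ms must lie within the trace span")
  out <- data.frame(t_ms = as.numeric(t_ms), x_deg = as.numeric(x_deg))
  attr(out, "cue_onset_ms") <- as.numeric(cue_onset_ms)
  class(out) <- c("gaze_trace", "data.frame")
  out
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("Gaze trace: %d samples, %.1f-%.1f ms, cue at %.1f ms\n",
              nrow(x), x$t_ms[1L], x$t_ms[nrow(x)], attr(x, "cue_onset_ms")))
  invisible(x)
}

# centered moving average; half-width w samples (w = 0 returns x unchanged)
.moving_average <- function(x, w) {
  if (w <= 0L) return(x)
  n <- length(x)
  k <- 2L * w + 1L
  cs <- cumsum(c(0, x))
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# least-squares template refinement of the movement onset: the position
# signal is modelled as baseline, then a linear ramp of duration D starting
# at tau, then the landing plateau; (tau, D) are fit by grid search on the
# samples around the detected velocity run and tau is returned.
.refine_onset <- function(t, x, i0, i1, baseline, landing, period) {
  lo <- t[i0] - 6 * period
  hi <- t[i1] + 6 * period
  use <- which(t >= lo - 80 & t <= hi + 80)
  tt <- t[use]; xx <- x[use]
  run_span <- max(t[i1] - t[i0], period)
  taus <- seq(t[i0] - 5 * period, t[i0] + 5 * period, by = period / 10)
  amp <- landing - baseline
  # candidate durations: the saccadic main-sequence band for this amplitude
  # (duration ~ 2.2 deg/ms * A + 21 ms), plus short ones for step-like
  # traces; an unconstrained duration trades off against onset and inflates
  # the onset error at low signal-to-noise
  d_main <- 2.2 * abs(amp) + 21
  durs <- sort(unique(c(d_main * seq(0.7, 1.3, by = 0.06),
                        run_span * seq(0.3, 1.2, by = 0.15),
                        period * c(0.25, 0.5, 1))))
  best <- c(t[i0], Inf)
  for (D in durs) {
    for (tau in taus) {
      pred <- baseline + amp * pmin(1, pmax(0, (tt - tau) / D))
      sse <- sum((xx - pred)^2)
      if (sse < best[2L]) best <- c(tau, sse)
    }
  }
  best[1L]
}

#' Detect the first scored saccade in a gaze trace
#'
#' Finds the earliest post-cue horizontal movement whose (centered-difference)
#' velocity exceeds `velocity_threshold_deg_s` for at least two consecutive
#' samples of consistent sign and whose displacement, measured from the
#' pre-movement median position to the median position over the 50 ms after
#' movement offset, exceeds `min_amplitude_deg`. Sub-amplitude velocity events
#' (noise) are skipped; only the first suprathreshold saccade is scored even
#' if corrective saccades follow.
#'
#' The reported onset is refined by a least-squares template fit
#' (baseline, linear ramp, landing plateau) around the detected velocity
#' run, which is robust to sample-level velocity noise around the
#' threshold and recovers onsets to sub-sample precision.
#'
#' @param trace A [gaze_trace()].
#' @param min_amplitude_deg Minimum saccade amplitude in degrees (default 2).
#' @param velocity_threshold_deg_s Velocity threshold in deg/s (default 30).
#' @param smooth_halfwidth Half-width, in samples, of the centered moving
#'   average applied to position before differentiation (default 1).
#' @return A list of class `saccade_event` with elements `onset_ms` (relative
#'   to cue onset), `amplitude_deg` and `direction` (`"left"`/`"right"`), or
#'   `NULL` if no qualifying saccade is found.
#' @export
detect_first_saccade <- function(trace, min_amplitude_deg = 2,
                                 velocity_threshold_deg_s = 30,
                                 smooth_halfwidth = 1L) {
  if (!inherits(trace, "gaze_trace"))
    trace <- gaze_trace(trace$t_ms, trace$x_deg, attr(trace, "cue_onset_ms"))
  t <- trace$t_ms
  x <- trace$x_deg
  cue <- attr(trace, "cue_onset_ms")
  n <- length(t)
  period <- stats::median(diff(t))
  if (any(abs(diff(t) - period) > 0.1 * period + 1e-9))
    warning("sampling period jitter exceeds 10% of the nominal period")

  xs <- .moving_average(x, as.integer(smooth_halfwidth))
  idx <- 2:(n - 1L)
  v <- rep(NA_real_, n)
  v[idx] <- (xs[idx + 1L] - xs[idx - 1L]) / (t[idx + 1L] - t[idx - 1L]) * 1000

  above <- !is.na(v) & abs(v) >= velocity_threshold_deg_s
  sgn <- sign(v)

  # maximal runs of >= 2 consecutive suprathreshold samples of constant sign,
  # merging same-sign runs separated by a single sub-threshold sample
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j, sgn[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) > 1L) {
    merged <- list(runs[[1L]])
    for (r in runs[-1L]) {
      last <- merged[[length(merged)]]
      if (r[3L] == last[3L] && r[1L] - last[2L] <= 2L) {
        merged[[length(merged)]][2L] <- r[2L]
      } else merged[[length(merged) + 1L]] <- r
    }
    runs <- merged
  }
  runs <- Filter(function(r) r[2L] - r[1L] >= 1L, runs)

  for (r in runs) {
    i0 <- r[1L]; i1 <- r[2L]
    # a scored saccade must follow the cue (allow centered-difference lead)
    if (t[i1] < cue) next
    pre <- x[t >= t[i0] - 100 & t < t[i0]]
    post <- x[t >= t[i1] & t <= t[i1] + 50]
    if (length(pre) == 0L) pre <- x[1L]
    if (length(post) == 0L) post <- x[n]
    baseline <- stats::median(pre)
    landing <- stats::median(post)
    amp <- abs(landing - baseline)
    if (amp <= min_amplitude_deg) next
    # guard against noise flutter just ahead of a real saccade: the run
    # itself must carry a substantial part of the displacement
    if (abs(xs[i1] - baseline) <= min_amplitude_deg / 2) next

    # onset: least-squares fit of a baseline-ramp-plateau template around
    # the detected run (grid over onset time and movement duration), which
    # is far more noise-tolerant than the raw threshold-crossing sample
    onset_t <- .refine_onset(t, x, i0, i1, baseline, landing, period)
    if (onset_t < cue - period) next
    ev <- list(onset_ms = onset_t - cue,
               amplitude_deg = amp,
               direction = if (landing < baseline) "left" else "right")
    class(ev) <- "saccade_event"
    return(ev)
  }
  NULL
}

#' @export
print.saccade_event <- function(x, ...) {
  cat(sprintf("Saccade: onset %.1f ms post-cue, amplitude %.2f deg, %s\n",
              x$onset_ms, x$amplitude_deg, x$direction))
  invisible(x)
}

#' Score a single trial
#'
#' Applies the trial-level filters to a detected saccade (or a gaze trace):
#' trials with no detected saccade are excluded; saccadic latencies below
#' `rt_bounds[1]` ms are rejected as anticipations and above `rt_bounds[2]` ms
#' as delays (bounds inclusive for kept trials). Directional correctness is
#' saccade direction equal to the instructed cue direction.
#'
#' @param x A `saccade_event`, `NULL` (no saccade), or a [gaze_trace()]
#'   (in which case [detect_first_saccade()] is run with `...` passed on).
#' @param cue_direction `"left"` or `"right"`.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param character Model/character label for the block.
#' @param participant_id,group Observer identifiers.
#' @param rt_bounds Kept-latency bounds in ms (default `c(100, 500)`).
#' @param ... Passed to [detect_first_saccade()] when `x` is a trace.
#' @return One-row data frame with the trial design cell, `rt_ms`, `correct`
#'   and `status` (`kept`, `excluded_no_saccade`, `rejected_anticipation`,
#'   `rejected_delay`).
#' @export
score_trial <- function(x, cue_direction, congruency, character = NA_character_,
                        participant_id = NA_character_, group = NA_character_,
                        rt_bounds = c(100, 500), ...) {
  stopifnot(cue_direction %in% c("left", "right"),
            congruency %in% c("congruent", "incongruent"),
            length(rt_bounds) == 2L, rt_bounds[1L] <= rt_bounds[2L])
  if (inherits(x, "gaze_trace")) x <- detect_first_saccade(x, ...)
  if (is.null(x)) {
    rt <- NA_real_; dir <- NA_character_
  } else {
    rt <- x$onset_ms; dir <- x$direction
  }
  status <- if (is.na(rt)) "excluded_no_saccade"
            else if (rt < rt_bounds[1L]) "rejected_anticipation"
            else if (rt > rt_bounds[2L]) "rejected_delay"
            else "kept"
  data.frame(participant_id = participant_id, group = group,
             character = character, cue_direction = cue_direction,
             congruency = congruency, rt_ms = rt,
             direction = dir,
             correct = if (is.na(dir)) NA else dir == cue_direction,
             status = status, stringsAsFactors = FALSE)
}

#' Score a table of trials
#'
#' Vectorised trial scoring for a trial table that already carries a detected
#' (or absent) saccade per row, e.g. the output of [generate_cohort()].
#' Assigns `status` and `correct` using the same filter rules as
#' [score_trial()].
#'
#' @param trials Data frame with columns `cue_direction`, `direction`
#'   (NA when no saccade) and `rt_ms` (NA when no saccade).
#' @param rt_bounds Kept-latency bounds in ms (default `c(100, 500)`).
#' @return The input with `correct` and `status` columns (re)computed.
#' @export
score_trials <- function(trials, rt_bounds = c(100, 500)) {
  stopifnot(is.data.frame(trials),
            all(c("cue_direction", "direction", "rt_ms") %in% names(trials)))
  rt <- trials$rt_ms
  status <- ifelse(is.na(rt), "excluded_no_saccade",
            ifelse(rt < rt_bounds[1L], "rejected_anticipation",
            ifelse(rt > rt_bounds[2L], "rejected_delay", "kept")))
  trials$correct <- ifelse(is.na(trials$direction), NA,
                           trials$direction == trials$cue_direction)
  trials$status <- status
  trials
}

#' Summarise trial-level filtering
#'
#' Counts trials by exclusion status. Anticipation/delay rejection rates are
#' reported against two denominators: all trials, and only the trials with a
#' detected saccade (the eligible set), since published totals are ambiguous
#' about which convention they use.
#'
#' @param trials A scored trial table (see [score_trials()]).
#' @return A list of class `filter_summary` with a per-status count table and
#'   the headline percentages.
#' @export
filter_summary <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L, "status" %in% names(trials))
  lv <- c("kept", "excluded_no_saccade", "rejected_anticipation", "rejected_delay")
  counts <- table(factor(trials$status, levels = lv))
  n <- nrow(trials)
  tab <- data.frame(status = lv, n = as.integer(counts),
                    pct_total = 100 * as.integer(counts) / n)
  n_detected <- n - tab$n[tab$status == "excluded_no_saccade"]
  n_rejected <- sum(tab$n[tab$status %in% c("rejected_anticipation", "rejected_delay")])
  out <- list(
    table = tab,
    n_total = n,
    pct_no_saccade = 100 * tab$n[tab$status == "excluded_no_saccade"] / n,
    pct_rejected_of_total = 100 * n_rejected / n,
    pct_rejected_of_detected = if (n_detected > 0) 100 * n_rejected / n_detected else NA_real_)
  class(out) <- "filter_summary"
  out
}

#' @export
print.filter_summary <- function(x, ...) {
  cat("Trial filtering summary\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("no-saccade: %.1f%% of total; anticipation/delay: %.1f%% of total (%.1f%% of detected)\n",
              x$pct_no_saccade, x$pct_rejected_of_total, x$pct_rejected_of_detected))
  invisible(x)
}

#' Read gaze traces from a delimited text file
#'
#' Expects columns `trial_id`, `t_ms`, `x_deg` and a `cue_onset_ms` column
#' (constant within trial) or a single `cue_onset_ms` argument.
#'
#' @param path CSV file path.
#' @param cue_onset_ms Cue onset used for all trials when the file has no
#'   `cue_onset_ms` column.
#' @return Named list of [gaze_trace()] objects, one per `trial_id`.
#' @export
read_traces <- function(path, cue_onset_ms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "t_ms", "x_deg") %in% names(df)))
  lapply(split(df, df$trial_id), function(d) {
    cue <- if (!is.null(cue_onset_ms)) cue_onset_ms else d$cue_onset_ms[1L]
    gaze_trace(d$t_ms, d$x_deg, cue)
  })
}
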