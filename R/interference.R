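#' Accuracy interference for one congruency cell pair
#'
#' Interference of the model's gaze on response accuracy: percentage of
#' correct responses on kept congruent trials minus percentage correct on
#' kept incongruent trials (positive = the gaze helped when congruent /
#' hurt when incongruent).
#'
#' @param trials Scored trial table for one participant-character block (or
#'   any trial subset), with columns `congruency`, `correct`, `status`.
#' @return Interference in percentage points, or `NA` if either congruency
#'   condition has no kept trial.
#' @export
interference_accuracy <- function(trials) {
  k <- trials[trials$status == "kept", ]
  pc <- k$correct[k$congruency == "congruent"]
  pi <- k$correct[k$congruency == "incongruent"]
  if (length(pc) == 0L || length(pi) == 0L) return(NA_real_)
  100 * (mean(pc) - mean(pi))
}

#' Saccadic RT interference for one congruency cell pair
#'
#' Mean saccadic latency on kept, correct incongruent trials minus mean
#' latency on kept, correct congruent trials (positive = incongruent slower,
#' i.e. the gaze captured the eyes).
#'
#' @inheritParams interference_accuracy
#' @return Interference in ms, or `NA` if either condition has no kept
#'   correct trial.
#' @export
interference_rt <- function(trials) {
  k <- trials[trials$status == "kept" & !is.na(trials$correct) & trials$correct, ]
  rc <- k$rt_ms[k$congruency == "congruent"]
  ri <- k$rt_ms[k$congruency == "incongruent"]
  if (length(rc) == 0L || length(ri) == 0L) return(NA_real_)
  mean(ri) - mean(rc)
}

#' Per-participant, per-character interference table
#'
#' Computes the accuracy and RT interference indices for every
#' participant-by-character cell of a scored trial table.
#'
#' @param trials Scored trial table (see [score_trials()]).
#' @return Data frame of class `interference_table` with one row per
#'   participant-character cell: `acc_interference` (percentage points),
#'   `rt_interference` (ms) and kept/correct trial counts. Cells with an
#'   empty condition are `NA`, never zero.
#' @export
interference_table <- function(trials) {
  stopifnot(all(c("participant_id", "group", "character", "congruency",
                  "correct", "status", "rt_ms") %in% names(trials)))
  cells <- unique(trials[, c("participant_id", "group", "character")])
  cells <- cells[order(cells$participant_id, cells$character), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- trials[trials$participant_id == cells$participant_id[i] &
                 trials$character == cells$character[i], ]
    k <- tr[tr$status == "kept", ]
    data.frame(
      cells[i, ],
      acc_interference = interference_accuracy(tr),
      rt_interference = interference_rt(tr),
      n_kept_congruent = sum(k$congruency == "congruent"),
      n_kept_incongruent = sum(k$congruency == "incongruent"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("interference_table", "data.frame")
  out
}

#' Exclude outlying participants from an interference table
#'
#' A participant is removed when, in any single character condition, their
#' interference index lies more than `k_sd` standard deviations (n-1
#' denominator) from the mean of their reference set for that condition.
#' Means and SDs are computed on the original table in a single pass (no
#' iterative re-screening). Conditions with zero variance exclude no one.
#'
#' @param table An [interference_table()] (or any data frame with
#'   `participant_id`, `group`, `character` and the measure column).
#' @param k_sd SD multiplier (default 3).
#' @param measure Which index to screen: `"acc_interference"` or
#'   `"rt_interference"`.
#' @param scope Reference set for the mean/SD: the participant's own group
#'   (default, `"group"`) or the whole sample (`"sample"`).
#' @return List with `table` (rows of excluded participants removed),
#'   `excluded` (participant ids) and `flags` (the offending cells).
#' @export
exclude_outlier_participants <- function(table, k_sd = 3,
                                         measure = c("acc_interference", "rt_interference"),
                                         scope = c("group", "sample")) {
  measure <- match.arg(measure)
  scope <- match.arg(scope)
  stopifnot(measure %in% names(table))
  v <- table[[measure]]
  ref <- if (scope == "group") interaction(table$group, table$character)
         else factor(table$character)
  m <- stats::ave(v, ref, FUN = function(z) mean(z, na.rm = TRUE))
  s <- stats::ave(v, ref, FUN = function(z) stats::sd(z, na.rm = TRUE))
  flag <- !is.na(v) & !is.na(s) & s > 0 & abs(v - m) > k_sd * s
  excluded <- unique(table$participant_id[flag])
  list(table = table[!table$participant_id %in% excluded, , drop = FALSE],
       excluded = excluded,
       flags = table[flag, c("participant_id", "group", "character", measure),
                     drop = FALSE])
}

#' Write an interference table as CSV
#'
#' @param table An [interference_table()].
#' @param path Output file.
#' @param shape `"long"` (one row per participant-character) or `"wide"`
#'   (one row per participant, one column pair per character).
#' @export
write_interference <- function(table, path, shape = c("long", "wide")) {
  shape <- match.arg(shape)
  if (shape == "wide") {
    acc <- stats::reshape(
      table[, c("participant_id", "group", "character", "acc_interference")],
      idvar = c("participant_id", "group"), timevar = "character",
      direction = "wide")
    table <- acc
  }
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
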