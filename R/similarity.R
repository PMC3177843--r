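.check_profile <- function(p, integer_grid = TRUE, what = "profile") {
  if (length(p) != 25L)
    stop(sprintf("%s must have exactly 25 items", what))
  if (any(!is.finite(p)) || any(p < 1) || any(p > 5))
    stop(sprintf("%s ratings must lie in [1, 5]", what))
  if (integer_grid && any(p != round(p)))
    stop(sprintf("%s ratings must be integers in 1..5", what))
  invisible(p)
}

#' Emotion-positivity index
#'
#' Positive-emotion rating minus negative-emotion rating for one character,
#' each on the 1-5 scale; the index therefore lies in \[-4, 4\], negative
#' values meaning negative emotions predominate.
#'
#' @param pos,neg Integer ratings in 1..5 (vectorised).
#' @return `pos - neg`.
#' @export
emotion_positivity <- function(pos, neg) {
  if (any(!pos %in% 1:5) || any(!neg %in% 1:5))
    stop("emotion ratings must be integers in 1..5")
  pos - neg
}

#' Perceived personality similarity between a rater and a character
#'
#' Per item, the distance between the self rating and the character rating is
#' the Euclidean distance computed item-wise, i.e. `sqrt((a-b)^2) = |a-b|`.
#' The summed distance is normalised by its maximum (25 items x maximum
#' distance 4 = 100) to give a dissimilarity in \[0, 1\]; similarity is one
#' minus that, so 1 means identical profiles and 0 maximal difference on
#' every item.
#'
#' @param self_profile,char_profile Vectors of 25 integer ratings in 1..5.
#'   If named, the item names must align.
#' @return Similarity score in \[0, 1\].
#' @export
perceived_similarity <- function(self_profile, char_profile) {
  .check_profile(self_profile, what = "self profile")
  .check_profile(char_profile, what = "character profile")
  if (!is.null(names(self_profile)) && !is.null(names(char_profile)) &&
      !identical(names(self_profile), names(char_profile)))
    stop("profile item keys are misaligned")
  1 - sum(abs(self_profile - char_profile)) / 100
}

#' Objective personality similarity against a sample consensus
#'
#' Same formula as [perceived_similarity()], but the individual's character
#' ratings are replaced by the consensus profile (the per-item mean rating of
#' the character across the whole sample). Consensus items are real-valued;
#' per-item distances are capped at 4 before summation.
#'
#' @param self_profile Vector of 25 integer ratings in 1..5.
#' @param consensus Vector of 25 real-valued consensus means in \[1, 5\]
#'   (see [consensus_profile()]).
#' @return Similarity score in \[0, 1\].
#' @export
objective_similarity <- function(self_profile, consensus) {
  .check_profile(self_profile, what = "self profile")
  .check_profile(consensus, integer_grid = FALSE, what = "consensus profile")
  1 - sum(pmin(4, abs(self_profile - consensus))) / 100
}

#' Per-item consensus profile of a character
#'
#' Averages, across all raters in the sample (both groups, self-rater
#' included), the 25 item ratings given to one character.
#'
#' @param ratings Long ratings table (`participant_id`, `target`, `item`,
#'   `rating`).
#' @param character Character label to aggregate.
#' @return Named numeric vector of 25 item means.
#' @export
consensus_profile <- function(ratings, character) {
  r <- ratings[ratings$target == character, ]
  if (nrow(r) == 0L) stop("no ratings found for character ", character)
  if (length(unique(r$participant_id)) < 2L)
    stop("consensus requires ratings from at least 2 raters")
  out <- tapply(r$rating, r$item, mean)
  # preserve the item order of the first rater
  first <- r$item[r$participant_id == r$participant_id[1L]]
  as.numeric(out[first]) -> v
  names(v) <- first
  v
}

#' Similarity and emotion score table
#'
#' Computes, for every participant-character pair, the perceived similarity,
#' the objective similarity (against the sample consensus profile) and the
#' emotion-positivity index.
#'
#' @param ratings Long profile ratings table (`participant_id`, `target`
#'   = "self" or a character label, `item`, `rating`).
#' @param character_ratings Optional table with `participant_id`,
#'   `character`, `positive`, `negative` for the emotion index.
#' @return Data frame with columns `participant_id`, `character`,
#'   `perceived`, `objective` and (if available) `emotion_positivity`.
#' @export
similarity_table <- function(ratings, character_ratings = NULL) {
  stopifnot(all(c("participant_id", "target", "item", "rating") %in% names(ratings)))
  chars <- setdiff(unique(ratings$target), "self")
  ids <- unique(ratings$participant_id)
  cons <- lapply(chars, function(ch) consensus_profile(ratings, ch))
  names(cons) <- chars
  rows <- list()
  for (id in ids) {
    rp <- ratings[ratings$participant_id == id, ]
    self <- rp$rating[rp$target == "self"]
    if (length(self) != 25L) next
    for (ch in chars) {
      cp <- rp$rating[rp$target == ch]
      if (length(cp) != 25L) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = id, character = ch,
        perceived = perceived_similarity(self, cp),
        objective = objective_similarity(self, cons[[ch]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(character_ratings)) {
    e <- character_ratings
    e$emotion_positivity <- emotion_positivity(e$positive, e$negative)
    out <- merge(out, e[, c("participant_id", "character", "emotion_positivity")],
                 by = c("participant_id", "character"), all.x = TRUE, sort = FALSE)
  }
  out[order(out$participant_id, out$character), ]
}
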