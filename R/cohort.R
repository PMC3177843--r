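#' Big-Five adjective markers
#'
#' The 25 adjective markers (5 per factor) used for the self and character
#' personality profiles: Energy/Extraversion, Agreeableness,
#' Conscientiousness, Emotional stability, Openness.
#'
#' @format Character vector of length 25, names give the factor.
#' @export
big_five_adjectives <- c(
  energy          = "happy",      energy          = "determined",
  energy          = "dynamic",    energy          = "energetic",
  energy          = "active",
  agreeableness   = "cordial",    agreeableness   = "generous",
  agreeableness   = "loyal",      agreeableness   = "sincere",
  agreeableness   = "unselfish",
  conscientiousness = "efficient", conscientiousness = "scrupulous",
  conscientiousness = "precise",  conscientiousness = "conscientious",
  conscientiousness = "diligent",
  stability       = "optimistic", stability       = "self-confident",
  stability       = "solid",      stability       = "relaxed",
  stability       = "calm",
  openness        = "sharp",      openness        = "creative",
  openness        = "innovative", openness        = "modern",
  openness        = "informed")

.default_characters <- c("DiPietro", "Prodi", "Berlusconi", "Vespa")
.default_groups <- c("left", "right")

# default accuracy-interference targets (percentage points), group x character;
# for non-standard designs a flat moderate interference is assumed
.default_acc_targets <- function(characters = .default_characters,
                                 groups = .default_groups) {
  if (length(characters) == 4L && length(groups) == 2L) {
    m <- rbind(c(10.0, 9.0, 2.1, 5.2),
               c(8.7, 4.0, 18.3, 17.4))
  } else {
    m <- matrix(8, length(groups), length(characters))
  }
  dimnames(m) <- list(groups, characters)
  m
}

# default emotion-positivity (positive minus negative) means and SDs
.default_emotion_means <- function(characters = .default_characters,
                                   groups = .default_groups) {
  if (length(characters) == 4L && length(groups) == 2L) {
    m <- rbind(c(1.4, 0.3, -3.1, -2.3),
               c(-0.2, -2.2, 1.5, 0.2))
  } else {
    m <- matrix(0, length(groups), length(characters))
  }
  dimnames(m) <- list(groups, characters)
  m
}
.default_emotion_sds <- function(characters = .default_characters,
                                 groups = .default_groups) {
  if (length(characters) == 4L && length(groups) == 2L) {
    m <- rbind(c(1.9, 2.3, 1.4, 1.8),
               c(2.2, 2.0, 2.0, 1.2))
  } else {
    m <- matrix(2, length(groups), length(characters))
  }
  dimnames(m) <- list(groups, characters)
  m
}

#' Configure a synthetic gaze-cueing cohort
#'
#' Defines the design and the stochastic structure of a synthetic experiment:
#' two observer groups, four model characters presented in separate blocks,
#' and per block a balanced 2 (cue direction) x 2 (congruency) factorial with
#' `reps_per_cell` repetitions. Directional-error probabilities carry the
#' group-by-character interference structure; trial losses (no detectable
#' saccade, anticipations, delays) and rating tables are generated with
#' tunable parameters.
#'
#' @param n_per_group Named integer vector of group sizes
#'   (default `c(left = 15, right = 13)`).
#' @param characters Ordered character labels for the four blocks.
#' @param reps_per_cell Repetitions per design cell per block (default 12,
#'   i.e. 48 trials per block).
#' @param soa_ms Gaze-cue to imperative-cue stimulus onset asynchrony (ms).
#' @param err_prob 3-d array `[group, character, congruency]` of directional
#'   error probabilities (each in \[0, 0.5\]). Default: 0.05 on congruent
#'   trials and 0.05 plus the group-by-character interference target (in
#'   proportion units) on incongruent trials.
#' @param acc_targets Group x character matrix of accuracy-interference
#'   targets in percentage points, used to build the default `err_prob`.
#' @param rt_model List with `shift_ms`, `meanlog`, `sdlog` (shifted lognormal
#'   latency) and `incongruent_shift_ms` (congruency cost added to the shift).
#' @param p_no_saccade,p_anticipation,p_delay Marginal probabilities that a
#'   trial has no detectable saccade, an anticipatory latency (< 100 ms) or a
#'   delayed latency (> 500 ms).
#' @param subject_sd SD (probability scale) of the participant-level random
#'   shift of the incongruent error rate, shared across characters.
#' @param cell_sd SD (probability scale) of the participant-by-character
#'   random shift of the incongruent error rate.
#' @param rt_subject_sd SD (ms) of the participant-level latency shift.
#' @param similarity_coupling Correlation, in \[-1, 1\], between a
#'   participant's perceived similarity to a character and the interference
#'   injected for that participant-character cell.
#' @param similarity_mean,similarity_sd Location and spread of the perceived
#'   similarity targets on the \[0, 1\] scale.
#' @param missing_ratings Number of participants whose questionnaire tables
#'   are dropped (default 0; complete data).
#' @param seed Integer seed recorded in the configuration and used by
#'   [generate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(left = 15L, right = 13L),
                          characters = .default_characters,
                          reps_per_cell = 12L,
                          soa_ms = 75,
                          err_prob = NULL,
                          acc_targets = NULL,
                          rt_model = list(shift_ms = 150, meanlog = log(105),
                                          sdlog = 0.25, incongruent_shift_ms = 33),
                          p_no_saccade = 0.135,
                          p_anticipation = 0.017,
                          p_delay = 0.017,
                          subject_sd = 0.09,
                          cell_sd = 0.04,
                          rt_subject_sd = 25,
                          similarity_coupling = 0.5,
                          similarity_mean = 0.67,
                          similarity_sd = 0.08,
                          missing_ratings = 0L,
                          seed = 1L) {
  if (length(n_per_group) < 1L || any(n_per_group < 1L))
    stop("invalid configuration field 'n_per_group': need positive group sizes")
  if (is.null(names(n_per_group)))
    names(n_per_group) <- .default_groups[seq_along(n_per_group)]
  if (length(characters) < 2L)
    stop("invalid configuration field 'characters': need at least 2 labels")
  if (reps_per_cell < 1L)
    stop("invalid configuration field 'reps_per_cell'")
  for (f in c("p_no_saccade", "p_anticipation", "p_delay")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("invalid configuration field '%s': must be a probability", f))
  }
  if (p_no_saccade + p_anticipation + p_delay >= 1)
    stop("trial-loss probabilities must sum to less than 1")
  if (is.null(acc_targets)) {
    acc_targets <- .default_acc_targets(characters, names(n_per_group))
  }
  if (is.null(err_prob)) {
    err_prob <- array(0.05, dim = c(length(n_per_group), length(characters), 2L),
                      dimnames = list(names(n_per_group), characters,
                                      c("congruent", "incongruent")))
    err_prob[, , "incongruent"] <- 0.05 + acc_targets / 100
  }
  if (any(err_prob < 0) || any(err_prob > 0.5))
    stop("invalid configuration field 'err_prob': entries must lie in [0, 0.5]")
  if (abs(similarity_coupling) > 1)
    stop("invalid configuration field 'similarity_coupling': must lie in [-1, 1]")
  cfg <- list(n_per_group = n_per_group, characters = characters,
              reps_per_cell = as.integer(reps_per_cell), soa_ms = soa_ms,
              err_prob = err_prob, rt_model = rt_model,
              p_no_saccade = p_no_saccade, p_anticipation = p_anticipation,
              p_delay = p_delay, subject_sd = subject_sd, cell_sd = cell_sd,
              rt_subject_sd = rt_subject_sd,
              similarity_coupling = similarity_coupling,
              similarity_mean = similarity_mean, similarity_sd = similarity_sd,
              missing_ratings = as.integer(missing_ratings),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: groups [%s], %d characters x %d trials/block, seed %d\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "),
              length(x$characters), 4L * x$reps_per_cell, x$seed))
  invisible(x)
}

# integer ratings 1..5 from a discretised normal
.discrete_rating <- function(n, mean, sd) {
  pmin(5L, pmax(1L, as.integer(round(stats::rnorm(n, mean, sd)))))
}

# build a character profile at integer city-block distance D from `self`
.profile_at_distance <- function(self, D) {
  cap_up <- 5L - self
  cap_dn <- self - 1L
  cap <- pmax(cap_up, cap_dn)
  D <- min(D, sum(cap))
  d <- integer(length(self))
  while (D > 0L) {
    open <- which(d < cap)
    i <- if (length(open) == 1L) open else sample(open, 1L)
    d[i] <- d[i] + 1L
    D <- D - 1L
  }
  out <- self
  for (i in which(d > 0L)) {
    up_ok <- d[i] <= cap_up[i]
    dn_ok <- d[i] <= cap_dn[i]
    s <- if (up_ok && dn_ok) sample(c(1L, -1L), 1L) else if (up_ok) 1L else -1L
    out[i] <- self[i] + s * d[i]
  }
  out
}

# map an integer positivity differential d in [-4, 4] to (positive, negative)
.emotion_pair <- function(d) {
  pos <- 3L + as.integer(ceiling(d / 2))
  neg <- 3L - as.integer(floor(d / 2))
  cbind(positive = pmin(5L, pmax(1L, pos)), negative = pmin(5L, pmax(1L, neg)))
}

#' Generate a complete synthetic gaze-cueing experiment
#'
#' Draws a full dataset with the configured statistical structure: balanced
#' trial cells before stochastic losses, congruency-dependent directional
#' errors carrying a group-by-character interference pattern plus participant
#' and participant-by-character heterogeneity, shifted-lognormal latencies,
#' and questionnaire tables (self/character Big-Five profiles, emotion,
#' exposure and influence ratings) in which perceived similarity is coupled
#' to the injected interference at approximately `similarity_coupling`.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `cohort` with data frames `participants`,
#'   `trials` (unscored; see [score_trials()]), `ratings` (long profile
#'   table), `character_ratings` (emotion/exposure/influence), the diagnostic
#'   `injected` table (true per-cell error rates and injected interference)
#'   and a `provenance` record (seed and config echo).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(seed)
  groups <- names(config$n_per_group)
  chars <- config$characters
  n_tot <- sum(config$n_per_group)
  ids <- sprintf("P%02d", seq_len(n_tot))
  grp <- rep(groups, config$n_per_group)
  participants <- data.frame(participant_id = ids, group = grp,
                             stringsAsFactors = FALSE)

  # participant-level and participant-by-character interference heterogeneity
  subj_re <- stats::rnorm(n_tot, 0, config$subject_sd)
  cell_re <- matrix(stats::rnorm(n_tot * length(chars), 0, config$cell_sd),
                    n_tot, length(chars), dimnames = list(ids, chars))
  rt_subj <- stats::rnorm(n_tot, 0, config$rt_subject_sd)

  inj <- expand.grid(participant_id = ids, character = chars,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inj$group <- grp[match(inj$participant_id, ids)]
  e_cong <- config$err_prob[cbind(inj$group, inj$character, "congruent")]
  e_inc0 <- config$err_prob[cbind(inj$group, inj$character, "incongruent")]
  e_inc <- pmin(0.6, pmax(0, e_inc0 +
                subj_re[match(inj$participant_id, ids)] +
                cell_re[cbind(inj$participant_id, inj$character)]))
  inj$err_congruent <- e_cong
  inj$err_incongruent <- e_inc
  inj$injected_interference <- 100 * (e_inc - e_cong)

  # ---- trials -------------------------------------------------------------
  reps <- config$reps_per_cell
  cell <- expand.grid(cue_direction = c("left", "right"),
                      congruency = c("congruent", "incongruent"),
                      rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_block <- nrow(cell)                      # 2 x 2 x reps
  blocks <- inj[order(match(inj$participant_id, ids), match(inj$character, chars)), ]
  trial_list <- vector("list", nrow(blocks))
  rtm <- config$rt_model
  for (b in seq_len(nrow(blocks))) {
    ord <- sample.int(n_block)
    d <- cell[ord, c("cue_direction", "congruency")]
    pid <- blocks$participant_id[b]
    pidx <- match(pid, ids)
    err_p <- ifelse(d$congruency == "congruent",
                    blocks$err_congruent[b], blocks$err_incongruent[b])
    u <- stats::runif(n_block)
    kind <- ifelse(u < config$p_no_saccade, "none",
            ifelse(u < config$p_no_saccade + config$p_anticipation, "anticipation",
            ifelse(u < config$p_no_saccade + config$p_anticipation + config$p_delay,
                   "delay", "kept")))
    shift <- rtm$shift_ms + rt_subj[pidx] +
             ifelse(d$congruency == "incongruent", rtm$incongruent_shift_ms, 0)
    rt <- shift + stats::rlnorm(n_block, rtm$meanlog, rtm$sdlog)
    # keep nominal latencies inside the analysis window
    bad <- kind == "kept" & (rt < 100 | rt > 500)
    while (any(bad)) {
      rt[bad] <- shift[bad] + stats::rlnorm(sum(bad), rtm$meanlog, rtm$sdlog)
      bad <- kind == "kept" & (rt < 100 | rt > 500)
    }
    rt[kind == "anticipation"] <- stats::runif(sum(kind == "anticipation"), 40, 95)
    rt[kind == "delay"] <- stats::runif(sum(kind == "delay"), 505, 900)
    rt[kind == "none"] <- NA_real_
    err <- stats::runif(n_block) < err_p
    dir <- ifelse(err, ifelse(d$cue_direction == "left", "right", "left"),
                  d$cue_direction)
    dir[kind == "none"] <- NA_character_
    trial_list[[b]] <- data.frame(
      participant_id = pid, group = blocks$group[b],
      character = blocks$character[b], block = match(blocks$character[b], chars),
      trial = seq_len(n_block), cue_direction = d$cue_direction,
      congruency = d$congruency, rt_ms = rt, direction = dir,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL

  # ---- ratings ------------------------------------------------------------
  # latent similarity coupled to the injected interference
  z <- inj$injected_interference
  z <- if (stats::sd(z) > 0) as.numeric(scale(z)) else rep(0, length(z))
  cc <- config$similarity_coupling
  latent <- cc * z + sqrt(max(0, 1 - cc^2)) * stats::rnorm(length(z))
  sim_target <- pmin(0.98, pmax(0.05, config$similarity_mean +
                                config$similarity_sd * latent))
  inj$similarity_target <- sim_target

  items <- unname(big_five_adjectives)
  rating_rows <- vector("list", n_tot * (1L + length(chars)))
  k <- 0L
  for (p in seq_len(n_tot)) {
    self <- .discrete_rating(25L, 3.4, 0.9)
    k <- k + 1L
    rating_rows[[k]] <- data.frame(participant_id = ids[p], target = "self",
                                   item = items, rating = self,
                                   stringsAsFactors = FALSE)
    for (ch in chars) {
      s <- inj$similarity_target[inj$participant_id == ids[p] & inj$character == ch]
      prof <- .profile_at_distance(self, as.integer(round(100 * (1 - s))))
      k <- k + 1L
      rating_rows[[k]] <- data.frame(participant_id = ids[p], target = ch,
                                     item = items, rating = prof,
                                     stringsAsFactors = FALSE)
    }
  }
  ratings <- do.call(rbind, rating_rows)

  emo_m <- .default_emotion_means(chars, groups)
  emo_s <- .default_emotion_sds(chars, groups)
  influence_m <- c(DiPietro = 2.6, Prodi = 3.6, Berlusconi = 1.4, Vespa = 3.1)
  exposure_m <- c(DiPietro = 2.0, Prodi = 2.2, Berlusconi = 1.5, Vespa = 2.5)
  cr <- expand.grid(participant_id = ids, character = chars,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cr$group <- grp[match(cr$participant_id, ids)]
  gi <- cbind(match(cr$group, rownames(emo_m)), match(cr$character, colnames(emo_m)))
  dtar <- emo_m[gi] + stats::rnorm(nrow(cr)) * emo_s[gi]
  pn <- .emotion_pair(as.integer(round(pmin(4, pmax(-4, dtar)))))
  cr$positive <- pn[, "positive"]
  cr$negative <- pn[, "negative"]
  im <- influence_m[cr$character]; em <- exposure_m[cr$character]
  im[is.na(im)] <- 2.5; em[is.na(em)] <- 2.0
  cr$influence <- .discrete_rating(nrow(cr), im, 0.9)
  cr$exposure <- .discrete_rating(nrow(cr), em, 0.9)

  if (config$missing_ratings > 0L) {
    drop <- sample(ids, config$missing_ratings)
    ratings <- ratings[!ratings$participant_id %in% drop, ]
    cr <- cr[!cr$participant_id %in% drop, ]
  }

  out <- list(participants = participants, trials = trials, ratings = ratings,
              character_ratings = cr, injected = inj,
              provenance = list(seed = seed, config = config))
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%s), %d trials, seed %d\n",
              nrow(x$participants),
              paste(sprintf("%s=%d", names(x$provenance$config$n_per_group),
                            x$provenance$config$n_per_group), collapse = ", "),
              nrow(x$trials), x$provenance$seed))
  invisible(x)
}

#' Write a synthetic dataset as delimited text
#'
#' Writes the participants, trials, ratings and character-ratings tables as
#' CSV files plus a JSON provenance record (seed and configuration echo).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("participants", "trials", "ratings", "character_ratings")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(cohort[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  prov <- cohort$provenance
  prov$config <- unclass(prov$config)
  prov$config$err_prob <- as.vector(prov$config$err_prob)  # flattened echo
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, p))
}

#' Generate a synthetic gaze trace for one trial
#'
#' Produces fixation noise around zero followed by a constant-velocity ramp
#' of the requested amplitude and direction starting at the requested latency
#' after cue onset. Ramp duration follows the saccadic main sequence
#' (approximately `2.2 * amplitude + 21` ms).
#'
#' @param rt_ms Target saccade latency relative to cue onset (ms).
#' @param amplitude_deg Saccade amplitude in degrees (0 for no saccade).
#' @param direction `"left"` or `"right"`.
#' @param sampling_hz Sampling rate in Hz (default 240).
#' @param cue_onset_ms Cue time within the trace (default 200 ms).
#' @param duration_ms Total trace duration (default `cue_onset_ms + 700`).
#' @param noise_sd Fixation/position noise SD in degrees (default 0.1).
#' @return A [gaze_trace()].
#' @export
generate_trace <- function(rt_ms, amplitude_deg, direction = c("right", "left"),
                           sampling_hz = 240, cue_onset_ms = 200,
                           duration_ms = cue_onset_ms + 700, noise_sd = 0.1) {
  direction <- match.arg(direction)
  if (sampling_hz <= 0) stop("sampling_hz must be positive")
  if (amplitude_deg < 0) stop("amplitude_deg must be nonnegative")
  onset <- cue_onset_ms + rt_ms
  if (onset < 0 || onset > duration_ms)
    stop("rt_ms places the saccade outside the trace span")
  t <- seq(0, duration_ms, by = 1000 / sampling_hz)
  x <- numeric(length(t))
  if (amplitude_deg > 0) {
    dur <- 2.2 * amplitude_deg + 21
    s <- if (direction == "left") -1 else 1
    ramp <- pmin(1, pmax(0, (t - onset) / dur))
    x <- s * amplitude_deg * ramp
  }
  x <- x + stats::rnorm(length(t), 0, noise_sd)
  gaze_trace(t, x, cue_onset_ms)
}
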