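# independent split-plot oracle via stats::aov error strata
aov_splitplot_oracle <- function(y, group) {
  N <- nrow(y); b <- ncol(y)
  d <- data.frame(v = as.vector(y),
                  s = factor(rep(seq_len(N), b)),
                  g = factor(rep(group, b)),
                  c = factor(rep(seq_len(b), each = N)))
  sm <- summary(stats::aov(v ~ g * c + Error(s / c), data = d))
  s1 <- sm[[1L]][[1L]]   # between stratum: g, residuals
  s2 <- sm[[2L]][[1L]]   # within stratum: c, g:c, residuals
  list(ss = c(group = s1[1L, "Sum Sq"], subj = s1[2L, "Sum Sq"],
              cond = s2[1L, "Sum Sq"], int = s2[2L, "Sum Sq"],
              res = s2[3L, "Sum Sq"]),
       F = c(group = s1[1L, "F value"],
             cond = s2[1L, "F value"], int = s2[2L, "F value"]))
}

# minimal scored-trial rows for index arithmetic tests
make_cell_trials <- function(n_cong_correct, n_cong, n_inc_correct, n_inc,
                             rt_cong = 250, rt_inc = 285) {
  one <- function(congruency, n_corr, n, rt) {
    if (n == 0L) return(NULL)
    data.frame(congruency = congruency,
               correct = rep(c(TRUE, FALSE), c(n_corr, n - n_corr)),
               rt_ms = rt, status = "kept")
  }
  rbind(one("congruent", n_cong_correct, n_cong, rt_cong),
        one("incongruent", n_inc_correct, n_inc, rt_inc))
}

# noiseless constant-velocity ramp trace built directly (not via generator)
make_ramp_trace <- function(rt_ms, amplitude, direction = "right",
                            hz = 240, cue = 200, dur_total = 900,
                            ramp_dur = 40, noise_sd = 0, x0 = 0) {
  t <- seq(0, dur_total, by = 1000 / hz)
  s <- if (direction == "left") -1 else 1
  ramp <- pmin(1, pmax(0, (t - cue - rt_ms) / ramp_dur))
  x <- x0 + s * amplitude * ramp + stats::rnorm(length(t), 0, noise_sd)
  gaze_trace(t, x, cue)
}

# frozen textbook split-plot table: 2 groups x 3 subjects x 4 conditions.
# Hand decomposition (verified independently against aov):
#   SS_group 24 (df 1), SS_subj 16 (df 4), SS_cond 48 (df 3),
#   SS_int 0 (df 3), SS_res 4 (df 12); F = 6, 48, 0.
textbook_y <- rbind(c(5, 5, 8, 6),
                    c(1, 5, 6, 4),
                    c(3, 5, 7, 5),
                    c(6, 8, 10, 8),
                    c(4, 6, 8, 6),
                    c(5, 7, 9, 7))
textbook_group <- rep(c("A", "B"), each = 3)
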