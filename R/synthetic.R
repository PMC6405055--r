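# Synthetic improvisation generator: reproducible sessions with
# controllable session length, start delay, inter-onset timing, note
# durations, octave/velocity placement, black-key preference, cluster
# sizes and idle gaps. Quantities with a lower bound are drawn from
# lower-truncated normal distributions (inverse-CDF truncation, so the
# shape is exact, not clipped).

rtnorm <- function(n, mean, sd, lower = -Inf) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  fa <- stats::pnorm(lower, mean, sd)
  if (fa >= 1) return(rep(lower, n))
  stats::qnorm(fa + stats::runif(n) * (1 - fa), mean, sd)
}

dist3 <- function(x, what) {
  x <- c(x)
  if (!all(c("mean", "sd", "min") %in% names(x)))
    stop(what, " must be c(mean=, sd=, min=)", call. = FALSE)
  if (x["sd"] < 0) stop(what, ": sd must be >= 0", call. = FALSE)
  x
}

# truncated-geometric cluster-size probabilities over 1..12
cluster_size_probs <- function(mean_size = 2.4) {
  stopifnot(mean_size >= 1)
  r <- max(0, 1 - 1 / mean_size)
  p <- r^(0:11)
  p / sum(p)
}

#' A generative profile for synthetic improvisation sessions
#'
#' Holds the distributions the generator draws from. Durations and times
#' are lower-truncated normal `c(mean=, sd=, min=)` in seconds; octave and
#' velocity placement are normal with a center and spread; `p_black` is
#' the probability that a key choice is a black key; `cluster_size` is a
#' probability vector over cluster sizes 1..12 (the number of
#' near-simultaneous onsets per cluster event); idle gaps are inserted
#' after a cluster event with probability `idle_gap_rate`. With
#' `sustain = TRUE` notes are held until the next cluster onset instead of
#' drawing a duration, so a fixed cluster size k yields a concurrency near
#' 100 k %.
#'
#' The defaults emulate a cohort-average improvisation: sessions of about
#' 0.9 min with a few seconds' start delay, around 0.5 s between cluster
#' events, mean note duration under a second, mid-keyboard octave
#' placement, mezzo-forte velocities, a modest black-key share and small
#' clusters.
#'
#' @param session_duration,start_delay,ioi,note_duration Lower-truncated
#'   normal parameters `c(mean=, sd=, min=)`, seconds.
#' @param octave_center,octave_spread Octave placement (octave units).
#' @param velocity_center,velocity_spread Velocity placement (MIDI units).
#' @param p_black Probability of choosing a black key, in `[0, 1]`.
#' @param cluster_size Probability vector over sizes 1..12; default a
#'   truncated geometric with mean about 2.4.
#' @param idle_gap_rate Probability of an idle gap after a cluster event.
#' @param idle_gap_length Gap length distribution, `c(mean=, sd=, min=)`.
#' @param sustain Hold notes until the next cluster onset?
#' @return An object of class `improv_profile`.
#' @export
improv_profile <- function(session_duration = c(mean = 52, sd = 20, min = 10),
                           start_delay = c(mean = 8, sd = 5, min = 0),
                           ioi = c(mean = 0.45, sd = 0.25, min = 0.05),
                           note_duration = c(mean = 0.55, sd = 0.35, min = 0.05),
                           octave_center = 3.6, octave_spread = 1.2,
                           velocity_center = 72, velocity_spread = 18,
                           p_black = 0.16,
                           cluster_size = cluster_size_probs(1.9),
                           idle_gap_rate = 0.04,
                           idle_gap_length = c(mean = 2, sd = 1.5, min = 0.3),
                           sustain = FALSE) {
  prof <- list(session_duration = dist3(session_duration, "session_duration"),
               start_delay = dist3(start_delay, "start_delay"),
               ioi = dist3(ioi, "ioi"),
               note_duration = dist3(note_duration, "note_duration"),
               octave_center = octave_center, octave_spread = octave_spread,
               velocity_center = velocity_center,
               velocity_spread = velocity_spread,
               p_black = p_black,
               cluster_size = cluster_size / sum(cluster_size),
               idle_gap_rate = idle_gap_rate,
               idle_gap_length = dist3(idle_gap_length, "idle_gap_length"),
               sustain = isTRUE(sustain))
  if (p_black < 0 || p_black > 1)
    stop("p_black must be in [0, 1]", call. = FALSE)
  if (idle_gap_rate < 0 || idle_gap_rate > 1)
    stop("idle_gap_rate must be in [0, 1]", call. = FALSE)
  if (length(cluster_size) != 12 || any(cluster_size < 0) ||
      sum(cluster_size) <= 0)
    stop("cluster_size must be 12 non-negative probabilities", call. = FALSE)
  if (prof$start_delay["min"] >= prof$session_duration["min"])
    stop("infeasible profile: minimum start delay >= minimum session duration",
         call. = FALSE)
  if (prof$ioi["min"] <= 0)
    stop("infeasible profile: minimum inter-onset interval must be > 0",
         call. = FALSE)
  structure(prof, class = "improv_profile")
}

#' @export
print.improv_profile <- function(x, ...) {
  cat(sprintf(
    paste0("Improvisation profile: session %.0f s (sd %.0f), start %.1f s, ",
           "IOI %.2f s, note %.2f s,\n  octave %.1f +- %.1f, velocity %.0f ",
           "+- %.0f, p_black %.2f, E[cluster] %.2f, idle rate %.2f%s\n"),
    x$session_duration["mean"], x$session_duration["sd"],
    x$start_delay["mean"], x$ioi["mean"], x$note_duration["mean"],
    x$octave_center, x$octave_spread, x$velocity_center, x$velocity_spread,
    x$p_black, sum(seq_len(12) * x$cluster_size), x$idle_gap_rate,
    if (x$sustain) ", sustained" else ""))
  invisible(x)
}

#' Task-flavoured generator presets
#'
#' Qualitative parameter directions for the four improvisation tasks:
#' "ugly" and "negative" are loud, low-register, black-key-leaning and
#' cluster-heavy; "beautiful" and "positive" are softer, mid-register,
#' white-key-leaning and sparse. The presets encode directions, not fitted
#' parameters.
#'
#' @param task One of `"ugly"`, `"beautiful"`, `"negative"`, `"positive"`.
#' @return An [improv_profile()].
#' @export
improv_preset <- function(task = c("ugly", "beautiful", "negative",
                                   "positive")) {
  task <- match.arg(task)
  switch(task,
    ugly = improv_profile(
      start_delay = c(mean = 14, sd = 8, min = 0),
      ioi = c(mean = 0.45, sd = 0.3, min = 0.05),
      note_duration = c(mean = 1.2, sd = 0.7, min = 0.05),
      octave_center = 2.4, octave_spread = 1.0,
      velocity_center = 95, velocity_spread = 18,
      p_black = 0.30, cluster_size = cluster_size_probs(3.5)),
    beautiful = improv_profile(
      start_delay = c(mean = 9, sd = 5, min = 0),
      ioi = c(mean = 0.55, sd = 0.3, min = 0.05),
      note_duration = c(mean = 0.8, sd = 0.5, min = 0.05),
      octave_center = 4.3, octave_spread = 0.9,
      velocity_center = 58, velocity_spread = 15,
      p_black = 0.10, cluster_size = cluster_size_probs(1.6)),
    negative = improv_profile(
      start_delay = c(mean = 11, sd = 6, min = 0),
      ioi = c(mean = 0.5, sd = 0.3, min = 0.05),
      note_duration = c(mean = 1.1, sd = 0.6, min = 0.05),
      octave_center = 2.6, octave_spread = 1.0,
      velocity_center = 90, velocity_spread = 18,
      p_black = 0.22, cluster_size = cluster_size_probs(3.0)),
    positive = improv_profile(
      start_delay = c(mean = 9, sd = 5, min = 0),
      ioi = c(mean = 0.5, sd = 0.3, min = 0.05),
      note_duration = c(mean = 0.8, sd = 0.5, min = 0.05),
      octave_center = 4.2, octave_spread = 1.0,
      velocity_center = 70, velocity_spread = 15,
      p_black = 0.07, cluster_size = cluster_size_probs(1.9))
  )
}

# one cluster's keys: the color draw is exactly Bernoulli(p_black) per
# member; key collisions inside the cluster are resolved by moving to the
# nearest free octave of the same pitch class, so the color distribution
# is never biased by cluster size
sample_cluster_notes <- function(k, base_octave, p_black, keyboard) {
  notes <- integer(0)
  for (i in seq_len(k)) {
    black <- stats::runif(1) < p_black
    classes <- if (black) BLACK_CLASSES else setdiff(0:11, BLACK_CLASSES)
    pc_try <- sample(classes)
    note <- NA_integer_
    for (shift in c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L)) {
      for (pc in pc_try) {
        cand <- (base_octave + shift + 1L) * 12L + pc
        while (cand < keyboard$lowest_note) cand <- cand + 12L
        while (cand > keyboard$highest_note) cand <- cand - 12L
        if (!(cand %in% notes)) { note <- cand; break }
      }
      if (!is.na(note)) break
    }
    if (!is.na(note)) notes <- c(notes, note)
  }
  notes
}

#' Sample one synthetic improvisation session
#'
#' Reproducible given `(profile, seed)`. Cluster events are emitted along
#' the session clock: each draws a cluster size k and presses k distinct
#' nearby keys near-simultaneously (members spread within 10 ms), with
#' velocities, durations and the advance to the next cluster drawn from
#' the profile.
#'
#' @param profile An [improv_profile()].
#' @param keyboard A [keyboard_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param session_id,participant_id,task,gender,age,proficiency Metadata
#'   for the resulting record.
#' @return A [session_record()] with `t0 = 0` and `t_end` equal to the
#'   drawn session duration.
#' @export
sample_session <- function(profile = improv_profile(),
                           keyboard = keyboard_spec(), seed = NULL,
                           session_id = "synthetic",
                           participant_id = NA, task = NA, gender = NA,
                           age = NA, proficiency = NA) {
  stopifnot(inherits(profile, "improv_profile"))
  if (!is.null(seed)) set.seed(seed)
  p <- profile
  dur <- rtnorm(1, p$session_duration["mean"], p$session_duration["sd"],
                p$session_duration["min"])
  t <- min(rtnorm(1, p$start_delay["mean"], p$start_delay["sd"],
                  p$start_delay["min"]), 0.9 * dur)
  oct_lo <- note_octave(keyboard$lowest_note)
  oct_hi <- note_octave(keyboard$highest_note)
  onset <- numeric(0); offset <- numeric(0)
  note <- integer(0); vel <- integer(0)
  while (t < dur) {
    k <- sample.int(12L, 1L, prob = p$cluster_size)
    base_oct <- round(rtnorm(1, p$octave_center, p$octave_spread, oct_lo))
    base_oct <- min(max(base_oct, oct_lo), oct_hi)
    notes_k <- sample_cluster_notes(k, base_oct, p$p_black, keyboard)
    k <- length(notes_k)
    if (k == 0) break
    ons <- t + c(0, stats::runif(k - 1, 0, 0.010))
    ons <- ons[ons < dur]
    notes_k <- notes_k[seq_along(ons)]
    gap <- max(rtnorm(1, p$ioi["mean"], p$ioi["sd"], p$ioi["min"]), 0.011)
    if (stats::runif(1) < p$idle_gap_rate)
      gap <- gap + rtnorm(1, p$idle_gap_length["mean"],
                          p$idle_gap_length["sd"], p$idle_gap_length["min"])
    t_next <- t + gap
    if (p$sustain) {
      offs <- rep(min(t_next, dur), length(ons))
    } else {
      d <- rtnorm(length(ons), p$note_duration["mean"],
                  p$note_duration["sd"], p$note_duration["min"])
      offs <- pmin(ons + d, dur)
    }
    keep <- offs > ons
    onset <- c(onset, ons[keep]); offset <- c(offset, offs[keep])
    note <- c(note, notes_k[keep])
    v <- round(rtnorm(sum(keep), p$velocity_center, p$velocity_spread, 1))
    vel <- c(vel, pmin(pmax(v, 1L), 127L))
    t <- t_next
  }
  ev <- data.frame(
    time = c(onset, offset),
    kind = rep(c("on", "off"), c(length(onset), length(offset))),
    note = c(note, note),
    velocity = c(vel, rep(NA_integer_, length(offset))))
  session_record(ev, session_id = session_id,
                 participant_id = participant_id, task = task,
                 gender = gender, age = age, proficiency = proficiency,
                 t0 = 0, t_end = dur)
}

#' Sample a labeled synthetic cohort
#'
#' Draws `n_per_group` sessions from each profile in a named list; the
#' profile name becomes the session's task/group label. Per-session seeds
#' are derived deterministically from the master seed, so the cohort is
#' reproducible as a whole.
#'
#' @param n_per_group Sessions per group, `>= 1`.
#' @param profiles Named list of [improv_profile()]s with unique names;
#'   default the four task presets.
#' @param seed Master integer seed.
#' @param keyboard A [keyboard_spec()].
#' @return A [cohort()]; session ids are `<group>_<i>`.
#' @export
sample_cohort <- function(n_per_group,
                          profiles = list(ugly = improv_preset("ugly"),
                                          beautiful = improv_preset("beautiful"),
                                          negative = improv_preset("negative"),
                                          positive = improv_preset("positive")),
                          seed = 1L, keyboard = keyboard_spec()) {
  stopifnot(n_per_group >= 1)
  labels <- names(profiles)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("profiles must be a named list", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate group label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  sessions <- list()
  counter <- 0L
  for (g in seq_along(profiles)) {
    for (i in seq_len(n_per_group)) {
      counter <- counter + 1L
      sessions[[counter]] <- sample_session(
        profiles[[g]], keyboard = keyboard,
        seed = (as.integer(seed) %% 1000000L) * 2000L + counter,
        session_id = sprintf("%s_%03d", labels[g], i),
        participant_id = sprintf("p%03d", i),
        task = labels[g])
    }
  }
  cohort(sessions)
}
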