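# Per-session behavioral parameters of an improvisation: time budget,
# concurrency, key use, dynamics/octave/pitch-class profiles, cluster
# configurations and press-to-press transitions. Quantities that need a
# minimum number of presses are NA ("flagged missing") below that minimum.

first_onset <- function(intervals) {
  if (nrow(intervals) == 0) NA_real_ else min(intervals$onset)
}

#' Time-budget metrics of a session
#'
#' @param session A [session_record()].
#' @return List with `pct_playing_time`, `pct_idle_time`, `start_time_s`,
#'   `pct_start_time`, `total_session_min`. Playing time is the union of
#'   note intervals; idle is its complement; start time is the delay until
#'   the first press (NA for a silent session). Percentages are of the
#'   session duration `t_end - t0`.
#' @export
compute_time_metrics <- function(session) {
  stopifnot(inherits(session, "session_record"))
  st <- session$t_end - session$t0
  if (st <= 0) stop("zero-length session", call. = FALSE)
  iv <- pair_events(session)
  pt <- playing_time(iv)
  pct_playing <- 100 * pt / st
  start_s <- first_onset(iv) - session$t0
  list(pct_playing_time = pct_playing,
       pct_idle_time = 100 - pct_playing,
       start_time_s = start_s,
       pct_start_time = 100 * start_s / st,
       total_session_min = st / 60)
}

#' Concurrent-playing metric
#'
#' The integral of the simultaneously-held-key count divided by the net
#' playing time, as a percentage: 100% when no two notes ever overlap,
#' 200% when two keys are held throughout the playing time, 300% for
#' three, and so on.
#'
#' @param session A [session_record()], or an interval table from
#'   [pair_events()].
#' @return Percentage (`>= 100` whenever anything sounds); NA for a silent
#'   session.
#' @export
compute_concurrent_metric <- function(session) {
  iv <- if (inherits(session, "session_record")) pair_events(session)
        else session
  pt <- playing_time(iv)
  if (pt <= 0) return(NA_real_)
  100 * timeline_integral(held_timeline(iv)) / pt
}

#' Key-use metrics of a session
#'
#' @param session A [session_record()].
#' @param keyboard A [keyboard_spec()].
#' @return List with `n_presses`, `pct_keys_used` (distinct keys over the
#'   keyboard size), `presses_per_key` (presses over distinct keys),
#'   `play_per_key_s` (mean press duration), `pct_black_presses`,
#'   `pct_white_presses`.
#' @export
compute_key_metrics <- function(session, keyboard = keyboard_spec()) {
  iv <- pair_events(session)
  n <- nrow(iv)
  if (n == 0)
    return(list(n_presses = 0L, pct_keys_used = 0,
                presses_per_key = NA_real_, play_per_key_s = NA_real_,
                pct_black_presses = NA_real_, pct_white_presses = NA_real_))
  distinct <- length(unique(iv$note))
  pct_black <- 100 * mean(note_color(iv$note) == "black")
  list(n_presses = n,
       pct_keys_used = 100 * distinct / keyboard$n_keys,
       presses_per_key = n / distinct,
       play_per_key_s = sum(iv$offset - iv$onset) / n,
       pct_black_presses = pct_black,
       pct_white_presses = 100 - pct_black)
}

# duration-weighted (or press-weighted) modal bin; ties -> lowest bin
weighted_mode <- function(values, weights) {
  w <- tapply(weights, values, sum)
  as.numeric(names(w)[which.max(w)])   # which.max takes the first (lowest) tie
}

#' Dynamics, octave and pitch-class profiles of a session
#'
#' Per-press dynamics levels and octave numbers are summarised as the
#' press-weighted mean, the per-press minimum and maximum, and the "most
#' used" value: the modal bin weighted by note-sounding time (the same
#' weighting as the histograms; a press-weighted variant is available via
#' `weight`). Histograms give the percentage of note-sounding time spent
#' in each dynamics level, octave and pitch class; their denominator is the
#' summed note duration, so simultaneous notes each contribute.
#'
#' @param session A [session_record()].
#' @param keyboard A [keyboard_spec()] (sets the octave bins).
#' @param scale A [dynamics_scale()].
#' @param weight `"duration"` (default) or `"press"`: weighting of the
#'   "most used" level/octave.
#' @param octave_offset Octave numbering convention, see [note_octave()].
#' @return List with `intensity_avg`, `intensity_min`, `intensity_max`,
#'   `intensity_most_used`, the octave counterparts, `pitch_class_pct`
#'   (named length-12 vector), `octave_hist` and `intensity_hist`
#'   (percentages summing to 100). All NA for a silent session.
#' @export
compute_profiles <- function(session, keyboard = keyboard_spec(),
                             scale = dynamics_scale(),
                             weight = c("duration", "press"),
                             octave_offset = -1L) {
  weight <- match.arg(weight)
  iv <- pair_events(session)
  octaves <- seq.int(note_octave(keyboard$lowest_note, octave_offset),
                     note_octave(keyboard$highest_note, octave_offset))
  pc_named <- stats::setNames(rep(NA_real_, 12), PITCH_CLASS_NAMES)
  if (nrow(iv) == 0)
    return(list(intensity_avg = NA_real_, intensity_min = NA_integer_,
                intensity_max = NA_integer_, intensity_most_used = NA_integer_,
                octave_avg = NA_real_, octave_min = NA_integer_,
                octave_max = NA_integer_, octave_most_used = NA_integer_,
                pitch_class_pct = pc_named,
                octave_hist = stats::setNames(rep(NA_real_, length(octaves)),
                                              octaves),
                intensity_hist = stats::setNames(rep(NA_real_, 10),
                                                 scale$level_names)))
  lev <- unname(dynamics_level(iv$velocity, scale))
  oct <- note_octave(iv$note, octave_offset)
  pc <- unname(pitch_class(iv$note))
  dur <- iv$offset - iv$onset
  w <- if (weight == "duration") dur else rep(1, length(dur))
  hist_pct <- function(values, bins) {
    h <- tapply(dur, factor(values, levels = bins), sum, default = 0)
    100 * as.numeric(h) / sum(dur)
  }
  list(intensity_avg = mean(lev),
       intensity_min = min(lev), intensity_max = max(lev),
       intensity_most_used = as.integer(weighted_mode(lev, w)),
       octave_avg = mean(oct),
       octave_min = min(oct), octave_max = max(oct),
       octave_most_used = as.integer(weighted_mode(oct, w)),
       pitch_class_pct = stats::setNames(hist_pct(pc, 0:11),
                                         PITCH_CLASS_NAMES),
       octave_hist = stats::setNames(hist_pct(oct, octaves), octaves),
       intensity_hist = stats::setNames(hist_pct(lev, 1:10),
                                        scale$level_names))
}

#' Cluster-configuration metrics of a session
#'
#' A cluster configuration is the instantaneous number of simultaneously
#' held keys. From the positive segments of the held-key timeline:
#' `cluster_instances` counts the maximal constant-count segments,
#' `cluster_max` the largest count, `cluster_mode` the duration-weighted
#' modal count (ties to the smaller count), and `pct_time_cluster_mode`
#' the share of net playing time spent at the modal count.
#'
#' @param session A [session_record()].
#' @return List with the four fields above (zeros/NA for a silent session).
#' @export
compute_cluster_metrics <- function(session) {
  iv <- pair_events(session)
  if (nrow(iv) == 0)
    return(list(cluster_instances = 0L, cluster_max = NA_integer_,
                cluster_mode = NA_integer_, pct_time_cluster_mode = NA_real_))
  tl <- held_timeline(iv)
  pos <- tl$counts >= 1
  seg_dur <- diff(tl$breakpoints)[pos]
  seg_cnt <- tl$counts[pos]
  mode_cnt <- weighted_mode(seg_cnt, seg_dur)
  list(cluster_instances = sum(pos),
       cluster_max = max(seg_cnt),
       cluster_mode = as.integer(mode_cnt),
       pct_time_cluster_mode =
         100 * sum(seg_dur[seg_cnt == mode_cnt]) / sum(seg_dur))
}

#' Press-to-press transition metrics of a session
#'
#' Over the press sequence ordered by `(onset, note)` (optionally chord
#' grouped; a chord is represented by its first member): consecutive
#' velocity pairs are classified crescendo / diminuendo / same intensity;
#' consecutive key-color pairs as white-to-white, white-to-black,
#' black-to-white, black-to-black; and consecutive inter-onset-interval
#' pairs as accelerando (IOI shrinks) or ritardando (IOI grows or is
#' unchanged). All reported as percentages of their pair counts.
#'
#' @param session A [session_record()].
#' @param keyboard A [keyboard_spec()] (interface symmetry).
#' @param chord_window Chord grouping window in seconds; 0 (default)
#'   classifies every press individually.
#' @return List with `pct_crescendo`, `pct_diminuendo`,
#'   `pct_same_intensity`, `pct_ww`, `pct_wb`, `pct_bw`, `pct_bb`,
#'   `pct_accelerando`, `pct_ritardando`. Fields are NA when the session
#'   has fewer presses (or onsets) than the transition needs.
#' @export
compute_transition_metrics <- function(session, keyboard = keyboard_spec(),
                                       chord_window = 0) {
  iv <- pair_events(session)
  sq <- onset_sequence(iv, chord_window)
  if (nrow(sq) && chord_window > 0)
    sq <- sq[!duplicated(sq$chord), , drop = FALSE]   # chord representative
  n <- nrow(sq)
  out <- list(pct_crescendo = NA_real_, pct_diminuendo = NA_real_,
              pct_same_intensity = NA_real_,
              pct_ww = NA_real_, pct_wb = NA_real_,
              pct_bw = NA_real_, pct_bb = NA_real_,
              pct_accelerando = NA_real_, pct_ritardando = NA_real_)
  if (n >= 2) {
    v1 <- sq$velocity[-n]; v2 <- sq$velocity[-1]
    np <- n - 1
    out$pct_crescendo <- 100 * sum(v2 > v1) / np
    out$pct_diminuendo <- 100 * sum(v2 < v1) / np
    out$pct_same_intensity <- 100 * sum(v2 == v1) / np
    c1 <- note_color(sq$note[-n]); c2 <- note_color(sq$note[-1])
    out$pct_ww <- 100 * sum(c1 == "white" & c2 == "white") / np
    out$pct_wb <- 100 * sum(c1 == "white" & c2 == "black") / np
    out$pct_bw <- 100 * sum(c1 == "black" & c2 == "white") / np
    out$pct_bb <- 100 * sum(c1 == "black" & c2 == "black") / np
  }
  if (n >= 3) {
    ioi <- diff(sq$onset)
    k <- length(ioi) - 1
    accel <- sum(ioi[-1] < ioi[-length(ioi)])
    out$pct_accelerando <- 100 * accel / k
    out$pct_ritardando <- 100 * (k - accel) / k    # ties count as ritardando
  }
  out
}

#' All behavioral metrics of one session
#'
#' Assembles the full per-session parameter set: time budget, concurrency,
#' key use, dynamics/octave/pitch-class profiles, cluster configurations
#' and transitions. Fields whose minimum press requirement is not met are
#' NA.
#'
#' @inheritParams compute_profiles
#' @param chord_window Chord window for transition metrics (seconds);
#'   default 0 (ungrouped).
#' @return An object of class `session_metrics`: a named list of scalar
#'   fields plus the vectors `pitch_class_pct`, `octave_hist`,
#'   `intensity_hist`.
#' @examples
#' ev <- raw_events(time = c(0, 1, 0.5, 2), kind = c("on", "off", "on", "off"),
#'                  note = c(60, 60, 64, 64), velocity = c(80, NA, 90, NA))
#' m <- compute_session_metrics(session_record(ev, "demo", t_end = 2.5))
#' m$pct_playing_time
#' m$pct_concurrent
#' @export
compute_session_metrics <- function(session, keyboard = keyboard_spec(),
                                    scale = dynamics_scale(),
                                    chord_window = 0,
                                    weight = c("duration", "press"),
                                    octave_offset = -1L) {
  stopifnot(inherits(session, "session_record"))
  m <- c(compute_time_metrics(session),
         list(pct_concurrent = compute_concurrent_metric(session)),
         compute_key_metrics(session, keyboard),
         compute_profiles(session, keyboard, scale, weight, octave_offset),
         compute_cluster_metrics(session),
         compute_transition_metrics(session, keyboard, chord_window))
  m$session_id <- session$session_id
  structure(m, class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(render_session_report(x), sep = "\n")
  invisible(x)
}

SESSION_META_COLS <- c("session_id", "participant_id", "task", "gender",
                       "age", "proficiency")

#' Metrics table for a cohort
#'
#' One row per session: the session metadata followed by every scalar
#' metric and the flattened histograms (`pc_*` pitch-class percentages,
#' `oct_*` octave percentages, `int_*` dynamics-level percentages).
#'
#' @param x A [cohort()].
#' @inheritParams compute_session_metrics
#' @return A `data.frame`; metric column names are in
#'   `attr(, "metric_cols")`.
#' @export
metrics_table <- function(x, keyboard = keyboard_spec(),
                          scale = dynamics_scale(), chord_window = 0,
                          weight = c("duration", "press"),
                          octave_offset = -1L) {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x, function(s) {
    m <- compute_session_metrics(s, keyboard, scale, chord_window,
                                 weight, octave_offset)
    flat <- c(m[!names(m) %in%
                  c("pitch_class_pct", "octave_hist", "intensity_hist",
                    "session_id")],
              stats::setNames(as.list(m$pitch_class_pct),
                              paste0("pc_", sub("#", "s", names(m$pitch_class_pct)))),
              stats::setNames(as.list(m$octave_hist),
                              paste0("oct_", names(m$octave_hist))),
              stats::setNames(as.list(m$intensity_hist),
                              paste0("int_", seq_along(m$intensity_hist))))
    cbind(data.frame(session_id = s$session_id,
                     participant_id = s$participant_id, task = s$task,
                     gender = s$gender, age = s$age,
                     proficiency = s$proficiency),
          as.data.frame(flat))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "metric_cols") <- setdiff(names(out), SESSION_META_COLS)
  out
}

metric_columns <- function(mt) {
  mc <- attr(mt, "metric_cols")
  if (is.null(mc)) mc <- setdiff(names(mt)[vapply(mt, is.numeric, TRUE)],
                                 SESSION_META_COLS)
  mc
}

# grouping labels for a metrics table
grouping_labels <- function(mt, by) {
  kw <- c("task", "gender", "proficiency", "age", "valence", "none")
  if (!(length(by) == 1 && is.character(by) && by %in% kw)) {
    if (length(by) != nrow(mt))
      stop("by must be one of ", paste(kw, collapse = "/"),
           " or a label vector of length nrow(mt)", call. = FALSE)
    if (is.factor(by)) {
      missing_lv <- setdiff(levels(by), unique(as.character(by)))
      if (length(missing_lv))
        stop("empty group: ", paste(missing_lv, collapse = ", "),
             call. = FALSE)
    }
    return(as.character(by))
  }
  switch(by,
    task = mt$task,
    gender = mt$gender,
    proficiency = mt$proficiency,
    age = {
      med <- stats::median(mt$age, na.rm = TRUE)
      ifelse(is.na(mt$age), NA, ifelse(mt$age > med, "old", "young"))
    },
    valence = {
      v <- rep(NA_character_, nrow(mt))
      v[mt$task %in% c("ugly", "negative")] <- "negative_valence"
      v[mt$task %in% c("beautiful", "positive")] <- "positive_valence"
      v
    },
    none = rep("average", nrow(mt))
  )
}

#' Aggregate session metrics over groups
#'
#' Computes the mean (M) and the standard error of the mean (SEM = sd /
#' sqrt(n)) of every metric within each group. Missing metric values are
#' excluded pairwise (per parameter). The built-in groupings are the task
#' label, gender, proficiency, the median age split (over the cohort
#' median counts as old), the bipolar valence collapse (ugly/negative vs
#' beautiful/positive), and `"none"` (one overall group, labelled
#' "average"); any custom label vector of the same length works too.
#'
#' @param mt Metrics table from [metrics_table()].
#' @param by Grouping: `"task"`, `"gender"`, `"proficiency"`, `"age"`,
#'   `"valence"`, `"none"`, or a label vector of length `nrow(mt)`.
#' @param params Metric columns to aggregate; default all.
#' @return An object of class `group_aggregate`: a long `data.frame` with
#'   columns `group`, `parameter`, `mean`, `sem`, `n`.
#' @export
aggregate_metrics <- function(mt, by = "task", params = NULL) {
  labels <- grouping_labels(mt, by)
  if (is.null(params)) params <- metric_columns(mt)
  keep <- !is.na(labels)
  mt <- mt[keep, , drop = FALSE]; labels <- labels[keep]
  groups <- unique(labels)
  if (length(groups) == 0) stop("no non-missing groups", call. = FALSE)
  rows <- list()
  for (g in groups) {
    sub <- mt[labels == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty group: ", g, call. = FALSE)
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p,
        mean = if (n) mean(v) else NA_real_,
        sem = if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
        n = n)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("group_aggregate", "data.frame")
  out
}

#' @export
print.group_aggregate <- function(x, ...) {
  cat(sprintf("Group aggregate: %d group(s) x %d parameter(s)\n",
              length(unique(x$group)), length(unique(x$parameter))))
  NextMethod()
}

#' Write a metrics table as TSV
#'
#' One row per session, one column per metric, missing values as empty
#' cells.
#'
#' @param mt Metrics table from [metrics_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(mt, path) {
  utils::write.table(mt, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
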