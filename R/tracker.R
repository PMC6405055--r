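# The executable equivalent of the reactive session model: raw on/off
# events are paired into note intervals, reduced to the piecewise-constant
# count of simultaneously held keys, and replayed as an Idle/Playing state
# trace with running extrema.

as_events <- function(x) {
  if (inherits(x, "session_record")) x$events else x
}

#' Pair note on/off events into note intervals
#'
#' Per-note FIFO pairing: each `"off"` closes the earliest still-open
#' `"on"` of the same note. A dangling `"on"` (no matching `"off"`) is
#' closed at the session end `t_end` with a warning, preserving its
#' playing-time mass; an unmatched `"off"` is dropped with a warning.
#'
#' @param events A [session_record()] or an event table from [raw_events()].
#' @param t_end Session end used to close dangling notes; defaults to the
#'   session's `t_end` or the last event time.
#' @return A `data.frame` with columns `onset`, `offset`, `note`,
#'   `velocity`, ordered by `(onset, note)`. Intervals satisfy
#'   `offset > onset`; the convention is half-open `[onset, offset)`.
#' @export
pair_events <- function(events, t_end = NULL) {
  if (inherits(events, "session_record")) {
    if (is.null(t_end)) t_end <- events$t_end
    events <- events$events
  }
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      note = integer(), velocity = integer())
  if (is.null(events) || nrow(events) == 0) return(empty)
  if (is.null(t_end)) t_end <- max(events$time)
  ivs <- lapply(split(seq_len(nrow(events)), events$note), function(idx) {
    tm <- events$time[idx]; kd <- events$kind[idx]; vl <- events$velocity[idx]
    open_t <- numeric(0); open_v <- integer(0)
    onset <- numeric(0); offset <- numeric(0); vel <- integer(0)
    dropped <- 0L
    for (i in seq_along(idx)) {
      if (kd[i] == "on") {
        open_t <- c(open_t, tm[i]); open_v <- c(open_v, vl[i])
      } else if (length(open_t)) {
        onset <- c(onset, open_t[1]); offset <- c(offset, tm[i])
        vel <- c(vel, open_v[1])
        open_t <- open_t[-1]; open_v <- open_v[-1]
      } else dropped <- dropped + 1L
    }
    note <- events$note[idx[1]]
    if (dropped)
      warning(sprintf("note %d: dropped %d unmatched note-off event(s)",
                      note, dropped), call. = FALSE)
    if (length(open_t)) {
      warning(sprintf("note %d: closed %d dangling note-on(s) at t_end = %g",
                      note, length(open_t), t_end), call. = FALSE)
      onset <- c(onset, open_t); offset <- c(offset, rep(t_end, length(open_t)))
      vel <- c(vel, open_v)
    }
    data.frame(onset = onset, offset = offset,
               note = rep(note, length(onset)), velocity = vel)
  })
  out <- do.call(rbind, c(ivs, list(make.row.names = FALSE)))
  zero <- out$offset <= out$onset
  if (any(zero)) {
    warning(sprintf("dropped %d zero-length interval(s)", sum(zero)),
            call. = FALSE)
    out <- out[!zero, , drop = FALSE]
  }
  out <- out[order(out$onset, out$note, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Net playing time of a set of note intervals
#'
#' The measure of the union of the half-open intervals `[onset, offset)`:
#' time during which at least one key sounds. Overlapping notes are not
#' double counted.
#'
#' @param intervals Interval table from [pair_events()].
#' @return Seconds (0 for an empty set).
#' @export
playing_time <- function(intervals) {
  n <- nrow(intervals)
  if (is.null(n) || n == 0) return(0)
  ord <- order(intervals$onset, method = "radix")
  on <- intervals$onset[ord]; off <- intervals$offset[ord]
  total <- 0
  cur_on <- on[1]; cur_off <- off[1]
  for (i in seq_len(n)[-1]) {
    if (on[i] > cur_off) {
      total <- total + (cur_off - cur_on)
      cur_on <- on[i]; cur_off <- off[i]
    } else cur_off <- max(cur_off, off[i])
  }
  total + (cur_off - cur_on)
}

#' Timeline of the number of simultaneously held keys
#'
#' Reduces note intervals to a piecewise-constant function of time: the
#' count of keys held at each instant (the instantaneous cluster
#' configuration). Adjacent segments with equal counts are merged, so each
#' segment is a maximal constant-count stretch.
#'
#' @param intervals Interval table from [pair_events()].
#' @return An object of class `held_timeline`: a list with `breakpoints`
#'   (ascending, length `k + 1`) and `counts` (length `k`). The integral of
#'   the count equals the summed interval durations.
#' @export
held_timeline <- function(intervals) {
  n <- nrow(intervals)
  if (is.null(n) || n == 0)
    return(structure(list(breakpoints = c(0, 0), counts = 0),
                     class = "held_timeline"))
  t <- c(intervals$onset, intervals$offset)
  d <- rep(c(1, -1), each = n)
  ord <- order(t, method = "radix")
  t <- t[ord]; d <- d[ord]
  last <- !duplicated(t, fromLast = TRUE)
  counts <- cumsum(d)[last]
  bp <- t[last]
  counts <- counts[-length(counts)]        # count after the final offset is 0
  keep <- c(TRUE, diff(counts) != 0)       # merge equal neighbours
  structure(list(breakpoints = c(bp[c(keep, TRUE)]),
                 counts = counts[keep]),
            class = "held_timeline")
}

#' @export
print.held_timeline <- function(x, ...) {
  cat(sprintf("Held-key timeline: %d segments over [%g, %g] s, max %d keys\n",
              length(x$counts), x$breakpoints[1],
              x$breakpoints[length(x$breakpoints)], max(x$counts)))
  invisible(x)
}

#' @export
as.data.frame.held_timeline <- function(x, ...) {
  k <- length(x$counts)
  data.frame(start = x$breakpoints[seq_len(k)],
             end = x$breakpoints[seq_len(k) + 1L],
             count = x$counts)
}

# integral of the held count = total key-seconds
timeline_integral <- function(tl) {
  sum(tl$counts * diff(tl$breakpoints))
}

#' Ordered press sequence with optional chord grouping
#'
#' Presses ordered by `(onset, note)`. With `chord_window > 0`, presses
#' whose onset falls strictly within the window of the first onset of the
#' current group are treated as one chord (the spread of a humanly
#' "simultaneous" chord); `chord_window = 0` puts every press in its own
#' group.
#'
#' @param intervals Interval table from [pair_events()].
#' @param chord_window Grouping window in seconds, `>= 0`; default 0.03.
#' @return A `data.frame` with columns `onset`, `note`, `velocity`,
#'   `chord` (group index, 1-based).
#' @export
onset_sequence <- function(intervals, chord_window = 0.03) {
  stopifnot(chord_window >= 0)
  n <- nrow(intervals)
  if (is.null(n) || n == 0)
    return(data.frame(onset = numeric(), note = integer(),
                      velocity = integer(), chord = integer()))
  ord <- order(intervals$onset, intervals$note, method = "radix")
  onset <- intervals$onset[ord]
  chord <- integer(n)
  chord[1] <- 1L
  g0 <- onset[1]
  for (i in seq_len(n)[-1]) {
    if (onset[i] - g0 < chord_window) {
      chord[i] <- chord[i - 1L]
    } else {
      chord[i] <- chord[i - 1L] + 1L
      g0 <- onset[i]
    }
  }
  data.frame(onset = onset, note = intervals$note[ord],
             velocity = intervals$velocity[ord], chord = chord)
}

#' Replay a session as an Idle/Playing state trace
#'
#' Replays the event stream of a session: the session is `Playing` whenever
#' at least one key is held and `Idle` otherwise; every entry into a new
#' cluster configuration (held-key count) is recorded, together with the
#' running minima and maxima of the dynamics level, the octave number and
#' the cluster size up to each change point.
#'
#' @param session A [session_record()].
#' @param keyboard A [keyboard_spec()] (kept for interface symmetry).
#' @param scale A [dynamics_scale()] used for intensity levels.
#' @return An object of class `state_trace`: list with `states`
#'   (`data.frame(time, state)`, entry times), `clusters`
#'   (`data.frame(time, size)`, configuration entries) and `extrema`
#'   (`data.frame(time, min_intensity, max_intensity, min_octave,
#'   max_octave, max_cluster)`, running values at each press).
#' @export
state_trace <- function(session, keyboard = keyboard_spec(),
                        scale = dynamics_scale()) {
  stopifnot(inherits(session, "session_record"))
  iv <- pair_events(session)
  tl <- held_timeline(iv)
  if (nrow(iv) == 0) {
    states <- data.frame(time = session$t0, state = "Idle")
    return(structure(list(states = states,
                          clusters = data.frame(time = numeric(),
                                                size = integer()),
                          extrema = data.frame(time = numeric(),
                                               min_intensity = integer(),
                                               max_intensity = integer(),
                                               min_octave = integer(),
                                               max_octave = integer(),
                                               max_cluster = integer())),
                     class = "state_trace"))
  }
  k <- length(tl$counts)
  seg_start <- tl$breakpoints[seq_len(k)]
  seg_state <- ifelse(tl$counts >= 1, "Playing", "Idle")
  times <- seg_start; st <- seg_state
  if (tl$breakpoints[1] > session$t0) {
    times <- c(session$t0, times); st <- c("Idle", st)
  }
  if (tl$breakpoints[k + 1] < session$t_end) {
    times <- c(times, tl$breakpoints[k + 1]); st <- c(st, "Idle")
  }
  keep <- c(TRUE, st[-1] != st[-length(st)])
  states <- data.frame(time = times[keep], state = st[keep])
  pos <- tl$counts >= 1
  clusters <- data.frame(time = seg_start[pos], size = tl$counts[pos])

  seq_press <- onset_sequence(iv, chord_window = 0)
  lev <- unname(dynamics_level(seq_press$velocity, scale))
  oct <- note_octave(seq_press$note)
  cl_at_press <- tl$counts[findInterval(seq_press$onset, tl$breakpoints,
                                        rightmost.closed = TRUE)]
  extrema <- data.frame(time = seq_press$onset,
                        min_intensity = cummin(lev),
                        max_intensity = cummax(lev),
                        min_octave = cummin(oct),
                        max_octave = cummax(oct),
                        max_cluster = cummax(cl_at_press))
  structure(list(states = states, clusters = clusters, extrema = extrema),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("State trace: %d state change(s), %d cluster entries\n",
              nrow(x$states), nrow(x$clusters)))
  if (nrow(x$extrema)) {
    last <- x$extrema[nrow(x$extrema), ]
    cat(sprintf("  final running extrema: intensity %d..%d, octave %d..%d, max cluster %d\n",
                last$min_intensity, last$max_intensity,
                last$min_octave, last$max_octave, last$max_cluster))
  }
  invisible(x)
}

#' @export
as.data.frame.state_trace <- function(x, ...) x$states

#' Write a state trace as TSV
#'
#' @param trace A [state_trace()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_state_trace <- function(trace, path) {
  stopifnot(inherits(trace, "state_trace"))
  utils::write.table(trace$states, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quintile duration labels for sessions of a cohort
#'
#' Descriptive labels ("extremely_short" .. "extremely_long") assigned by
#' the quintiles of session duration across the cohort. Reported for
#' documentation; not used by any statistic.
#'
#' @param x A [cohort()].
#' @return Named character vector, one label per session.
#' @export
session_length_category <- function(x) {
  stopifnot(inherits(x, "cohort"))
  dur <- vapply(x, function(s) s$t_end - s$t0, 0)
  labels <- c("extremely_short", "short", "medium", "long", "extremely_long")
  if (length(dur) < 5 || stats::sd(dur) == 0)
    return(stats::setNames(rep("medium", length(dur)), names(x)))
  q <- stats::quantile(dur, probs = seq(0, 1, 0.2), names = FALSE)
  idx <- findInterval(dur, q, rightmost.closed = TRUE, all.inside = TRUE)
  stats::setNames(labels[idx], names(x))
}
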