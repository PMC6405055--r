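# Textual and tabular reporting: the comprehensive per-session report, the
# piano-roll view, and the cohort mean (SEM) matrix with significance
# stars. Rendering is deterministic: fixed field order, fixed precision
# (percentages and seconds 1 decimal, minutes 2, levels integer), missing
# values as "n/a".

fmt_num <- function(x, digits = 1) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "n/a"
  else formatC(x, format = "f", digits = digits)
}

fmt_int <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "n/a" else sprintf("%d", as.integer(x))
}

#' Render the comprehensive textual report of a session
#'
#' Deterministic layout: labeled sections for time, concurrency, keys,
#' intensity, octave, pitch classes, clusters and transitions; every
#' computed field appears exactly once; missing fields render as "n/a".
#'
#' @param metrics A [compute_session_metrics()] result.
#' @return Character vector of report lines, class `session_report`.
#' @export
render_session_report <- function(metrics) {
  m <- metrics
  line <- function(label, value) sprintf("  %-28s %s", label, value)
  lines <- c(
    sprintf("Improvisation session report: %s",
            if (is.null(m$session_id)) "(unnamed)" else m$session_id),
    "Time",
    line("% playing time", fmt_num(m$pct_playing_time)),
    line("% idle time", fmt_num(m$pct_idle_time)),
    line("start time (sec)", fmt_num(m$start_time_s)),
    line("% start time", fmt_num(m$pct_start_time)),
    line("total session (min)", fmt_num(m$total_session_min, 2)),
    line("% concurrent", fmt_num(m$pct_concurrent)),
    "Notes/Keys",
    line("# of presses", fmt_int(m$n_presses)),
    line("% keys used", fmt_num(m$pct_keys_used)),
    line("presses per key", fmt_num(m$presses_per_key, 2)),
    line("play per key (sec)", fmt_num(m$play_per_key_s, 2)),
    line("% black presses", fmt_num(m$pct_black_presses)),
    line("% white presses", fmt_num(m$pct_white_presses)),
    "Intensity (dynamics level 1-10)",
    line("average", fmt_num(m$intensity_avg)),
    line("lowest (minimum)", fmt_int(m$intensity_min)),
    line("highest (maximum)", fmt_int(m$intensity_max)),
    line("most used", fmt_int(m$intensity_most_used)),
    line("% of play per level",
         paste(vapply(m$intensity_hist, fmt_num, ""), collapse = " ")),
    "Octave",
    line("average", fmt_num(m$octave_avg)),
    line("lowest (minimum)", fmt_int(m$octave_min)),
    line("highest (maximum)", fmt_int(m$octave_max)),
    line("most used", fmt_int(m$octave_most_used)),
    line("% of play per octave",
         paste(vapply(m$octave_hist, fmt_num, ""), collapse = " ")),
    "Pitch classes (% of play)",
    line(paste(names(m$pitch_class_pct), collapse = " "),
         paste(vapply(m$pitch_class_pct, fmt_num, ""), collapse = " ")),
    "Clusters of notes",
    line("# of instances", fmt_int(m$cluster_instances)),
    line("max pressed", fmt_int(m$cluster_max)),
    line("most pressed", fmt_int(m$cluster_mode)),
    line("% most played", fmt_num(m$pct_time_cluster_mode)),
    "Transitions",
    line("% diminuendo", fmt_num(m$pct_diminuendo)),
    line("% crescendo", fmt_num(m$pct_crescendo)),
    line("% same intensity", fmt_num(m$pct_same_intensity)),
    line("% accelerando", fmt_num(m$pct_accelerando)),
    line("% ritardando", fmt_num(m$pct_ritardando)),
    line("% white to black", fmt_num(m$pct_wb)),
    line("% black to white", fmt_num(m$pct_bw)),
    line("% black to black", fmt_num(m$pct_bb)),
    line("% white to white", fmt_num(m$pct_ww))
  )
  structure(lines, class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Piano-roll view of one or more sessions
#'
#' One row per note interval: onset, offset, note name with octave (sharp
#' spelling), velocity and key color; a `session` column labels the series
#' when several sessions are overlaid. The `plot()` method draws time on
#' the abscissa and the keyboard on the ordinate.
#'
#' @param x A [session_record()], a list of them, or a [cohort()].
#' @param keyboard A [keyboard_spec()] (sets the plot range).
#' @return A `data.frame` of class `piano_roll` with columns `session`,
#'   `onset`, `offset`, `note`, `name`, `velocity`, `color`.
#' @export
render_piano_roll <- function(x, keyboard = keyboard_spec()) {
  if (inherits(x, "session_record")) x <- list(x)
  stopifnot(all(vapply(x, inherits, TRUE, "session_record")))
  rows <- lapply(x, function(s) {
    iv <- pair_events(s)
    if (nrow(iv) == 0)
      return(data.frame(session = character(), onset = numeric(),
                        offset = numeric(), note = integer(),
                        name = character(), velocity = integer(),
                        color = character()))
    data.frame(session = s$session_id, onset = iv$onset, offset = iv$offset,
               note = iv$note, name = note_name(iv$note),
               velocity = iv$velocity, color = note_color(iv$note))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "keyboard") <- keyboard
  class(out) <- c("piano_roll", "data.frame")
  out
}

#' @export
plot.piano_roll <- function(x, ...) {
  kb <- attr(x, "keyboard")
  if (is.null(kb)) kb <- keyboard_spec()
  sessions <- unique(x$session)
  pal <- grDevices::hcl.colors(max(2L, length(sessions)), "Dark 2")
  xmax <- if (nrow(x)) max(x$offset) else 1
  graphics::plot(NULL, xlim = c(0, xmax),
                 ylim = c(kb$lowest_note, kb$highest_note),
                 xlab = "time (s)", ylab = "MIDI note", yaxt = "n", ...)
  cnotes <- keyboard_notes(kb)
  cnotes <- cnotes[cnotes %% 12 == 0]
  graphics::axis(2, at = cnotes, labels = note_name(cnotes), las = 1)
  for (i in seq_along(sessions)) {
    sub <- x[x$session == sessions[i], , drop = FALSE]
    graphics::segments(sub$onset, sub$note, sub$offset, sub$note,
                       col = pal[i], lwd = 3, lend = 1)
  }
  if (length(sessions) > 1)
    graphics::legend("topright", legend = sessions,
                     col = pal[seq_along(sessions)], lwd = 3, bty = "n")
  invisible(x)
}

#' Render a cohort mean (SEM) comparison table
#'
#' Rows are parameters, columns are groups; each cell is "mean (SEM)".
#' When a [compare_collectives()] result is supplied, the cell of the
#' larger-mean group gains significance stars from the one-sided test
#' (`* p < .05, ** p < .01, *** p < .001`). The numeric long-format twin of
#' the rendered table is kept in `attr(, "twin")` and written alongside by
#' [write_cohort_table()].
#'
#' @param aggregates A [aggregate_metrics()] result (optionally rbind-ed
#'   with an overall "average" aggregate).
#' @param stats Optional [compare_collectives()] result for the same
#'   parameters.
#' @return A character `data.frame` of class `cohort_table` (rownames =
#'   parameters).
#' @export
render_cohort_table <- function(aggregates, stats = NULL) {
  stopifnot(inherits(aggregates, "data.frame"))
  params <- unique(aggregates$parameter)
  groups <- unique(aggregates$group)
  if (!is.null(stats)) {
    stats <- stats[stats$variant == stats$variant[1], , drop = FALSE]
    if (!setequal(stats$parameter, params))
      stop("parameter sets of aggregates and stats do not match",
           call. = FALSE)
  }
  cells <- matrix("", nrow = length(params), ncol = length(groups),
                  dimnames = list(params, groups))
  for (i in seq_len(nrow(aggregates))) {
    a <- aggregates[i, ]
    cells[a$parameter, a$group] <- sprintf(
      "%s (%s)",
      format(signif(a$mean, 3), scientific = FALSE, trim = TRUE),
      format(signif(a$sem, 2), scientific = FALSE, trim = TRUE))
  }
  if (!is.null(stats)) {
    for (i in seq_len(nrow(stats))) {
      s <- stats[i, ]
      star <- significance_stars(s$p_one_sided)
      if (nzchar(star) && !is.na(s$direction) && s$direction %in% groups)
        cells[s$parameter, s$direction] <-
          paste0(cells[s$parameter, s$direction], " ", star)
    }
  }
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  attr(out, "twin") <- aggregates
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort parameter table, cells are mean (SEM); ",
      "* p < .05, ** p < .01, *** p < .001\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a cohort table and its machine-readable twin
#'
#' Writes the rendered table as TSV and the numeric long-format twin
#' (`group, parameter, mean, sem, n`) as `<path>.twin.tsv`.
#'
#' @param ct A [render_cohort_table()] result.
#' @param path Destination path of the rendered table.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(ct, path) {
  stopifnot(inherits(ct, "cohort_table"))
  tab <- cbind(parameter = rownames(ct), as.data.frame(ct))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  twin <- attr(ct, "twin")
  utils::write.table(twin, paste0(path, ".twin.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
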