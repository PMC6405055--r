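#' Construct a raw note-event table
#'
#' The canonical in-memory event stream: one row per key press (`kind =
#' "on"`) or release (`kind = "off"`), with times in seconds from the start
#' of the recording. Events are stably sorted by `(time, kind, note)`, so a
#' release coincident with a press sorts first.
#'
#' @param time Event times in seconds, `>= 0`.
#' @param kind `"on"` or `"off"` per event.
#' @param note MIDI note number per event, 0..127.
#' @param velocity MIDI velocity per event; required for `"on"` events, may
#'   be `NA` for `"off"` events.
#' @return A `data.frame` with columns `time`, `kind`, `note`, `velocity`.
#' @export
raw_events <- function(time = numeric(), kind = character(),
                       note = integer(), velocity = integer()) {
  n <- length(time)
  stopifnot(length(kind) == n, length(note) == n, length(velocity) == n)
  if (n == 0)
    return(data.frame(time = numeric(), kind = character(),
                      note = integer(), velocity = integer()))
  if (anyNA(time) || !is.numeric(time) || any(time < 0))
    stop("event times must be non-negative numbers", call. = FALSE)
  kind <- as.character(kind)
  if (!all(kind %in% c("on", "off")))
    stop("event kind must be \"on\" or \"off\"", call. = FALSE)
  note <- check_note(note)
  on <- kind == "on"
  if (anyNA(velocity[on]))
    stop("\"on\" events must carry a velocity", call. = FALSE)
  velocity[on] <- check_velocity(velocity[on])
  velocity <- as.integer(velocity)
  ev <- data.frame(time = as.numeric(time), kind = kind,
                   note = note, velocity = velocity)
  ev <- ev[order(ev$time, ev$kind, ev$note, method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' A single improvisation session
#'
#' Bundles the raw note events of one improvisation with its metadata and
#' session bounds. By default the session starts at the recording start
#' (`t0 = 0`) and ends at the last event (`t_end = max(time)`); explicit
#' bounds can be supplied when the source encodes them, which affects the
#' idle- and start-time percentages.
#'
#' @param events Event table as produced by [raw_events()].
#' @param session_id Unique session identifier.
#' @param participant_id Participant identifier.
#' @param task Improvisation task label (e.g. `"ugly"`, `"beautiful"`,
#'   `"negative"`, `"positive"`, or free text).
#' @param gender,age,proficiency Participant demographics; `proficiency` is
#'   conventionally `"layman"` or `"professional"`.
#' @param t0 Session start, seconds (default 0).
#' @param t_end Session end, seconds; default the last event time (or `t0`
#'   for an empty session).
#' @return An object of class `session_record`.
#' @export
session_record <- function(events, session_id,
                           participant_id = NA_character_, task = NA_character_,
                           gender = NA_character_, age = NA_real_,
                           proficiency = NA_character_,
                           t0 = 0, t_end = NULL) {
  events <- raw_events(events$time, events$kind, events$note, events$velocity)
  if (is.null(t_end))
    t_end <- if (nrow(events)) max(events$time) else t0
  if (t_end < t0)
    stop("t_end must be >= t0", call. = FALSE)
  if (nrow(events) && (min(events$time) < t0 || max(events$time) > t_end))
    stop("all event times must lie in [t0, t_end]", call. = FALSE)
  structure(
    list(session_id = as.character(session_id),
         participant_id = as.character(participant_id),
         task = as.character(task), gender = as.character(gender),
         age = as.numeric(age), proficiency = as.character(proficiency),
         events = events, t0 = as.numeric(t0), t_end = as.numeric(t_end)),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session %s: %d events over %.2f s", x$session_id,
              nrow(x$events), x$t_end - x$t0))
  meta <- c(participant = x$participant_id, task = x$task, gender = x$gender,
            age = if (is.na(x$age)) NA else format(x$age),
            proficiency = x$proficiency)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat(" [", paste(names(meta), meta, sep = "=", collapse = ", "), "]",
        sep = "")
  cat("\n")
  invisible(x)
}

#' A cohort of improvisation sessions
#'
#' @param sessions List of [session_record()] objects with unique session ids.
#' @return An object of class `cohort` (a list of sessions).
#' @export
cohort <- function(sessions = list()) {
  stopifnot(all(vapply(sessions, inherits, TRUE, "session_record")))
  ids <- vapply(sessions, `[[`, "", "session_id")
  if (anyDuplicated(ids))
    stop("duplicate session_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(stats::setNames(sessions, ids), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_ev <- vapply(x, function(s) nrow(s$events), 0L)
  cat(sprintf("Cohort: %d sessions, %d events\n", length(x), sum(n_ev)))
  tasks <- table(vapply(x, `[[`, "", "task"), useNA = "no")
  if (length(tasks))
    cat("  tasks:", paste(names(tasks), tasks, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

EVENT_TABLE_COLS <- c("session_id", "participant_id", "task", "gender",
                      "age", "proficiency", "time_s", "kind", "note",
                      "velocity")

#' Read a canonical note-event table
#'
#' Reads the tab-separated event log written by [write_event_table()]:
#' one row per on/off event, UTF-8, `.` decimal, with columns
#' `session_id, participant_id, task, gender, age, proficiency, time_s,
#' kind, note, velocity`. Rows are grouped by `session_id` and events
#' re-sorted stably by time.
#'
#' @param path Path of the TSV file.
#' @return A [cohort()].
#' @export
read_event_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", na.strings = "",
                           comment.char = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(EVENT_TABLE_COLS, names(tab))
  if (length(missing_cols))
    stop("event table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("time_s", "note", "velocity", "age")) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.na(tab[[col]]) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value in column %s at line %d: \"%s\"",
                   col, bad[1] + 1L, tab[[col]][bad[1]]), call. = FALSE)
    tab[[col]] <- num
  }
  sessions <- lapply(split(tab, factor(tab$session_id,
                                       levels = unique(tab$session_id))),
                     function(rows) {
    session_record(
      data.frame(time = rows$time_s, kind = rows$kind,
                 note = rows$note, velocity = rows$velocity),
      session_id = rows$session_id[1], participant_id = rows$participant_id[1],
      task = rows$task[1], gender = rows$gender[1], age = rows$age[1],
      proficiency = rows$proficiency[1])
  })
  cohort(unname(sessions))
}

#' Write a cohort as a canonical note-event table
#'
#' Deterministic row order: `(session_id, time, note)`. An empty cohort
#' yields a header-only file.
#'
#' @param x A [cohort()] or single [session_record()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path) {
  if (inherits(x, "session_record")) x <- cohort(list(x))
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x, function(s) {
    ev <- s$events
    if (nrow(ev) == 0) return(NULL)
    data.frame(session_id = s$session_id, participant_id = s$participant_id,
               task = s$task, gender = s$gender, age = s$age,
               proficiency = s$proficiency, time_s = ev$time, kind = ev$kind,
               note = ev$note, velocity = ev$velocity)
  })
  rows <- Filter(Negate(is.null), rows)
  tab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    stats::setNames(
      as.data.frame(rep(list(character(0)), length(EVENT_TABLE_COLS))),
      EVENT_TABLE_COLS)
  tab <- tab[order(tab$session_id, tab$time_s, tab$note, method = "radix"), ,
             drop = FALSE]
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v)
    ifelse(is.na(v), NA, format(v, digits = 15, scientific = FALSE,
                                trim = TRUE)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
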