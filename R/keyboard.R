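#' Physical keyboard specification
#'
#' Describes the span of the controller keyboard as an inclusive MIDI note
#' range. The default is the standard 76-key instrument running from E1
#' (MIDI 28) to G7 (MIDI 103), which contains 31 black and 45 white keys.
#'
#' @param lowest_note Lowest playable MIDI note number.
#' @param highest_note Highest playable MIDI note number.
#' @return An object of class `keyboard_spec` with fields `lowest_note`,
#'   `highest_note` and `n_keys`.
#' @examples
#' kb <- keyboard_spec()
#' kb$n_keys                       # 76
#' sum(note_color(keyboard_notes(kb)) == "black")   # 31
#' @export
keyboard_spec <- function(lowest_note = 28L, highest_note = 103L) {
  lowest_note <- check_note(lowest_note)
  highest_note <- check_note(highest_note)
  if (highest_note < lowest_note)
    stop("highest_note must be >= lowest_note", call. = FALSE)
  structure(
    list(lowest_note = lowest_note, highest_note = highest_note,
         n_keys = highest_note - lowest_note + 1L),
    class = "keyboard_spec"
  )
}

#' @export
print.keyboard_spec <- function(x, ...) {
  notes <- keyboard_notes(x)
  cols <- note_color(notes)
  cat(sprintf("Keyboard: %d keys, %s (%d) .. %s (%d); %d black, %d white\n",
              x$n_keys,
              note_name(x$lowest_note), x$lowest_note,
              note_name(x$highest_note), x$highest_note,
              sum(cols == "black"), sum(cols == "white")))
  invisible(x)
}

#' All MIDI note numbers on a keyboard
#'
#' @param keyboard A [keyboard_spec()].
#' @return Integer vector of note numbers, lowest to highest.
#' @export
keyboard_notes <- function(keyboard = keyboard_spec()) {
  stopifnot(inherits(keyboard, "keyboard_spec"))
  seq.int(keyboard$lowest_note, keyboard$highest_note)
}

check_note <- function(note) {
  if (length(note) == 0 || anyNA(note) || !is.numeric(note))
    stop("note must be numeric and non-missing", call. = FALSE)
  if (any(note != floor(note)) || any(note < 0) || any(note > 127))
    stop("MIDI note numbers must be integers in 0..127", call. = FALSE)
  as.integer(note)
}

check_velocity <- function(velocity) {
  if (length(velocity) == 0 || anyNA(velocity) || !is.numeric(velocity))
    stop("velocity must be numeric and non-missing", call. = FALSE)
  if (any(velocity != floor(velocity)) || any(velocity < 0) || any(velocity > 127))
    stop("MIDI velocities must be integers in 0..127", call. = FALSE)
  as.integer(velocity)
}

# the five sharp pitch classes: C#, D#, F#, G#, A#
BLACK_CLASSES <- c(1L, 3L, 6L, 8L, 10L)
PITCH_CLASS_NAMES <- c("C", "C#", "D", "D#", "E", "F",
                       "F#", "G", "G#", "A", "A#", "B")

#' Key color of a MIDI note
#'
#' A key is black iff its pitch class is one of the five sharps
#' (C#, D#, F#, G#, A#); all other classes are white keys.
#'
#' @param note MIDI note number(s), 0..127.
#' @return Character vector, `"black"` or `"white"`.
#' @examples
#' note_color(60)  # middle C -> "white"
#' note_color(61)  # C# -> "black"
#' @export
note_color <- function(note) {
  note <- check_note(note)
  ifelse((note %% 12L) %in% BLACK_CLASSES, "black", "white")
}

#' Octave number of a MIDI note
#'
#' Uses the scientific pitch convention by default: middle C (MIDI 60) is C4,
#' i.e. `octave = floor(note / 12) - 1`. On the default 76-key instrument this
#' yields octaves 1 (E1) through 7 (G7). The convention can be shifted with
#' `offset` (e.g. `offset = 0` gives the convention where middle C is C5).
#'
#' @param note MIDI note number(s), 0..127.
#' @param offset Integer added to `floor(note/12)`; default `-1` (scientific).
#' @return Integer octave number(s).
#' @examples
#' note_octave(60)   # 4
#' note_octave(28)   # 1
#' @export
note_octave <- function(note, offset = -1L) {
  note <- check_note(note)
  note %/% 12L + as.integer(offset)
}

#' Pitch class of a MIDI note
#'
#' @param note MIDI note number(s), 0..127.
#' @return Integer class(es) in 0..11 named `C, C#, ..., B` (sharp spelling).
#' @examples
#' pitch_class(60)   # C
#' pitch_class(70)   # A#
#' @export
pitch_class <- function(note) {
  note <- check_note(note)
  pc <- note %% 12L
  names(pc) <- PITCH_CLASS_NAMES[pc + 1L]
  pc
}

#' Note name with octave
#'
#' Sharp spelling, octave per [note_octave()], e.g. `"C4"` for MIDI 60.
#'
#' @inheritParams note_octave
#' @return Character vector of names such as `"F#3"`.
#' @export
note_name <- function(note, offset = -1L) {
  note <- check_note(note)
  paste0(PITCH_CLASS_NAMES[note %% 12L + 1L], note %/% 12L + as.integer(offset))
}

#' Ten-level dynamics scale
#'
#' Maps MIDI velocity (0..127) onto the ten musical dynamics levels
#' 1-pppp, 2-ppp, 3-pp, 4-p, 5-mp, 6-mf, 7-f, 8-ff, 9-fff, 10-ffff.
#' The default boundaries are equal-width over the velocity range,
#' `level = 1 + floor(velocity * 10 / 128)`; published alternative
#' categorizations can be swapped in by supplying the nine `thresholds`
#' (the lowest velocity of levels 2..10).
#'
#' @param thresholds Strictly increasing integer vector of length 9 inside
#'   1..127: the lowest velocity belonging to levels 2..10. `NULL` selects the
#'   equal-width default `ceiling(128 * (1:9) / 10)`.
#' @return An object of class `dynamics_scale` with fields `thresholds`,
#'   `n_levels` and `level_names`.
#' @examples
#' dynamics_level(0)     # 1  (pppp)
#' dynamics_level(64)    # 6  (mf)
#' dynamics_level(127)   # 10 (ffff)
#' @export
dynamics_scale <- function(thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- as.integer(ceiling(128 * (1:9) / 10))
  thresholds <- as.integer(thresholds)
  if (length(thresholds) != 9 || anyNA(thresholds) ||
      any(diff(thresholds) <= 0) || thresholds[1] < 1 || thresholds[9] > 127)
    stop("thresholds must be 9 strictly increasing integers in 1..127",
         call. = FALSE)
  structure(
    list(thresholds = thresholds, n_levels = 10L,
         level_names = c("pppp", "ppp", "pp", "p", "mp",
                         "mf", "f", "ff", "fff", "ffff")),
    class = "dynamics_scale"
  )
}

#' @export
print.dynamics_scale <- function(x, ...) {
  lo <- c(0L, x$thresholds)
  hi <- c(x$thresholds - 1L, 127L)
  cat("Dynamics scale (velocity -> level):\n")
  cat(sprintf("  %2d %-4s  %3d..%3d\n", 1:10, x$level_names, lo, hi), sep = "")
  invisible(x)
}

#' Dynamics level of a MIDI velocity
#'
#' @param velocity MIDI velocity value(s), 0..127.
#' @param scale A [dynamics_scale()].
#' @return Integer level(s) in 1..10, named by dynamics label.
#' @export
dynamics_level <- function(velocity, scale = dynamics_scale()) {
  velocity <- check_velocity(velocity)
  stopifnot(inherits(scale, "dynamics_scale"))
  lev <- findInterval(velocity, scale$thresholds) + 1L
  names(lev) <- scale$level_names[lev]
  lev
}

#' Read an analysis configuration file
#'
#' Plain `key = value` text (one pair per line, `#` comments). Recognized
#' keys: `lowest_note`, `highest_note`, `dynamics_thresholds` (nine
#' comma-separated integers), `octave_offset`, `chord_window`.
#'
#' @param path Path to the configuration file.
#' @return A list with `keyboard` ([keyboard_spec()]), `scale`
#'   ([dynamics_scale()]), `octave_offset` and `chord_window`.
#' @export
read_improv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  conf <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(conf[[key]])) default else as.numeric(conf[[key]])
  }
  thresholds <- NULL
  if (!is.null(conf$dynamics_thresholds))
    thresholds <- as.integer(strsplit(conf$dynamics_thresholds, ",")[[1]])
  list(
    keyboard = keyboard_spec(num("lowest_note", 28), num("highest_note", 103)),
    scale = dynamics_scale(thresholds),
    octave_offset = as.integer(num("octave_offset", -1)),
    chord_window = num("chord_window", 0.03)
  )
}
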