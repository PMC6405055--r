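# Standard MIDI File (format 0/1) reader: chunked binary layout, variable-
# length delta times, running status, meta events. Only note on/off and
# tempo (meta 0x51) affect the output; everything else is skipped at the
# correct byte widths.

#' Read a Standard MIDI File
#'
#' Parses an SMF (format 0 or 1) and converts tick times to seconds via the
#' file's tempo map (all `Set Tempo` meta events, any track; default 120 BPM
#' before the first). A note-on with velocity 0 is treated as a note-off. By
#' default each track containing note events becomes one session; with
#' `merge_tracks = TRUE` all tracks merge into a single session.
#'
#' @param path Path to the `.mid` file.
#' @param merge_tracks Merge all tracks into one session?
#' @param session_id Base session id; defaults to the file name without
#'   extension. Per-track sessions get a `"_t<track>"` suffix.
#' @param ... Metadata fields passed to [session_record()] (`participant_id`,
#'   `task`, `gender`, `age`, `proficiency`).
#' @return A list of [session_record()] objects (empty for an empty file).
#' @export
read_smf <- function(path, merge_tracks = FALSE, session_id = NULL, ...) {
  n_bytes <- file.size(path)
  if (is.na(n_bytes)) stop("cannot read file: ", path, call. = FALSE)
  if (n_bytes == 0) return(list())
  b <- as.integer(readBin(path, "raw", n_bytes))
  if (is.null(session_id))
    session_id <- tools::file_path_sans_ext(basename(path))

  pos <- 1L
  need <- function(n) {
    if (pos + n - 1L > length(b))
      stop("corrupt MIDI file: unexpected end of data", call. = FALSE)
  }
  u8 <- function() { need(1L); v <- b[pos]; pos <<- pos + 1L; v }
  u16 <- function() { need(2L); v <- b[pos] * 256L + b[pos + 1L]; pos <<- pos + 2L; v }
  u32 <- function() {
    need(4L)
    v <- ((b[pos] * 256 + b[pos + 1L]) * 256 + b[pos + 2L]) * 256 + b[pos + 3L]
    pos <<- pos + 4L
    v
  }
  vlq <- function() {
    v <- 0
    repeat {
      byte <- u8()
      v <- v * 128 + byte %% 128L
      if (byte < 128L) return(v)
    }
  }
  tag <- function() { need(4L); s <- rawToChar(as.raw(b[pos:(pos + 3L)])); pos <<- pos + 4L; s }

  if (tag() != "MThd") stop("not a Standard MIDI File (missing MThd)", call. = FALSE)
  hd_len <- u32()
  if (hd_len < 6) stop("corrupt MIDI file: bad header length", call. = FALSE)
  fmt <- u16()
  n_trk <- u16()
  division <- u16()
  pos <- pos + (hd_len - 6L)
  if (!fmt %in% c(0L, 1L))
    stop("unsupported SMF format ", fmt, " (only 0 and 1)", call. = FALSE)
  smpte <- division >= 32768L
  if (smpte) {
    fps <- 256L - division %/% 256L       # two's complement of high byte
    tpf <- division %% 256L
    sec_per_tick <- 1 / (fps * tpf)
  } else {
    ppq <- division
    if (ppq == 0) stop("corrupt MIDI file: zero ticks per quarter", call. = FALSE)
  }

  tracks <- vector("list", n_trk)
  tempo_ticks <- numeric(0)    # (tick, us-per-quarter) across all tracks
  tempo_uspq <- numeric(0)
  for (ti in seq_len(n_trk)) {
    if (tag() != "MTrk") stop("corrupt MIDI file: missing MTrk chunk", call. = FALSE)
    trk_len <- u32()
    trk_end <- pos + trk_len
    need(trk_len)
    tick <- 0
    status <- NA_integer_
    ev_tick <- numeric(0); ev_kind <- character(0)
    ev_note <- integer(0); ev_vel <- integer(0)
    while (pos < trk_end) {
      tick <- tick + vlq()
      byte <- u8()
      if (byte == 255L) {                       # meta event
        type <- u8(); len <- vlq()
        if (type == 81L && len == 3L) {
          need(3L)
          uspq <- (b[pos] * 256 + b[pos + 1L]) * 256 + b[pos + 2L]
          tempo_ticks <- c(tempo_ticks, tick)
          tempo_uspq <- c(tempo_uspq, uspq)
        }
        pos <- pos + len
      } else if (byte %in% c(240L, 247L)) {     # sysex
        len <- vlq(); pos <- pos + len
        status <- NA_integer_
      } else {
        if (byte >= 128L) {
          status <- byte
          d1 <- u8()
        } else {
          if (is.na(status))
            stop("corrupt MIDI file: data byte without running status", call. = FALSE)
          d1 <- byte
        }
        hi <- status %/% 16L
        d2 <- if (hi %in% c(12L, 13L)) NA_integer_ else u8()
        if (hi == 9L) {                         # note on (vel 0 == off)
          ev_tick <- c(ev_tick, tick)
          ev_kind <- c(ev_kind, if (d2 == 0L) "off" else "on")
          ev_note <- c(ev_note, d1)
          ev_vel <- c(ev_vel, if (d2 == 0L) NA_integer_ else d2)
        } else if (hi == 8L) {                  # note off
          ev_tick <- c(ev_tick, tick)
          ev_kind <- c(ev_kind, "off")
          ev_note <- c(ev_note, d1)
          ev_vel <- c(ev_vel, NA_integer_)
        }
      }
    }
    if (pos != trk_end)
      stop("corrupt MIDI file: track overruns its declared length", call. = FALSE)
    tracks[[ti]] <- data.frame(tick = ev_tick, kind = ev_kind,
                               note = ev_note, velocity = ev_vel)
  }

  if (smpte) {
    tick_to_sec <- function(tick) tick * sec_per_tick
  } else {
    # tempo map: piecewise-linear tick -> seconds
    ord <- order(tempo_ticks)
    tmap_tick <- c(0, tempo_ticks[ord])
    tmap_uspq <- c(500000, tempo_uspq[ord])     # default 120 BPM
    keep <- !duplicated(tmap_tick, fromLast = TRUE)
    tmap_tick <- tmap_tick[keep]; tmap_uspq <- tmap_uspq[keep]
    tmap_sec <- cumsum(c(0, diff(tmap_tick) *
                              tmap_uspq[-length(tmap_uspq)])) / 1e6 / ppq
    tick_to_sec <- function(tick) {
      i <- findInterval(tick, tmap_tick)
      tmap_sec[i] + (tick - tmap_tick[i]) * tmap_uspq[i] / 1e6 / ppq
    }
  }

  tracks <- tracks[vapply(tracks, nrow, 0L) > 0]
  if (merge_tracks && length(tracks) > 1) tracks <- list(do.call(rbind, tracks))
  many <- length(tracks) > 1
  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    trk <- tracks[[i]]
    out[[i]] <- session_record(
      data.frame(time = tick_to_sec(trk$tick), kind = trk$kind,
                 note = trk$note, velocity = trk$velocity),
      session_id = if (many) paste0(session_id, "_t", i) else session_id,
      ...)
  }
  out
}
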