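# Shared fixtures: sessions built from explicit intervals, random interval
# sets on a 1-ms grid, a brute-force grid oracle, and a byte-level Standard
# MIDI File builder.

interval_session <- function(onset, offset, note, velocity = 80,
                             t_end = NULL, id = "fixture", ...) {
  n <- length(onset)
  velocity <- rep_len(velocity, n)
  session_record(
    data.frame(time = c(onset, offset),
               kind = rep(c("on", "off"), c(n, n)),
               note = c(note, note),
               velocity = c(velocity, rep(NA_integer_, n))),
    session_id = id, t_end = t_end, ...)
}

# random intervals snapped to the 1-ms grid so the grid oracle is exact
random_intervals <- function(n = 6, t_max = 10) {
  onset <- round(stats::runif(n, 0, t_max - 0.1), 3)
  dur <- round(stats::runif(n, 0.005, 2), 3)
  data.frame(onset = onset, offset = pmin(round(onset + dur, 3), t_max),
             note = sample(28:103, n, replace = TRUE),
             velocity = sample(1:127, n, replace = TRUE))
}

# brute-force 1-ms discretization of the held-key count; samples segment
# midpoints so on-grid breakpoints are unambiguous
grid_oracle <- function(iv, step = 0.001) {
  t_max <- max(iv$offset)
  n_cell <- as.integer(round(t_max / step))
  counts <- integer(n_cell)
  for (i in seq_len(nrow(iv))) {
    j1 <- as.integer(round(iv$onset[i] / step)) + 1L
    j2 <- as.integer(round(iv$offset[i] / step))
    if (j2 >= j1) counts[j1:j2] <- counts[j1:j2] + 1L
  }
  list(union = step * sum(counts > 0),
       integral = step * sum(counts),
       max = max(counts),
       time_at_count = step * table(counts[counts > 0]))
}

# ---- Standard MIDI File bytes ------------------------------------------

vlq_bytes <- function(v) {
  out <- v %% 128
  v <- v %/% 128
  while (v > 0) {
    out <- c(v %% 128 + 128, out)
    v <- v %/% 128
  }
  as.raw(out)
}

u32b <- function(v) as.raw(c(v %/% 16777216, (v %/% 65536) %% 256,
                             (v %/% 256) %% 256, v %% 256))
u16b <- function(v) as.raw(c(v %/% 256, v %% 256))

ev_on <- function(delta, note, vel, ch = 0)
  list(delta = delta, bytes = c(0x90 + ch, note, vel))
ev_off <- function(delta, note, ch = 0)
  list(delta = delta, bytes = c(0x80 + ch, note, 64))
ev_tempo <- function(delta, uspq)
  list(delta = delta, bytes = c(0xFF, 0x51, 0x03, uspq %/% 65536,
                                (uspq %/% 256) %% 256, uspq %% 256))

smf_file <- function(tracks, ppq = 480, format = NULL, path = NULL) {
  if (is.null(format)) format <- if (length(tracks) > 1) 1 else 0
  trks <- lapply(tracks, function(evs) {
    body <- do.call(c, c(lapply(evs, function(e)
      c(vlq_bytes(e$delta), as.raw(e$bytes))), list(as.raw(NULL))))
    body <- c(body, vlq_bytes(0), as.raw(c(0xFF, 0x2F, 0x00)))
    c(charToRaw("MTrk"), u32b(length(body)), body)
  })
  if (is.null(path)) path <- tempfile(fileext = ".mid")
  writeBin(c(charToRaw("MThd"), u32b(6), u16b(format),
             u16b(length(tracks)), u16b(ppq),
             do.call(c, trks)), path)
  path
}
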