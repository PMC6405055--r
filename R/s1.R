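# Tolerant reader for deposited de-identified improvisation datasets whose
# exact text dialect (delimiter, column order, session segmentation) is not
# published. The reader infers the dialect, logs it, and refuses with an
# explicit "unrecognized dialect" error when the layout cannot be decoded.

S1_SYNONYMS <- list(
  session = c("session", "session_id", "sessionid", "improvisation",
              "improv", "sample", "trial", "recording"),
  participant = c("participant", "participant_id", "subject", "subject_id",
                  "id", "person"),
  task = c("task", "title", "notion", "emotion", "condition", "label"),
  gender = c("gender", "sex"),
  age = c("age", "age_years"),
  proficiency = c("proficiency", "musician", "training", "level",
                  "expertise", "profession"),
  time = c("time", "time_s", "timestamp", "t", "onset", "onset_s", "start"),
  kind = c("kind", "type", "event", "status", "onoff", "message"),
  note = c("note", "note_number", "notenumber", "pitch", "key", "midi_note"),
  velocity = c("velocity", "vel", "intensity", "loudness"),
  duration = c("duration", "duration_s", "dur", "length", "hold")
)

KIND_ON <- c("on", "noteon", "note_on", "note on", "press", "down", "1")
KIND_OFF <- c("off", "noteoff", "note_off", "note off", "release", "up", "0")

s1_norm_task <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("negative feeling", "negative_feeling")] <- "negative"
  x[x %in% c("positive feeling", "positive_feeling")] <- "positive"
  x
}

s1_norm_gender <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("m", "male")] <- "male"
  x[x %in% c("f", "female")] <- "female"
  x
}

s1_norm_proficiency <- function(x) {
  x <- tolower(trimws(x))
  x[grepl("^(lay|amateur|none)", x)] <- "layman"
  x[grepl("^(pro|musician|expert)", x)] <- "professional"
  x
}

#' Read a deposited improvisation dataset with dialect auto-detection
#'
#' Reads a plain-text table of keyboard improvisation events whose exact
#' layout is unknown: the delimiter (tab, comma, semicolon or whitespace),
#' the presence of a header, the column roles and the session segmentation
#' are all inferred from the file itself and reported. Column roles are
#' matched by name when a header is present (see the synonym sets in the
#' package source) and positionally otherwise. Sessions are delimited by a
#' session-id column, by blank lines, by a change of (participant, task),
#' or by a backwards jump of the time column, in that order of preference.
#'
#' @param path Path to the text file.
#' @param quiet Suppress the inferred-dialect message?
#' @return A [cohort()] with a `"dialect"` attribute describing the
#'   inference. Errors with an "unrecognized dialect" message listing the
#'   detected columns when the layout cannot be decoded.
#' @export
read_s1_dataset <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines)) lines[1] <- sub("^﻿", "", lines[1])
  blank <- !nzchar(trimws(lines))
  if (all(blank))
    stop("unrecognized dialect: file is empty", call. = FALSE)

  probe <- utils::head(lines[!blank], 200)
  delims <- c(tab = "\t", comma = ",", semicolon = ";")
  delim_counts <- vapply(delims, function(d)
    stats::median(lengths(regmatches(probe, gregexpr(d, probe, fixed = TRUE)))),
    0)
  if (any(delim_counts >= 1)) {
    delim_name <- names(which.max(delim_counts))
    delim <- delims[[delim_name]]
    split_fields <- function(l) trimws(strsplit(l, delim, fixed = TRUE)[[1]])
  } else {
    delim_name <- "whitespace"
    split_fields <- function(l) strsplit(trimws(l), "[ \t]+")[[1]]
  }

  fields <- vector("list", length(lines))
  fields[!blank] <- lapply(lines[!blank], split_fields)
  n_col <- max(lengths(fields))

  # header: first non-blank row whose cells match known column names
  first_row <- fields[!blank][[1]]
  header_hits <- tolower(gsub("[^a-z_ ]", "", tolower(first_row)))
  has_header <- mean(header_hits %in% unlist(S1_SYNONYMS)) >= 0.5
  body_idx <- which(!blank)
  if (has_header) body_idx <- body_idx[-1]

  cols <- rep(NA_character_, n_col)
  if (has_header) {
    for (role in names(S1_SYNONYMS))
      cols[is.na(cols) & header_hits %in% S1_SYNONYMS[[role]]] <- role
  } else {
    # positional inference from value patterns
    sample_rows <- fields[utils::head(body_idx, 500)]
    col_vals <- lapply(seq_len(n_col), function(j)
      vapply(sample_rows, function(r) if (length(r) >= j) r[j] else NA, ""))
    is_num <- vapply(col_vals, function(v)
      all(!is.na(suppressWarnings(as.numeric(v[!is.na(v)])))) &&
        any(!is.na(v)), TRUE)
    low <- lapply(col_vals, function(v) tolower(trimws(v)))
    for (j in seq_len(n_col)) {
      v <- low[[j]][!is.na(low[[j]])]
      if (is_num[j]) next
      if (all(v %in% c(KIND_ON, KIND_OFF))) cols[j] <- "kind"
      else if (all(s1_norm_task(v) %in%
                   c("ugly", "beautiful", "negative", "positive"))) cols[j] <- "task"
      else if (all(v %in% c("m", "f", "male", "female"))) cols[j] <- "gender"
      else if (all(grepl("^(lay|pro|amateur|musician|expert|none)", v)))
        cols[j] <- "proficiency"
    }
    num_idx <- which(is_num & is.na(cols))
    nums <- lapply(num_idx, function(j)
      suppressWarnings(as.numeric(col_vals[[j]])))
    # the time column is the most nearly nondecreasing numeric column
    # (session resets make it non-monotone overall)
    nondecr <- vapply(nums, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(0)
      mean(diff(v) >= 0)
    }, 0)
    if (length(nondecr) && max(nondecr) > 0.7) {
      cols[num_idx[which.max(nondecr)]] <- "time"
      num_idx <- which(is_num & is.na(cols))
    }
    int127 <- vapply(num_idx, function(j) {
      v <- suppressWarnings(as.numeric(col_vals[[j]])); v <- v[!is.na(v)]
      length(v) > 0 && all(v == floor(v) & v >= 0 & v <= 127)
    }, TRUE)
    hit <- num_idx[int127]
    if (length(hit) >= 1 && is.na(match("note", cols))) cols[hit[1]] <- "note"
    if (length(hit) >= 2) cols[hit[2]] <- "velocity"
    if (!"kind" %in% cols) {
      spare <- which(is_num & is.na(cols))
      if (length(spare)) cols[spare[1]] <- "duration"
    }
  }

  found <- stats::setNames(match(names(S1_SYNONYMS), cols), names(S1_SYNONYMS))
  describe <- paste(stats::na.omit(paste0(cols, "@", seq_along(cols))[!is.na(cols)]),
                    collapse = ", ")
  if (is.na(found["time"]) || is.na(found["note"]) ||
      (is.na(found["kind"]) && is.na(found["duration"])))
    stop("unrecognized dialect: need time, note and kind-or-duration ",
         "columns; detected columns: ",
         if (nzchar(describe)) describe else "(none)", call. = FALSE)

  getcol <- function(r, role) {
    j <- found[[role]]
    if (is.na(j) || length(r) < j) NA_character_ else r[j]
  }

  # session segmentation
  rows <- fields[body_idx]
  if (!is.na(found["session"])) {
    seg <- vapply(rows, getcol, "", "session")
    segmentation <- "session-id column"
  } else if (any(blank[min(body_idx):max(body_idx)])) {
    seg <- cumsum(blank)[body_idx]
    segmentation <- "blank-line blocks"
  } else {
    pt <- paste(vapply(rows, getcol, "", "participant"),
                vapply(rows, getcol, "", "task"))
    if (length(unique(pt)) > 1) {
      seg <- cumsum(c(TRUE, pt[-1] != pt[-length(pt)]))
      segmentation <- "participant/task change"
    } else {
      tm <- suppressWarnings(as.numeric(vapply(rows, getcol, "", "time")))
      seg <- cumsum(c(TRUE, diff(tm) < -1e-9))
      segmentation <- "time reset"
    }
  }

  groups <- split(rows, factor(seg, levels = unique(seg)))
  sessions <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rs <- groups[[g]]
    tm <- as.numeric(vapply(rs, getcol, "", "time"))
    note <- as.integer(as.numeric(vapply(rs, getcol, "", "note")))
    vel <- suppressWarnings(as.numeric(vapply(rs, getcol, "", "velocity")))
    if (all(is.na(vel))) vel <- rep(64L, length(tm))  # no velocity column
    tm <- tm - min(tm, na.rm = TRUE)                  # per-session clock
    if (!is.na(found["kind"])) {
      kind_raw <- tolower(vapply(rs, getcol, "", "kind"))
      kind <- ifelse(kind_raw %in% KIND_OFF, "off", "on")
      kind[kind == "on" & !is.na(vel) & vel == 0] <- "off"
      vel[kind == "off"] <- NA
      ev <- data.frame(time = tm, kind = kind, note = note, velocity = vel)
    } else {
      dur <- as.numeric(vapply(rs, getcol, "", "duration"))
      ev <- data.frame(
        time = c(tm, tm + pmax(dur, 1e-6)),
        kind = rep(c("on", "off"), each = length(tm)),
        note = c(note, note),
        velocity = c(vel, rep(NA_real_, length(tm))))
    }
    meta1 <- function(role, norm = identity) {
      v <- vapply(rs, getcol, "", role)
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v)) norm(v[1]) else NA_character_
    }
    sid <- meta1("session")
    if (is.na(sid)) sid <- sprintf("session_%03d", g)
    sessions[[g]] <- session_record(
      ev, session_id = sid,
      participant_id = meta1("participant"),
      task = meta1("task", s1_norm_task),
      gender = meta1("gender", s1_norm_gender),
      age = suppressWarnings(as.numeric(meta1("age"))),
      proficiency = meta1("proficiency", s1_norm_proficiency))
  }
  ids <- vapply(sessions, `[[`, "", "session_id")
  if (anyDuplicated(ids))
    for (g in seq_along(sessions))
      sessions[[g]]$session_id <- sprintf("%s_%03d", ids[g], g)

  out <- cohort(sessions)
  dialect <- list(delimiter = delim_name, header = has_header,
                  columns = cols, segmentation = segmentation)
  attr(out, "dialect") <- dialect
  if (!quiet)
    message(sprintf(
      "read_s1_dataset: %d sessions; delimiter=%s, header=%s, columns=[%s], segmentation=%s",
      length(out), delim_name, has_header,
      paste(ifelse(is.na(cols), ".", cols), collapse = ","), segmentation))
  out
}
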