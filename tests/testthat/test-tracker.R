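test_that("on/off pairing is per-note FIFO", {
  ev <- raw_events(time = c(0, 1), kind = c("on", "off"),
                   note = c(60, 60), velocity = c(80, NA))
  iv <- pair_events(ev)
  expect_equal(iv$onset, 0)
  expect_equal(iv$offset, 1)
  expect_equal(iv$velocity, 80L)

  # overlapping re-press of the same note: first off closes first on
  ev <- raw_events(time = c(0, 0.5, 1, 2), kind = c("on", "on", "off", "off"),
                   note = rep(60, 4), velocity = c(80, 90, NA, NA))
  iv <- pair_events(ev)
  expect_equal(iv$onset, c(0, 0.5))
  expect_equal(iv$offset, c(1, 2))
  expect_equal(iv$velocity, c(80L, 90L))
})

test_that("dangling note-ons close at t_end and unmatched offs are dropped, with warnings", {
  ev <- raw_events(time = 0, kind = "on", note = 60, velocity = 80)
  expect_warning(iv <- pair_events(ev, t_end = 3), "dangling")
  expect_equal(iv$offset, 3)

  ev <- raw_events(time = c(0, 0.5, 1), kind = c("off", "on", "off"),
                   note = c(64, 60, 60), velocity = c(NA, 80, NA))
  expect_warning(iv <- pair_events(ev), "unmatched")
  expect_equal(nrow(iv), 1)
  expect_equal(iv$note, 60L)
})

test_that("playing time is the measure of the interval union", {
  iv <- data.frame(onset = c(0, 2), offset = c(1, 3),
                   note = c(60L, 62L), velocity = 80L)
  expect_equal(playing_time(iv), 2)
  iv <- data.frame(onset = c(0, 0), offset = c(1, 1),
                   note = c(60L, 62L), velocity = 80L)
  expect_equal(playing_time(iv), 1)
  iv <- data.frame(onset = c(0, 1), offset = c(2, 3),
                   note = c(60L, 62L), velocity = 80L)
  expect_equal(playing_time(iv), 3)
  expect_equal(playing_time(iv[0, ]), 0)
})

test_that("the held timeline enumerates maximal constant-count segments", {
  iv <- data.frame(onset = c(0, 1), offset = c(2, 3),
                   note = c(60L, 62L), velocity = 80L)
  tl <- held_timeline(iv)
  expect_equal(tl$breakpoints, c(0, 1, 2, 3))
  expect_equal(tl$counts, c(1, 2, 1))
  expect_equal(improv:::timeline_integral(tl), 4)   # = sum of durations

  expect_equal(held_timeline(iv[0, ])$counts, 0)

  iv10 <- data.frame(onset = rep(0, 10), offset = rep(1, 10),
                     note = 50:59, velocity = 80L)
  expect_equal(max(held_timeline(iv10)$counts), 10)

  # an offset coincident with an onset merges, no zero-width spike
  iv <- data.frame(onset = c(0, 1), offset = c(1, 2),
                   note = c(60L, 62L), velocity = 80L)
  tl <- held_timeline(iv)
  expect_equal(tl$breakpoints, c(0, 2))
  expect_equal(tl$counts, 1)
})

test_that("playing time and held timeline agree with the grid oracle on random intervals", {
  set.seed(42)
  for (rep in 1:50) {
    iv <- random_intervals(sample(1:8, 1))
    oracle <- grid_oracle(iv)
    tl <- held_timeline(iv)
    expect_equal(playing_time(iv), oracle$union, tolerance = 1e-9)
    expect_equal(improv:::timeline_integral(tl), oracle$integral,
                 tolerance = 1e-9)
    expect_equal(max(tl$counts), oracle$max)
    # playing time also equals the time the count is positive
    pos <- tl$counts > 0
    expect_equal(sum(diff(tl$breakpoints)[pos]), playing_time(iv),
                 tolerance = 1e-9)
  }
})

test_that("chord grouping joins onsets within the window of the group leader", {
  iv <- data.frame(onset = c(0, 0.01, 1), offset = c(0.5, 0.6, 1.5),
                   note = c(60L, 64L, 67L), velocity = 80L)
  sq <- onset_sequence(iv, chord_window = 0.03)
  expect_equal(unique(sq$chord), c(1L, 2L))
  expect_equal(sum(sq$chord == 1), 2)
  sq0 <- onset_sequence(iv, chord_window = 0)
  expect_equal(sq0$chord, 1:3)
  expect_equal(nrow(onset_sequence(iv[0, ], 0.03)), 0)
})

test_that("the state trace alternates Idle/Playing with the held count and tracks extrema", {
  s <- interval_session(1, 2, 60, velocity = 50, t_end = 3)
  tr <- state_trace(s)
  expect_equal(tr$states$time, c(0, 1, 2))
  expect_equal(tr$states$state, c("Idle", "Playing", "Idle"))

  s2 <- interval_session(c(0, 1), c(1, 2), c(60, 64), velocity = c(50, 90),
                         t_end = 2)
  tr2 <- state_trace(s2)
  expect_equal(tr2$extrema$max_intensity,
               unname(c(dynamics_level(50), dynamics_level(90))))
  expect_equal(tr2$extrema$min_intensity,
               unname(rep(dynamics_level(50), 2)))

  empty <- session_record(raw_events(), "empty", t_end = 5)
  tr3 <- state_trace(empty)
  expect_equal(tr3$states$state, "Idle")
})

test_that("session length categories are cohort quintiles", {
  sessions <- lapply(1:10, function(i)
    interval_session(0, i, 60, t_end = i, id = paste0("s", i)))
  lab <- session_length_category(cohort(sessions))
  expect_equal(unname(lab[1]), "extremely_short")
  expect_equal(unname(lab[10]), "extremely_long")
  expect_equal(length(unique(lab)), 5)
})
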