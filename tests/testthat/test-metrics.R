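test_that("time metrics follow directly from session bounds and the union", {
  # 100-s session: notes cover [22.2, 85.2) -> 63 s union, start 22.2 s
  s <- interval_session(c(22.2, 40), c(70, 85.2), c(60, 64), t_end = 100)
  tm <- compute_time_metrics(s)
  expect_equal(tm$pct_playing_time, 63)
  expect_equal(tm$pct_idle_time, 37)
  expect_equal(tm$start_time_s, 22.2)
  expect_equal(tm$pct_start_time, 22.2)
  expect_equal(tm$total_session_min, 100 / 60)

  silent <- session_record(raw_events(), "silent", t_end = 10)
  tm0 <- compute_time_metrics(silent)
  expect_equal(tm0$pct_playing_time, 0)
  expect_equal(tm0$pct_idle_time, 100)
  expect_true(is.na(tm0$start_time_s))

  whole <- interval_session(0, 10, 60, t_end = 10)
  tmw <- compute_time_metrics(whole)
  expect_equal(tmw$pct_playing_time, 100)
  expect_equal(tmw$pct_start_time, 0)

  expect_error(compute_time_metrics(session_record(raw_events(), "z",
                                                   t_end = 0)),
               "zero-length")
})

test_that("the concurrent metric is the held-count integral over the union", {
  two <- interval_session(c(0, 0), c(10, 10), c(60, 64), t_end = 10)
  expect_equal(compute_concurrent_metric(two), 200)
  three <- interval_session(c(0, 0, 0), c(10, 10, 10), c(60, 64, 67),
                            t_end = 10)
  expect_equal(compute_concurrent_metric(three), 300)
  stagger <- interval_session(c(0, 1), c(2, 3), c(60, 64), t_end = 3)
  expect_equal(compute_concurrent_metric(stagger), 100 * 4 / 3)
  expect_true(is.na(compute_concurrent_metric(
    session_record(raw_events(), "s", t_end = 1))))
})

test_that("key metrics count presses, distinct keys and colors", {
  s <- interval_session(c(0, 1, 2), c(1, 4, 3), c(60, 60, 61), t_end = 4)
  km <- compute_key_metrics(s)
  expect_equal(km$n_presses, 3)
  expect_equal(km$pct_keys_used, 100 * 2 / 76)
  expect_equal(km$presses_per_key, 1.5)
  expect_equal(km$pct_black_presses, 100 / 3)
  expect_equal(km$pct_white_presses, 200 / 3)
  expect_equal(km$play_per_key_s, (1 + 3 + 1) / 3)

  km0 <- compute_key_metrics(session_record(raw_events(), "s", t_end = 1))
  expect_equal(km0$n_presses, 0)
  expect_true(is.na(km0$presses_per_key))
})

test_that("profiles weight histograms by note-sounding time with ties to the lower bin", {
  one <- interval_session(0, 1, 60, velocity = 80, t_end = 1)
  pr <- compute_profiles(one)
  expect_equal(unname(pr$octave_hist["4"]), 100)
  expect_equal(sum(pr$octave_hist), 100)
  expect_equal(unname(pr$intensity_hist[unname(dynamics_level(80))]), 100)

  # C for 2 s, G for 1 s
  cg <- interval_session(c(0, 2), c(2, 3), c(60, 67), t_end = 3)
  pr2 <- compute_profiles(cg)
  expect_equal(unname(pr2$pitch_class_pct["C"]), 200 / 3)
  expect_equal(unname(pr2$pitch_class_pct["G"]), 100 / 3)

  # equal durations, velocities 30 and 120: most-used intensity tie -> lower
  tie <- interval_session(c(0, 1), c(1, 2), c(60, 62),
                          velocity = c(30, 120), t_end = 2)
  pr3 <- compute_profiles(tie)
  expect_equal(pr3$intensity_min, unname(dynamics_level(30)))
  expect_equal(pr3$intensity_max, unname(dynamics_level(120)))
  expect_equal(pr3$intensity_most_used, unname(dynamics_level(30)))
})

test_that("press-weighted averages ignore durations; duration-weighted modes ignore scaling", {
  s <- interval_session(c(0, 1), c(1, 3), c(60, 72), velocity = c(40, 100),
                        t_end = 3)
  pr <- compute_profiles(s)
  expect_equal(pr$intensity_avg,
               mean(unname(dynamics_level(c(40, 100)))))
  expect_equal(pr$octave_avg, mean(c(4, 5)))
  # doubling every duration changes neither averages nor modes
  s2 <- interval_session(c(0, 2), c(2, 6), c(60, 72), velocity = c(40, 100),
                         t_end = 6)
  pr2 <- compute_profiles(s2)
  expect_equal(pr2$intensity_avg, pr$intensity_avg)
  expect_equal(pr2$octave_most_used, pr$octave_most_used)
  expect_equal(pr2$intensity_most_used, pr$intensity_most_used)
})

test_that("cluster metrics segment the held timeline", {
  s <- interval_session(c(0, 1), c(2, 3), c(60, 64), t_end = 3)
  cm <- compute_cluster_metrics(s)
  expect_equal(cm$cluster_instances, 3)
  expect_equal(cm$cluster_max, 2)
  expect_equal(cm$cluster_mode, 1)
  expect_equal(cm$pct_time_cluster_mode, 200 / 3)

  single <- interval_session(0, 1, 60, t_end = 1)
  cs <- compute_cluster_metrics(single)
  expect_equal(cs$cluster_instances, 1)
  expect_equal(cs$pct_time_cluster_mode, 100)

  eleven <- interval_session(rep(0, 11), rep(1, 11), 50:60, t_end = 1)
  expect_equal(compute_cluster_metrics(eleven)$cluster_max, 11)
})

test_that("transition metrics classify consecutive presses and IOI pairs", {
  s <- interval_session(c(0, 1, 2), c(0.5, 1.5, 2.5), c(60, 62, 64),
                        velocity = c(50, 60, 60), t_end = 3)
  tr <- compute_transition_metrics(s)
  expect_equal(tr$pct_crescendo, 50)
  expect_equal(tr$pct_same_intensity, 50)
  expect_equal(tr$pct_diminuendo, 0)

  # onsets 0, 1, 3: IOIs (1, 2) -> ritardando (ties would count there too)
  s2 <- interval_session(c(0, 1, 3), c(0.5, 1.5, 3.5), c(60, 62, 64),
                         t_end = 4)
  tr2 <- compute_transition_metrics(s2)
  expect_equal(tr2$pct_ritardando, 100)
  expect_equal(tr2$pct_accelerando, 0)

  # colors W B W
  s3 <- interval_session(c(0, 1, 2), c(0.5, 1.5, 2.5), c(60, 61, 62),
                         t_end = 3)
  tr3 <- compute_transition_metrics(s3)
  expect_equal(tr3$pct_wb, 50)
  expect_equal(tr3$pct_bw, 50)
  expect_equal(tr3$pct_ww, 0)
  expect_equal(tr3$pct_bb, 0)

  one <- interval_session(0, 1, 60, t_end = 1)
  expect_true(is.na(compute_transition_metrics(one)$pct_crescendo))
  two <- interval_session(c(0, 1), c(0.5, 1.5), c(60, 62), t_end = 2)
  expect_true(is.na(compute_transition_metrics(two)$pct_accelerando))
})

test_that("percentage identities hold across seeded synthetic sessions", {
  for (seed in 1:60) {
    s <- sample_session(seed = seed, session_id = paste0("s", seed))
    m <- compute_session_metrics(s)
    expect_equal(m$pct_playing_time + m$pct_idle_time, 100)
    if (m$n_presses > 0) {
      expect_equal(m$pct_black_presses + m$pct_white_presses, 100)
      expect_gte(m$pct_concurrent, 100)
      expect_equal(sum(m$pitch_class_pct), 100)
      expect_equal(sum(m$octave_hist), 100)
      expect_equal(sum(m$intensity_hist), 100)
      expect_gte(m$cluster_max, m$cluster_mode)
      expect_gte(m$cluster_mode, 1)
    }
    if (m$n_presses >= 2)
      expect_equal(m$pct_crescendo + m$pct_diminuendo + m$pct_same_intensity,
                   100)
    if (m$n_presses >= 3) {
      expect_equal(m$pct_accelerando + m$pct_ritardando, 100)
      expect_equal(m$pct_ww + m$pct_wb + m$pct_bw + m$pct_bb, 100)
    }
  }
})

test_that("concurrency is exactly 100 iff no two intervals overlap", {
  s <- interval_session(c(0, 1, 2.5), c(1, 2, 3), c(60, 62, 64), t_end = 3)
  expect_equal(compute_concurrent_metric(s), 100)
  s2 <- interval_session(c(0, 0.5), c(1, 2), c(60, 62), t_end = 2)
  expect_gt(compute_concurrent_metric(s2), 100)
})

test_that("aggregation computes M and SEM with pairwise missing exclusion", {
  sessions <- lapply(1:4, function(i)
    interval_session(0, 1, 60, velocity = 80, t_end = 2,
                     id = paste0("s", i), task = "ugly"))
  mt <- metrics_table(cohort(sessions))
  ag <- aggregate_metrics(mt, by = "task", params = "pct_playing_time")
  expect_equal(ag$mean, 50)
  expect_equal(ag$sem, 0)     # identical sessions
  expect_equal(ag$n, 4)

  # values {1, 3}: M = 2, SEM = sd/sqrt(2) = 1
  mt2 <- data.frame(session_id = c("a", "b"), task = "x",
                    v = c(1, 3))
  attr(mt2, "metric_cols") <- "v"
  ag2 <- aggregate_metrics(mt2, by = "task")
  expect_equal(ag2$mean, 2)
  expect_equal(ag2$sem, 1)

  # missing values are excluded per parameter
  mt3 <- data.frame(session_id = c("a", "b", "c"), task = "x",
                    v = c(1, 3, NA))
  attr(mt3, "metric_cols") <- "v"
  ag3 <- aggregate_metrics(mt3, by = "task")
  expect_equal(ag3$n, 2)
  expect_equal(ag3$mean, 2)
})

test_that("built-in groupings: valence collapse and median age split", {
  mt <- data.frame(session_id = letters[1:8],
                   task = c("ugly", "negative", "beautiful", "positive",
                            "ugly", "negative", "beautiful", "positive"),
                   age = c(20, 25, 27, 28, 29, 35, 50, 77),
                   v = 1:8)
  attr(mt, "metric_cols") <- "v"
  val <- improv:::grouping_labels(mt, "valence")
  expect_equal(val[1:2], rep("negative_valence", 2))
  expect_equal(val[3:4], rep("positive_valence", 2))
  ages <- improv:::grouping_labels(mt, "age")   # median 28.5 -> 4 young, 4 old
  expect_equal(sum(ages == "old"), 4)
  expect_equal(ages[4], "young")                # at/below median is young
  expect_error(aggregate_metrics(mt, by = factor(rep("g1", 8),
                                                 levels = c("g1", "g2"))),
               "empty group: g2")
})
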