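test_that("DTW handles the textbook base cases", {
  expect_equal(dtw_distance(c(0), c(1)), 1)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  set.seed(2)
  v <- rnorm(30)
  expect_equal(dtw_distance(v, v), 0)
  expect_error(dtw_distance(numeric(0), 1), "empty")
})

test_that("DTW equals exhaustive path enumeration on short vectors", {
  set.seed(12)
  for (i in 1:60) {
    a <- rnorm(sample(1:8, 1))
    b <- rnorm(sample(1:8, 1))
    expect_equal(dtw_distance(a, b), dtw_enumerate(a, b), tolerance = 1e-12)
  }
})

test_that("DTW is symmetric and bounded by the diagonal path", {
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_lte(dtw_distance(a, b), sum((a - b)^2) + 1e-12)
  }
})

test_that("beat distances localise differences to the changed segment", {
  sim <- synthesize_record(n_leads = 1, duration = 10, seed = 17)
  x <- bandpass_filter(sim$record)$signals[, 1]
  beats <- segment_lead(x, 257)
  b1 <- beats[2, ]; b2 <- beats[3, ]
  expect_equal(beat_distance(x, b1, b1), 0)
  expect_equal(beat_distance(x, b1, b2), beat_distance(x, b2, b1))
  # make the second beat's P/PR samples an exact copy of the first's,
  # so only the QT term can contribute
  y <- x
  b2s <- b2
  b2s$p_onset <- b2$q - (b1$q - b1$p_onset)
  b2s$p_peak <- b2s$p_onset + (b1$p_peak - b1$p_onset)
  b2s$p_end <- b2s$p_onset + (b1$p_end - b1$p_onset)
  y[(b2s$p_onset + 1):b2s$q] <- x[(b1$p_onset + 1):b1$q]
  d_all <- beat_distance(y, b1, b2s)
  d_qt <- dtw_distance(
    znormalize(y[(b1$q + 1):b1$t_end]),
    znormalize(y[(b2s$q + 1):b2s$t_end]))
  expect_equal(d_all, d_qt, tolerance = 1e-10)
})

test_that("the distance matrix matches a direct double-loop recomputation", {
  sim <- synthesize_record(n_leads = 1, duration = 10, seed = 18)
  x <- bandpass_filter(sim$record)$signals[, 1]
  beats <- segment_lead(x, 257)[1:5, ]
  nnd <- nearest_neighbor_distances(x, beats)
  expect_equal(diag(nnd$distances), rep(0, 5))
  expect_equal(nnd$distances, t(nnd$distances))
  for (i in 1:5) {
    for (j in 1:5) {
      if (i == j) next
      expect_equal(nnd$distances[i, j],
                   beat_distance(x, beats[i, ], beats[j, ]),
                   tolerance = 1e-10)
    }
    expect_equal(nnd$nearest_neighbor[i], min(nnd$distances[i, -i]))
  }
  expect_error(nearest_neighbor_distances(x, beats[1, ]), "two beats")
})

test_that("adding a duplicate beat never hurts nearest neighbours", {
  sim <- synthesize_record(n_leads = 1, duration = 10, seed = 19)
  x <- bandpass_filter(sim$record)$signals[, 1]
  beats <- segment_lead(x, 257)
  base <- nearest_neighbor_distances(x, beats[1:4, ])
  ext <- nearest_neighbor_distances(x, beats[c(1:4, 2), ])
  expect_true(all(ext$nearest_neighbor[1:4] <= base$nearest_neighbor + 1e-12))
})

test_that("the mean-plus-sd threshold follows its closed form", {
  expect_equal(anomaly_threshold(c(0, 0, 0, 0)), 0)
  expect_equal(anomaly_threshold(c(1, 1, 1, 5)), 4)  # mean 2 + sd 2
  expect_equal(anomaly_threshold(rep(3.2, 6)), 3.2)
  expect_error(anomaly_threshold(1), "two")
})

test_that("flagging uses a strict comparison", {
  nn <- c(0.1, 0.1, 0.1, 9)
  expect_equal(flag_new_anomalies(nn, anomaly_threshold(nn)), 4L)
  expect_length(flag_new_anomalies(rep(2, 5), anomaly_threshold(rep(2, 5))), 0)
  expect_length(flag_new_anomalies(nn, Inf), 0)
})

test_that("candidate shifting snaps to the nearest cycle anchors", {
  beats <- data.frame(p_onset = c(100, 400, 700), t_end = c(250, 550, 850))
  # a beat span is a fixed point
  expect_equal(unname(shift_candidate(c(400, 550), beats)), c(400, 550))
  # small offsets snap back to the same beat
  expect_equal(unname(shift_candidate(c(393, 561), beats)), c(400, 550))
  # an inverted snap falls outward to the enclosing beat
  expect_equal(unname(shift_candidate(c(560, 690), beats)), c(400, 550))
  # equidistant anchors resolve to the earlier one
  expect_equal(unname(shift_candidate(c(250, 400), beats)), c(100, 250))
  expect_error(shift_candidate(c(0, 1), beats[0, ]), "no beats")
})

test_that("detection is a pure function of the record", {
  sim <- study_record(23, n_leads = 4)
  r1 <- detect_anomalies(sim$record)
  r2 <- detect_anomalies(sim$record)
  expect_identical(r1$record_intervals, r2$record_intervals)
  expect_identical(r1$flagged_beats, r2$flagged_beats)
  expect_identical(r1$cleanest_lead, r2$cleanest_lead)
})

test_that("record-level intervals are whole beat spans", {
  sim <- study_record(24, n_leads = 4)
  res <- detect_anomalies(sim$record)
  spans <- beat_spans(res$beats)
  for (i in seq_len(nrow(res$record_intervals))) {
    expect_true(any(spans$start == res$record_intervals$start[i] &
                    spans$end == res$record_intervals$end[i]))
  }
  if (nrow(res$record_intervals) > 1) {
    expect_true(all(diff(res$record_intervals$start) > 0))
  }
})

test_that("a single-lead PVC is found without false alarms", {
  sim <- synthesize_record(n_leads = 1, duration = 10, seed = 26)
  sim <- inject_anomaly(sim, 5)
  res <- detect_anomalies(sim$record)
  tb <- sim$truth$beats
  pvc <- which(tb$label == "anomalous")
  expect_equal(nrow(res$record_intervals), 1)
  expect_lte(res$record_intervals$start[1], tb$m_s[pvc])
  expect_gte(res$record_intervals$end[1], tb$m_e[pvc])
  expect_gte(res$record_intervals$start[1], tb$r_s[pvc])
  expect_lte(res$record_intervals$end[1], tb$r_e[pvc])
})
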