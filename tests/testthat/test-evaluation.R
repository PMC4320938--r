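test_that("overlapping ratio is the covered fraction of the truth beat", {
  expect_equal(overlapping_ratio(c(100, 200), c(100, 200)), 100)
  expect_equal(overlapping_ratio(c(100, 200), c(150, 250)), 50)
  expect_equal(overlapping_ratio(c(100, 200), c(300, 400)), 0)
  # fragmented detections accumulate without double counting
  expect_equal(overlapping_ratio(c(0, 100),
                                 intervals(c(0, 50, 40), c(30, 80, 60))),
               70)
  expect_error(overlapping_ratio(c(5, 5), c(0, 10)), "empty")
})

test_that("threshold matching distinguishes 0% from positive thresholds", {
  expect_true(matches_threshold(0.04, 0))    # a single overlapped point
  expect_false(matches_threshold(0, 0))
  expect_false(matches_threshold(79.9, 80))
  expect_true(matches_threshold(80, 80))
  expect_true(matches_threshold(30, 30))
})

test_that("the cardiologist criterion needs full morphology, no bleed", {
  beat <- list(m_s = 100, m_e = 200, r_s = 60, r_e = 260)
  expect_true(matches_cardiologist(c(100, 200), beat))
  expect_true(matches_cardiologist(c(60, 259), beat))
  expect_false(matches_cardiologist(c(59, 200), beat))   # covers neighbour
  expect_false(matches_cardiologist(c(101, 200), beat))  # misses onset
  expect_false(matches_cardiologist(c(100, 261), beat))
})

test_that("AoD averages per-beat overlap and is NA without anomalies", {
  truth <- data.frame(label = c("anomalous", "anomalous", "normal"),
                      m_s = c(0, 1000, 2000), m_e = c(500, 2000, 2500),
                      r_s = c(0, 900, 1900), r_e = c(600, 2100, 2600))
  det <- intervals(c(0, 1018), c(500, 2000))
  expect_equal(aod(truth, det), mean(c(100, 98.2)))
  expect_equal(aod(truth, intervals(c(0, 1000), c(500, 2000))), 100)
  expect_equal(aod(truth, intervals()), 0)
  expect_true(is.na(aod(truth[3, ], det)))
})

test_that("confusion counts follow the beat-level interpretation", {
  k <- 10
  truth <- data.frame(label = c("anomalous", rep("normal", 9)),
                      m_s = (0:9) * 100, m_e = (0:9) * 100 + 80)
  truth$r_s <- truth$m_s - 10
  truth$r_e <- truth$m_e + 10
  cc <- confusion(truth, intervals(0, 80))
  expect_equal(cc, list(tp = 1, fn = 0, fp = 0, tn = 9))
  cc2 <- confusion(truth, intervals(c(0, 300), c(80, 380)))
  expect_equal(cc2, list(tp = 1, fn = 0, fp = 1, tn = 8))
  cc3 <- confusion(truth, intervals())
  expect_equal(cc3, list(tp = 0, fn = 1, fp = 0, tn = 9))
  # a detection touching no beat at all is still one false alarm
  cc4 <- confusion(truth, intervals(85, 95))
  expect_equal(cc4$fp, 1)
})

test_that("rates follow their formulas and honour NA denominators", {
  c1 <- list(tp = 1, fn = 0, fp = 0, tn = 9)
  expect_equal(sensitivity(c1), 100)
  expect_equal(specificity(c1), 100)
  expect_equal(ppv(c1), 100)
  expect_equal(false_alarm_rate(c1), 0)
  c2 <- list(tp = 1, fn = 0, fp = 1, tn = 8)
  expect_equal(ppv(c2), 50)
  expect_equal(false_alarm_rate(c2), 100 / 9)
  c3 <- list(tp = 0, fn = 0, fp = 0, tn = 5)
  expect_true(is.na(sensitivity(c3)))
  expect_true(is.na(ppv(c3)))
})

test_that("metrics agree with brute-force recomputation on random instances", {
  for (seed in 1:200) {
    inst <- random_truth_instance(seed)
    truth <- inst$truth; det <- inst$detections
    for (crit in list(list(type = "threshold", t = 0),
                      list(type = "threshold", t = 40),
                      list(type = "cardiologist"))) {
      cc <- confusion(truth, det, crit)
      # brute force: reclassify each beat independently
      match1 <- function(d, b) {
        if (crit$type == "cardiologist") {
          d[1] <= truth$m_s[b] && d[2] >= truth$m_e[b] &&
            d[1] >= truth$r_s[b] && d[2] <= truth$r_e[b]
        } else {
          ov <- max(0, min(d[2], truth$m_e[b]) - max(d[1], truth$m_s[b]))
          pct <- ov / (truth$m_e[b] - truth$m_s[b]) * 100
          if (crit$t == 0) pct > 0 else pct >= crit$t
        }
      }
      dl <- lapply(seq_len(nrow(det)),
                   function(i) c(det$start[i], det$end[i]))
      anom <- which(truth$label == "anomalous")
      tp <- sum(vapply(anom, function(b) {
        any(vapply(dl, match1, logical(1), b = b))
      }, logical(1)))
      used <- vapply(dl, function(d) {
        any(vapply(anom, function(b) match1(d, b), logical(1)))
      }, logical(1))
      norm <- which(truth$label == "normal")
      fp_beats <- vapply(norm, function(b) {
        any(vapply(dl[!used], function(d) {
          min(d[2], truth$m_e[b]) > max(d[1], truth$m_s[b])
        }, logical(1)))
      }, logical(1))
      stray <- sum(vapply(dl[!used], function(d) {
        !any(vapply(seq_len(nrow(truth)), function(b) {
          min(d[2], truth$m_e[b]) > max(d[1], truth$m_s[b])
        }, logical(1)))
      }, logical(1)))
      expect_equal(cc$tp, tp)
      expect_equal(cc$fn, length(anom) - tp)
      expect_equal(cc$fp, sum(fp_beats) + stray)
      expect_equal(cc$tn, length(norm) - sum(fp_beats))
      # complementarity holds identically
      if (cc$tn + cc$fp > 0) {
        expect_equal(specificity(cc) + false_alarm_rate(cc), 100)
      }
    }
  }
})

test_that("evaluation reports cover all requested criteria", {
  truth <- data.frame(label = c("anomalous", "normal"),
                      m_s = c(0, 100), m_e = c(50, 150),
                      r_s = c(0, 60), r_e = c(60, 160))
  rep <- evaluate_detection(truth, intervals(0, 50))
  expect_named(rep$criteria, c("overlap_0", "overlap_30", "overlap_40",
                               "overlap_80", "cardiologist"))
  expect_equal(rep$aod, 100)
  expect_equal(rep$criteria$cardiologist$tp, 1)
  expect_output(print(rep), "AoD")
})
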