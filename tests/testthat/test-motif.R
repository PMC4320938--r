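test_that("starting length follows the systolic-third rule", {
  expect_equal(starting_length(360), 200)
  expect_equal(starting_length(257), 143)
  expect_error(starting_length(0), "positive")
  expect_error(starting_length(-100), "positive")
})

test_that("z-normalisation centres, scales and is idempotent", {
  z <- znormalize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(znormalize(c(5, 5, 5, 5)), rep(0, 4))
  set.seed(11)
  w <- rnorm(40, sd = 4) + 2
  expect_equal(mean(znormalize(w)), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(znormalize(w)^2)), 1, tolerance = 1e-12)
  expect_equal(znormalize(znormalize(w)), znormalize(w), tolerance = 1e-12)
})

test_that("subsequence extraction slides by one sample", {
  expect_equal(length(extract_subsequences(rnorm(10), 10)$starts), 1)
  sub <- extract_subsequences(rnorm(10), 4)
  expect_equal(sub$starts, 0:6)
  expect_equal(nrow(sub$values), 7)
  expect_error(extract_subsequences(rnorm(10), 11), "exceeds")
})

test_that("the motif candidate is the closest non-overlapping pair", {
  # exact duplicate windows dominate
  set.seed(40)
  x <- rnorm(40, sd = 0.4)
  tpl <- c(0, 2, 5, 2, 0.5, -1)
  x[3 + 1:6] <- tpl
  x[25 + 1:6] <- tpl
  x[14 + 1:6] <- c(1, -3, 2, 2, 0, 4)
  sub <- extract_subsequences(x, 6)
  cand <- find_motif_candidate(sub)
  expect_equal(cand$distance, 0)
  expect_equal(c(cand$a, cand$b), c(3, 25))

  # all-overlapping candidates cannot pair
  expect_error(find_motif_candidate(extract_subsequences(rnorm(8), 5)),
               "non-overlapping")
})

test_that("candidate search agrees with the exhaustive oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- rnorm(120) + sin(seq_len(120) / 5)
    sub <- extract_subsequences(x, 20)
    got <- find_motif_candidate(sub)
    want <- pair_oracle(sub)
    expect_equal(c(got$ia, got$ib), c(want$ia, want$ib))
    expect_equal(got$distance^2, want$dist2, tolerance = 1e-9)
  }
})

test_that("raw-lead pair scan matches the subsequence-matrix search", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(200) + rep(sin(seq_len(20) / 3), 10)
    sub <- extract_subsequences(x, 25)
    a <- find_motif_candidate(sub)
    b <- raad:::cpp_pair_search(x, 25L)
    expect_equal(c(a$a, a$b), c(b$i, b$j))
  }
})

test_that("bitsave rewards duplicate-rich groups and penalises noise", {
  set.seed(5)
  center <- znormalize(sin(seq_len(64) / 4))
  dup <- rbind(center, center)
  expect_gt(bitsave(dup, center), 0)
  noise <- rbind(center, znormalize(rnorm(64)))
  expect_gt(bitsave(dup, center), bitsave(noise, center))
  # a member's contribution shrinks as its residual against the centre grows
  r0 <- rnorm(64, sd = 0.4)
  incr <- vapply(c(0, 0.2, 0.5, 1, 2, 4), function(s) {
    raad:::bitsave_increment(center + s * r0, center)
  }, numeric(1))
  expect_true(all(diff(incr) <= 0))
  expect_error(bitsave(matrix(1, 1, 4), c(0, 0)), "mismatch")
})

test_that("motif growth collects planted beats and stops at noise", {
  set.seed(9)
  tpl <- c(rep(0, 6), 1, 4, -2, rep(0, 4), 1.5, rep(0, 6))  # 20 samples
  x <- rnorm(460, sd = 0.05)
  starts0 <- 20 * (1:18)
  for (s in starts0) x[s + 1:20] <- x[s + 1:20] + tpl
  # two distinct beats
  x[1:20] <- rnorm(20, sd = 2)
  x[441:460] <- -2 * tpl + rnorm(20, sd = 0.5)
  sub <- extract_subsequences(x, 20)
  grp <- grow_motif(find_motif_candidate(sub), sub)
  # members may sit at a common phase offset from the planted starts
  hits <- sum(vapply(starts0, function(s) any(abs(grp$members - s) <= 10),
                     logical(1)))
  expect_gte(hits, 16)
  expect_false(any(abs(grp$members - 0) <= 10))
  expect_false(any(abs(grp$members - 440) <= 10))
  # accepted additions strictly increase the score
  expect_true(all(diff(grp$bitsave_trace) > 0))
  # members never overlap
  expect_true(all(diff(sort(grp$members)) >= grp$length))
})

test_that("a candidate pair among pure noise stays a pair", {
  set.seed(21)
  x <- rnorm(200, sd = 1)
  tpl <- sin(seq_len(20) / 2) * 4 + c(rep(0, 9), 8, -5, rep(0, 9))
  x[41:60] <- tpl
  x[121:140] <- tpl
  sub <- extract_subsequences(x, 20)
  grp <- grow_motif(find_motif_candidate(sub), sub)
  expect_equal(sort(grp$members), c(40, 120))
})

test_that("proper-length discovery picks the duplicate-rich length", {
  sim <- synthesize_record(n_leads = 1, duration = 10, seed = 31)
  x <- bandpass_filter(sim$record)$signals[, 1]
  grp <- discover_proper_length_motif(x, 257)
  l0 <- starting_length(257)
  expect_gte(grp$length, l0)
  expect_lte(grp$length, 2 * l0)
  # every interior beat ends up in the motif
  r_int <- sim$truth$beats$r
  r_int <- r_int[r_int > 300 & r_int < 2300]
  covered <- vapply(r_int, function(r) {
    any(grp$members <= r & r < grp$members + grp$length)
  }, logical(1))
  expect_true(all(covered))
  # the reported bitsave is at least the starting-length group's score
  sub0 <- extract_subsequences(x, l0)
  g0 <- grow_motif(find_motif_candidate(sub0), sub0)
  expect_gte(grp$bitsave, g0$bitsave)
  expect_error(discover_proper_length_motif(rnorm(50), 257), "shorter")
})

test_that("cleanest-lead choice avoids contaminated leads and is equivariant", {
  sim <- synthesize_record(n_leads = 3, duration = 10, seed = 33,
                           lead_gains = c(1, 0.9, 1.1))
  rec <- sim$record
  rec <- inject_artifact(rec, 2, c(257, 2056), "ac_interference",
                         magnitude = 0.5, seed = 33)
  rec <- inject_artifact(rec, 3, c(257, 2056), "muscle_tremor",
                         magnitude = 0.5, seed = 33)
  cl <- cleanest_lead(rec)
  expect_equal(cl$lead, 1)
  # permuting leads permutes the winner
  perm <- rec
  perm$signals <- rec$signals[, c(2, 3, 1)]
  expect_equal(cleanest_lead(perm)$lead, 3)
  # single lead: trivially that lead
  single <- ecg_record(rec$signals[, 1], rec$sampling_rate)
  expect_equal(cleanest_lead(single)$lead, 1)
})

test_that("anomaly candidates are the floor-filtered complement", {
  motif <- structure(list(length = 140,
                          members = c(0, 150, 300, 450),
                          center = numeric(140), bitsave = 1),
                     class = "motif_group")
  # members cover [0,140) [150,290) [300,440) [450,590): gaps of 10 dropped
  cand <- anomaly_candidates(800, motif)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(590, 800))
  # full tiling leaves nothing
  motif$members <- c(0, 150, 300, 450, 590)
  motif$length <- 210
  expect_equal(nrow(anomaly_candidates(800, motif)), 0)
})
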