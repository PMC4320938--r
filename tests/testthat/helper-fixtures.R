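# Shared fixture builders.  All fixtures are generated in code with fixed
# seeds; nothing is read from disk.

# A 12-lead study record: one PVC at beat 6 plus one artifact of each class
# (and a morphology mimic) spread over five leads.
study_record <- function(seed, n_leads = 12, duration = 10, pvc_beat = 6) {
  sim <- synthesize_record(n_leads = n_leads, duration = duration,
                           seed = seed)
  if (!is.na(pvc_beat)) sim <- inject_anomaly(sim, pvc_beat)
  put <- function(lead, iv, kind) {
    if (lead <= n_leads) {
      sim$record <<- inject_artifact(sim$record, lead, iv, kind, seed = seed)
    }
  }
  put(2, c(514, 1285), "wandering_baseline")
  put(3, c(771, 1799), "ac_interference")
  put(4, c(1285, 2056), "muscle_tremor")
  put(5, c(257, 771), "motion")
  if (n_leads >= 7) sim$record <- make_morphology_mimic(sim, 7, 3, seed = seed)
  sim
}

# Exhaustive DTW by enumerating every monotone warping path (oracle).
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# Brute-force closest non-overlapping pair in R (oracle).
pair_oracle <- function(subseqs) {
  k <- length(subseqs$starts)
  m <- subseqs$length
  best <- Inf; bi <- NA; bj <- NA
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (abs(subseqs$starts[i] - subseqs$starts[j]) < m) next
      d <- sum((subseqs$values[i, ] - subseqs$values[j, ])^2)
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
  }
  list(ia = bi, ib = bj, dist2 = best)
}

# Random ground-truth/detection instances for metric brute-force checks.
random_truth_instance <- function(seed) {
  set.seed(seed)
  k <- sample(3:12, 1)
  bounds <- sort(sample(0:2000, 2 * k))
  truth <- data.frame(
    label = sample(c("normal", "anomalous"), k, replace = TRUE,
                   prob = c(0.7, 0.3)),
    m_s = bounds[seq(1, 2 * k, 2)], m_e = bounds[seq(2, 2 * k, 2)])
  truth$r_s <- c(0, truth$m_e[-k])
  truth$r_e <- c(truth$m_s[-1], 2100)
  nd <- sample(0:4, 1)
  det <- if (nd > 0) {
    s <- sample(0:2000, nd)
    data.frame(start = s, end = s + sample(20:200, nd, replace = TRUE))
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  list(truth = truth, detections = det)
}
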