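#' Beat template parameters for the synthetic ECG generator
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) at fixed offsets
#' relative to the R peak, on an isoelectric (zero) baseline.  The default
#' template satisfies the standard normal ranges by construction:
#' PR interval 0.18 s (normal 0.12-0.20), P-wave 0.12 s (<= 0.12),
#' QRS 0.08 s (0.06-0.10) and QT 0.40 s (0.36-0.44).
#'
#' @param heart_rate beats per minute.
#' @param rr_jitter_sd standard deviation of the beat-to-beat RR interval
#'   variation, seconds.
#' @param amplitude_jitter_cv coefficient of variation of the per-beat
#'   amplitude factor.
#' @param noise_sd measurement-noise standard deviation, mV.
#' @param waves data.frame with `wave`, `center` (s, relative to R),
#'   `width` (Gaussian sd, s) and `amp` (mV).
#' @return a `beat_template_params` list.
#' @export
beat_template_params <- function(heart_rate = 63, rr_jitter_sd = 0.02,
                                 amplitude_jitter_cv = 0.05,
                                 noise_sd = 0.01,
                                 waves = NULL) {
  if (is.null(waves)) {
    waves <- data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center = c(-0.16, -0.04, 0.00, 0.04, 0.30),
      width = c(0.025, 0.010, 0.012, 0.010, 0.050),
      amp = c(0.15, -0.10, 1.00, -0.15, 0.30))
  }
  stopifnot(all(diff(waves$center) > 0), all(waves$width > 0),
            heart_rate > 0, rr_jitter_sd >= 0)
  structure(list(heart_rate = heart_rate, rr_jitter_sd = rr_jitter_sd,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 noise_sd = noise_sd, waves = waves),
            class = "beat_template_params")
}

# PVC-like template: no P bump, widened (1.5x) high-amplitude (1.5x) QRS,
# inverted T.
pvc_waves <- function() {
  data.frame(
    wave = c("Q", "R", "S", "T"),
    center = c(-0.06, 0.00, 0.06, 0.30),
    width = c(0.015, 0.018, 0.015, 0.050),
    amp = c(-0.15, 1.50, -0.25, -0.30))
}

# evaluate one beat's Gaussian bumps on sample indices 0..n-1 (0-based),
# truncating each bump at +-5 widths so beats have finite support
beat_waveform <- function(n, fs, r_time, waves, amp_factor = 1) {
  y <- numeric(n)
  for (w in seq_len(nrow(waves))) {
    c_s <- r_time + waves$center[w]
    sd_s <- waves$width[w]
    i0 <- max(0L, as.integer(floor((c_s - 5 * sd_s) * fs)))
    i1 <- min(n - 1L, as.integer(ceiling((c_s + 5 * sd_s) * fs)))
    if (i1 < i0) next
    idx <- i0:i1
    t <- idx / fs
    y[idx + 1] <- y[idx + 1] +
      amp_factor * waves$amp[w] * exp(-((t - c_s) / sd_s)^2 / 2)
  }
  y
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthesise a multi-lead ECG record with ground truth
#'
#' Beats are placed from `t0` onward with seeded RR and per-beat amplitude
#' jitter; leads differ by gain (polarity allowed); TP segments are
#' isoelectric apart from white measurement noise.  The record deliberately
#' begins and ends mid-cycle, as clinical excerpts do, so the first and last
#' beats are partial.
#'
#' Ground truth records, per beat: the wave-peak fiducials, the morphology
#' interval `[m_s, m_e)` (the essential PQRST extent a detection must
#' cover) and the beat bounds `[r_s, r_e)` (previous T end to next P onset,
#' which a detection must not exceed), all as 0-based sample indices.
#'
#' @param n_leads number of leads.
#' @param duration record length in seconds.
#' @param sampling_rate Hz.
#' @param params a [beat_template_params()].
#' @param lead_gains per-lead scale/polarity (recycled defaults if `NULL`).
#' @param seed integer seed; generation is a pure function of
#'   `(seed, parameters)`.
#' @param t0 time of the first R peak, seconds.
#' @param record_id identifier.
#' @return list with `record` (an [ecg_record()]) and `truth` (an
#'   `ecg_truth` list: `beats` data.frame, `artifacts`, `params`).
#' @export
synthesize_record <- function(n_leads = 12, duration = 10,
                              sampling_rate = 257,
                              params = beat_template_params(),
                              lead_gains = NULL, seed = 1, t0 = 0.15,
                              record_id = sprintf("synth-%d", seed)) {
  fs <- sampling_rate
  n <- as.integer(round(duration * fs))
  rr_mean <- 60 / params$heart_rate
  if (duration < 2 * rr_mean) stop("duration must cover at least two beats")
  if (is.null(lead_gains)) {
    pool <- c(1, 0.85, 1.1, 0.75, 0.9, 1.05, 0.8, 0.95, 1.15, 0.7, 1.0, 0.9)
    lead_gains <- rep_len(pool, n_leads)
  }
  stopifnot(length(lead_gains) == n_leads)
  with_seed(seed, {
    r_times <- t0
    repeat {
      nxt <- r_times[length(r_times)] + rr_mean +
        stats::rnorm(1, 0, params$rr_jitter_sd)
      if (nxt >= duration) break
      r_times <- c(r_times, nxt)
    }
    k <- length(r_times)
    amp <- 1 + params$amplitude_jitter_cv * stats::rnorm(k)
    clean <- numeric(n)
    for (b in seq_len(k)) {
      clean <- clean + beat_waveform(n, fs, r_times[b], params$waves, amp[b])
    }
    signals <- vapply(seq_len(n_leads), function(l) {
      lead_gains[l] * clean + stats::rnorm(n, 0, params$noise_sd)
    }, numeric(n))
    truth_beats <- ground_truth_beats(r_times, params$waves, fs, n)
    record <- ecg_record(signals, fs, record_id = record_id)
    truth <- structure(list(
      beats = truth_beats,
      artifacts = data.frame(lead = integer(0), start = integer(0),
                             end = integer(0), kind = character(0)),
      r_times = r_times, amp = amp, lead_gains = lead_gains,
      params = params, seed = seed, n_samples = n, sampling_rate = fs),
      class = "ecg_truth")
    list(record = record, truth = truth)
  })
}

# per-beat fiducials and evaluation geometry from exact beat placement
ground_truth_beats <- function(r_times, waves, fs, n, labels = NULL) {
  k <- length(r_times)
  wl <- function(nm, col) waves[[col]][match(nm, waves$wave)]
  idx <- function(t) as.integer(round(t * fs))
  r <- idx(r_times)
  has_p <- "P" %in% waves$wave
  p_peak <- if (has_p) idx(r_times + wl("P", "center")) else rep(NA_integer_, k)
  q <- idx(r_times + wl("Q", "center"))
  s <- idx(r_times + wl("S", "center"))
  t_peak <- idx(r_times + wl("T", "center"))
  hw <- as.integer(round(0.06 * fs))
  p_onset <- if (has_p) p_peak - hw else q - as.integer(round(0.02 * fs))
  t_end <- t_peak + hw
  m_s <- if (has_p) p_peak - as.integer(round(0.03 * fs)) else
    r - as.integer(round(0.05 * fs))
  m_e <- t_peak + as.integer(round(0.04 * fs))
  r_s <- c(0L, utils::head(t_end, -1))
  r_e <- c(utils::tail(p_onset, -1), n)
  data.frame(
    label = if (is.null(labels)) rep("normal", k) else labels,
    r = r, p_peak = p_peak, q = q, s = s, t_peak = t_peak,
    p_onset = p_onset, t_end = t_end,
    m_s = pmax(0L, m_s), m_e = pmin(n, m_e),
    r_s = pmax(0L, r_s), r_e = pmin(n, r_e))
}

#' Replace a beat with a PVC-like anomalous complex
#'
#' The chosen beat loses its P wave and gains a widened (1.5x), taller
#' (1.5x) QRS with an inverted T wave; the signal outside the union of the
#' old and new beat supports is untouched, and the ground truth is
#' relabelled with the PVC's own morphology bounds.
#'
#' @param sim list `(record, truth)` from [synthesize_record()].
#' @param beat_index 1-based beat number to replace.
#' @return modified `(record, truth)` list.
#' @export
inject_anomaly <- function(sim, beat_index) {
  record <- sim$record
  truth <- sim$truth
  k <- nrow(truth$beats)
  if (beat_index < 1 || beat_index > k) stop("invalid beat index")
  fs <- record$sampling_rate
  n <- n_samples(record)
  r_time <- truth$r_times[beat_index]
  amp <- truth$amp[beat_index]
  old <- beat_waveform(n, fs, r_time, truth$params$waves, amp)
  new <- beat_waveform(n, fs, r_time, pvc_waves(), amp)
  delta <- new - old
  for (l in seq_len(n_leads(record))) {
    record$signals[, l] <- record$signals[, l] + truth$lead_gains[l] * delta
  }
  b <- truth$beats[beat_index, ]
  r <- b$r
  b$label <- "anomalous"
  b$p_peak <- NA_integer_
  b$q <- r - as.integer(round(0.06 * fs))
  b$s <- r + as.integer(round(0.06 * fs))
  b$p_onset <- b$q - as.integer(round(0.02 * fs))
  b$m_s <- r - as.integer(round(0.05 * fs))
  b$m_e <- r + as.integer(round(0.07 * fs))
  truth$beats[beat_index, ] <- b
  if (beat_index > 1) truth$beats$r_e[beat_index - 1] <- b$p_onset
  list(record = record, truth = truth)
}

#' Inject a recording artifact into one lead
#'
#' Adds, over the given interval of a single lead only, one of the four
#' classic ECG artifact classes: a slow baseline wander (< 0.5 Hz
#' sinusoid), powerline AC interference (50 Hz sinusoid), muscle tremor
#' (band-limited > 25 Hz spike noise) or a motion artifact (large smoothed
#' baseline swing).  Injection is additive and local: other leads and
#' samples outside the interval are bit-identical.
#'
#' @param record an [ecg_record()].
#' @param lead 1-based lead index.
#' @param interval `c(start, end)` 0-based half-open sample interval.
#' The artifact amplitude ramps up and down with a raised-cosine envelope
#' (up to 0.5 s at each end) because physical artifacts fade in and out
#' rather than switching on instantaneously.
#'
#' @param kind artifact class.
#' @param magnitude amplitude in mV (defaults per class).
#' @param seed integer seed for the stochastic classes.
#' @param ramp_s envelope ramp duration at each end, seconds.
#' @return the contaminated [ecg_record()].
#' @export
inject_artifact <- function(record, lead, interval,
                            kind = c("wandering_baseline", "ac_interference",
                                     "muscle_tremor", "motion"),
                            magnitude = NULL, seed = 1, ramp_s = 0.5) {
  kind <- match.arg(kind)
  fs <- record$sampling_rate
  n <- n_samples(record)
  if (lead < 1 || lead > n_leads(record)) stop("invalid lead")
  if (interval[1] < 0 || interval[2] > n || interval[1] >= interval[2])
    stop("invalid artifact interval")
  if (is.null(magnitude)) {
    magnitude <- switch(kind, wandering_baseline = 0.5, ac_interference = 0.3,
                        muscle_tremor = 0.25, motion = 0.8)
  }
  idx <- (interval[1] + 1):interval[2]
  t <- (idx - 1) / fs
  len <- length(idx)
  comp <- with_seed(seed, switch(kind,
    wandering_baseline =
      magnitude * sin(2 * pi * 0.33 * t + stats::runif(1, 0, 2 * pi)),
    ac_interference =
      magnitude * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)),
    muscle_tremor = {
      hp <- signal::butter(4, min(25 / (fs / 2), 0.95), type = "high")
      x <- stats::rnorm(len, 0, magnitude)
      if (len > 30) filtfilt_pad(hp$b, hp$a, x, 12) else x
    },
    motion = {
      # a few smoothed random baseline steps
      n_steps <- max(2L, as.integer(round(len / fs)))
      bounds <- sort(sample.int(len - 1, n_steps - 1))
      levels <- stats::runif(n_steps, -magnitude, magnitude)
      step <- rep(levels, diff(c(0, bounds, len)))
      kern_w <- max(3L, as.integer(round(0.1 * fs)))
      kern <- exp(-seq(-2, 2, length.out = kern_w)^2)
      kern <- kern / sum(kern)
      as.numeric(stats::filter(c(rep(step[1], kern_w), step,
                                 rep(step[len], kern_w)),
                               kern, sides = 2))[(kern_w + 1):(kern_w + len)]
    }))
  ramp <- min(as.integer(round(ramp_s * fs)), len %/% 4)
  if (ramp > 0) {
    env <- rep(1, len)
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
    env[seq_len(ramp)] <- up
    env[len - ramp + seq_len(ramp)] <- rev(up)
    comp <- comp * env
  }
  record$signals[idx, lead] <- record$signals[idx, lead] + comp
  record
}

#' Superimpose a morphology-mimicking artifact in a TP segment
#'
#' Adds a scaled, time-compressed copy of the normal beat template inside
#' the electrically silent TP segment following `beat_index`, on one lead
#' only.  This emulates artifacts that look like genuine cardiac activity;
#' truth labels are unchanged because it is an artifact, not an anomaly.
#'
#' @param sim list `(record, truth)` from [synthesize_record()].
#' @param lead 1-based lead index to contaminate.
#' @param beat_index the TP segment used is the one after this beat.
#' @param seed integer seed (placement jitter).
#' @param scale amplitude scale of the mimic relative to a normal beat.
#' @param warp time-compression factor of the mimic.
#' @return the contaminated [ecg_record()] (truth is unchanged by design).
#' @export
make_morphology_mimic <- function(sim, lead, beat_index, seed = 1,
                                  scale = 0.5, warp = 0.5) {
  record <- sim$record
  truth <- sim$truth
  fs <- record$sampling_rate
  n <- n_samples(record)
  k <- nrow(truth$beats)
  if (beat_index < 1 || beat_index >= k) stop("invalid beat index")
  tp_start <- truth$beats$t_end[beat_index]
  tp_end <- truth$beats$p_onset[beat_index + 1]
  if (tp_end - tp_start < 0.2 * fs) stop("TP segment too short for a mimic")
  waves <- truth$params$waves
  waves$center <- waves$center * warp
  waves$width <- waves$width * warp
  waves$amp <- waves$amp * scale
  tp_len <- (tp_end - tp_start) / fs
  r_time <- with_seed(seed,
    stats::runif(1, tp_start / fs + 0.35 * tp_len,
                 tp_start / fs + 0.65 * tp_len))
  comp <- beat_waveform(n, fs, r_time, waves)
  # the artifact lives strictly inside the electrically silent interval
  comp[-((tp_start + 1):tp_end)] <- 0
  record$signals[, lead] <- record$signals[, lead] +
    truth$lead_gains[lead] * comp
  record
}
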