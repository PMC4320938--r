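#' QRS detection by the difference operation method
#'
#' Works on the first difference of the (band-pass filtered) lead.  An R
#' candidate is a maximal positive slope followed within
#' `qrs_slope_pair_s` seconds by a minimal negative slope, both exceeding an
#' adaptive threshold (half the median of the ten largest local
#' slope-magnitude extrema per two-second stretch); R is the signal argmax
#' between the slope pair.  Q is the last local minimum within 0.05 s before
#' R and S the first local minimum within 0.05 s after R (window argmin when
#' no strict local minimum exists).  R peaks closer than the 0.2 s refractory
#' period are merged, keeping the taller peak.
#'
#' All returned positions are 0-based sample indices.
#'
#' @param lead numeric vector (a band-pass filtered lead).
#' @param sampling_rate Hz.
#' @param qrs_slope_pair_s maximum slope-pair separation in seconds.
#' @param refractory_s minimum R-R separation in seconds.
#' @return data.frame with columns `q`, `r`, `s`.
#' @export
detect_qrs <- function(lead, sampling_rate, qrs_slope_pair_s = 0.10,
                       refractory_s = 0.20) {
  n <- length(lead)
  if (n < sampling_rate) stop("lead shorter than one second")
  d <- diff(lead)
  thr <- slope_threshold(d, sampling_rate)
  pos <- local_extrema(d, "max")
  pos <- pos[d[pos] > thr[pos]]
  neg <- local_extrema(d, "min")
  neg <- neg[d[neg] < -thr[neg]]
  if (!length(pos) || !length(neg)) stop("no QRS detected")
  w <- as.integer(round(qrs_slope_pair_s * sampling_rate))
  r_cand <- integer(0)
  for (i in pos) {
    js <- neg[neg > i & neg <= i + w]
    if (!length(js)) next
    j <- js[1]
    seg <- i:(j + 1)
    r_cand <- c(r_cand, seg[which.max(lead[seg])])
  }
  if (!length(r_cand)) stop("no QRS detected")
  r_cand <- sort(unique(r_cand))
  # adaptive amplitude threshold: the enclosed peak must reach half the
  # largest peak of its 2-s stretch, which rejects tall T waves
  awin <- as.integer(round(2 * sampling_rate))
  amp_ok <- vapply(r_cand, function(r) {
    w0 <- ((r - 1) %/% awin) * awin + 1
    lead[r] >= 0.5 * max(lead[w0:min(n, w0 + awin - 1)])
  }, logical(1))
  if (any(amp_ok)) r_cand <- r_cand[amp_ok]
  # refractory merge: among peaks closer than refractory_s keep the taller
  refr <- as.integer(round(refractory_s * sampling_rate))
  keep <- r_cand[1]
  for (r in r_cand[-1]) {
    last <- keep[length(keep)]
    if (r - last >= refr) {
      keep <- c(keep, r)
    } else if (lead[r] > lead[last]) {
      keep[length(keep)] <- r
    }
  }
  half <- as.integer(round(0.05 * sampling_rate))
  res <- lapply(keep, function(r) {
    qw <- max(1, r - half):(r - 1)
    if (r - 1 < max(1, r - half)) return(NULL)
    q <- last_local_min(lead, qw)
    sw <- (r + 1):min(n, r + half)
    if (r + 1 > min(n, r + half)) return(NULL)
    s <- first_local_min(lead, sw)
    c(q = q, r = r, s = s)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || !nrow(res)) stop("no QRS detected")
  data.frame(q = res[, "q"] - 1L, r = res[, "r"] - 1L, s = res[, "s"] - 1L)
}

# Adaptive slope threshold: per 2-s stretch, half the median of the ten
# largest local |slope| extrema; returned per-sample.
slope_threshold <- function(d, sampling_rate) {
  n <- length(d)
  win <- as.integer(round(2 * sampling_rate))
  ad <- abs(d)
  ext <- local_extrema(ad, "max")
  thr <- numeric(n)
  for (w0 in seq(1, n, by = win)) {
    w1 <- min(n, w0 + win - 1)
    e <- ext[ext >= w0 & ext <= w1]
    vals <- sort(ad[e], decreasing = TRUE)
    if (!length(vals)) vals <- max(ad[w0:w1])
    thr[w0:w1] <- 0.5 * stats::median(utils::head(vals, 10))
  }
  thr
}

# strict local extrema (1-based indices, interior points only)
local_extrema <- function(x, type = c("max", "min")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  if (type == "max") {
    1L + which(x[i] > x[i - 1] & x[i] >= x[i + 1])
  } else {
    1L + which(x[i] < x[i - 1] & x[i] <= x[i + 1])
  }
}

last_local_min <- function(x, window) {
  lm <- window[window > 1 & window < length(x)]
  lm <- lm[x[lm] < x[lm - 1] & x[lm] <= x[lm + 1]]
  if (length(lm)) lm[length(lm)] else window[which.min(x[window])]
}

first_local_min <- function(x, window) {
  lm <- window[window > 1 & window < length(x)]
  lm <- lm[x[lm] < x[lm - 1] & x[lm] <= x[lm + 1]]
  if (length(lm)) lm[1] else window[which.min(x[window])]
}

#' Locate the P wave before a QRS complex
#'
#' The P peak is the voltage maximum within `pr_window_s` (0.20 s, the upper
#' bound of a normal PR interval) before the Q position; onset and end are
#' the voltage minima within `half_wave_window_s` (0.06 s, half the normal
#' P-wave duration bound) before and after the peak, the end clipped at Q.
#' Argmax/argmin ties break to the earliest index.
#'
#' @param lead numeric vector.
#' @param q 0-based Q position.
#' @param sampling_rate Hz.
#' @param pr_window_s,half_wave_window_s clinical search windows in seconds.
#' @return named vector `p_onset`, `p_peak`, `p_end` (0-based).
#' @export
locate_p_wave <- function(lead, q, sampling_rate, pr_window_s = 0.20,
                          half_wave_window_s = 0.06) {
  q1 <- q + 1L  # 1-based
  wpr <- as.integer(round(pr_window_s * sampling_rate))
  whw <- as.integer(round(half_wave_window_s * sampling_rate))
  win <- max(1, q1 - wpr):(q1 - 1)
  if (q1 - 1 < 1) stop("empty P search window")
  p_peak <- win[which.max(lead[win])]
  ow <- max(1, p_peak - whw):(p_peak - 1)
  if (p_peak - 1 < 1) stop("empty P-onset window")
  p_onset <- ow[which.min(lead[ow])]
  ew <- (p_peak + 1):min(q1, p_peak + whw)
  if (p_peak + 1 > min(q1, p_peak + whw)) stop("empty P-end window")
  p_end <- ew[which.min(lead[ew])]
  c(p_onset = p_onset - 1L, p_peak = p_peak - 1L, p_end = p_end - 1L)
}

#' Locate the T wave after a QRS complex
#'
#' The T peak is the voltage maximum within `t_search_s` (0.38 s: upper
#' normal QT bound minus lower normal QRS bound) after the S position; onset
#' and end are the voltage minima within `half_wave_window_s` before and
#' after the peak, the onset clipped at S.
#'
#' @param lead numeric vector.
#' @param s 0-based S position.
#' @param sampling_rate Hz.
#' @param t_search_s,half_wave_window_s clinical search windows in seconds.
#' @return named vector `t_onset`, `t_peak`, `t_end` (0-based).
#' @export
locate_t_wave <- function(lead, s, sampling_rate, t_search_s = 0.38,
                          half_wave_window_s = 0.06) {
  n <- length(lead)
  s1 <- s + 1L
  wt <- as.integer(round(t_search_s * sampling_rate))
  whw <- as.integer(round(half_wave_window_s * sampling_rate))
  win <- (s1 + 1):min(n, s1 + wt)
  if (s1 + 1 > min(n, s1 + wt)) stop("empty T search window")
  t_peak <- win[which.max(lead[win])]
  ow <- max(s1 + 1, t_peak - whw):(t_peak - 1)
  if (t_peak - 1 < s1 + 1) stop("empty T-onset window")
  t_onset <- ow[which.min(lead[ow])]
  ew <- (t_peak + 1):min(n, t_peak + whw)
  if (t_peak + 1 > min(n, t_peak + whw)) stop("empty T-end window")
  t_end <- ew[which.min(lead[ew])]
  c(t_onset = t_onset - 1L, t_peak = t_peak - 1L, t_end = t_end - 1L)
}

#' Delineate all beats on a lead
#'
#' Applies [detect_qrs()], then [locate_p_wave()] and [locate_t_wave()] to
#' every QRS triple.  Beats whose P or T search windows would extend past
#' the record edges are dropped (partial morphology cannot feed the partial
#' DTW comparison), as are beats violating the fiducial ordering
#' `p_onset < p_peak < p_end <= q < r < s <= t_onset < t_peak < t_end`.
#'
#' @param lead numeric vector (band-pass filtered).
#' @param sampling_rate Hz.
#' @return a `beat_annotation` data.frame with the nine fiducials (0-based
#'   sample indices), ordered by R position.
#' @export
segment_lead <- function(lead, sampling_rate) {
  qrs <- detect_qrs(lead, sampling_rate)
  n <- length(lead)
  pr_w <- as.integer(round(0.20 * sampling_rate))
  hw <- as.integer(round(0.06 * sampling_rate))
  t_w <- as.integer(round(0.38 * sampling_rate))
  beats <- lapply(seq_len(nrow(qrs)), function(b) {
    q <- qrs$q[b]; r <- qrs$r[b]; s <- qrs$s[b]
    if (q - pr_w - hw < 0) return(NULL)          # P windows leave record
    if (s + t_w + hw > n - 1) return(NULL)       # T windows leave record
    p <- tryCatch(locate_p_wave(lead, q, sampling_rate),
                  error = function(e) NULL)
    tt <- tryCatch(locate_t_wave(lead, s, sampling_rate),
                   error = function(e) NULL)
    if (is.null(p) || is.null(tt)) return(NULL)
    ann <- c(p, q = q, r = r, s = s, tt)
    if (!beat_ordering_ok(ann)) return(NULL)
    ann
  })
  beats <- do.call(rbind, beats[!vapply(beats, is.null, logical(1))])
  if (is.null(beats) || !nrow(beats))
    stop("no complete beats could be delineated")
  out <- as.data.frame(beats)
  class(out) <- c("beat_annotation", "data.frame")
  out
}

beat_ordering_ok <- function(a) {
  a["p_onset"] < a["p_peak"] && a["p_peak"] < a["p_end"] &&
    a["p_end"] <= a["q"] && a["q"] < a["r"] && a["r"] < a["s"] &&
    a["s"] <= a["t_onset"] && a["t_onset"] < a["t_peak"] &&
    a["t_peak"] < a["t_end"]
}

#' Beat spans and derived intervals
#'
#' `beat_spans` returns the `[p_onset, t_end)` interval of each annotated
#' beat; these spans are the subsequences the detector compares and reports.
#'
#' @param beats a `beat_annotation` data.frame.
#' @export
beat_spans <- function(beats) intervals(beats$p_onset, beats$t_end)

#' TP segments between consecutive beats
#'
#' The electrically silent interval from one beat's T-wave end to the next
#' beat's P-wave onset.  Inverted (overlapping-beat) segments are emitted
#' with zero length and flagged.
#'
#' @param beats a `beat_annotation` data.frame with at least two beats.
#' @return data.frame `start`, `end`, `empty`.
#' @export
tp_segments <- function(beats) {
  k <- nrow(beats)
  if (k < 2) stop("need at least two beats")
  start <- beats$t_end[-k]
  end <- beats$p_onset[-1]
  empty <- end <= start
  end[empty] <- start[empty]
  data.frame(start = start, end = end, empty = empty)
}

#' Propagate cleanest-lead fiducials to every lead
#'
#' Because all leads observe the same electrical activity simultaneously,
#' the fiducial sample indices found on the cleanest lead are used verbatim
#' on every other lead; no per-lead re-detection takes place.
#'
#' @param beats cleanest-lead `beat_annotation`.
#' @param n_leads number of leads.
#' @return list of `n_leads` identical annotation data.frames (value
#'   semantics: mutating one copy does not affect the others).
#' @export
propagate_reference <- function(beats, n_leads) {
  lapply(seq_len(n_leads), function(i) beats)
}
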