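#' Dynamic time warping distance with squared pointwise cost
#'
#' Minimal cumulative sum of squared point differences over all monotone
#' warping paths with step set \{(1,1),(1,0),(0,1)\}, anchored at both ends;
#' no window constraint is applied.
#'
#' @param a,b numeric vectors (non-empty).
#' @return non-negative cumulative squared distance.
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("dtw_distance: empty input")
  cpp_dtw(as.numeric(a), as.numeric(b))
}

#' Partial DTW distance between two beats
#'
#' Unconstrained DTW over whole beats can align a P wave with a QRS complex;
#' restricting each alignment to one portion of the morphology prevents such
#' excessive warping.  The distance is the sum of DTW distances over the
#' P wave `[p_onset, p_end)`, the PR segment `[p_end, q)` and the QT
#' interval `[q, t_end)`, each segment cut from the same lead with each
#' beat's own fiducials and (by default) z-normalised per beat so the three
#' terms are comparable across amplitude differences.
#'
#' A zero-length segment contributes the DTW of the other beat's segment
#' against a single zero sample.
#'
#' @param lead numeric vector of one lead's samples.
#' @param beat_p,beat_q single-row `beat_annotation` entries (0-based
#'   fiducials).
#' @param znorm_segments z-normalise each segment before DTW.
#' @return non-negative partial DTW distance.
#' @export
beat_distance <- function(lead, beat_p, beat_q, znorm_segments = TRUE) {
  segs_p <- beat_segments(lead, beat_p, znorm_segments)
  segs_q <- beat_segments(lead, beat_q, znorm_segments)
  sum(vapply(seq_along(segs_p), function(i) {
    dtw_distance(segs_p[[i]], segs_q[[i]])
  }, numeric(1)))
}

beat_segments <- function(lead, beat, znorm_segments = TRUE) {
  cuts <- list(p_wave = c(beat$p_onset, beat$p_end),
               pr_segment = c(beat$p_end, beat$q),
               qt_interval = c(beat$q, beat$t_end))
  lapply(cuts, function(iv) {
    if (iv[2] <= iv[1]) return(0)  # empty segment -> single zero sample
    seg <- lead[(iv[1] + 1):iv[2]]
    if (znorm_segments && length(seg) >= 2) znormalize(seg) else seg
  })
}

#' Pairwise partial-DTW distances and nearest neighbours
#'
#' @param lead numeric vector of one lead's samples.
#' @param beats a `beat_annotation` data.frame (>= 2 beats).
#' @param znorm_segments passed to [beat_distance()].
#' @return list with the symmetric `distances` matrix (zero diagonal) and
#'   `nearest_neighbor`, each beat's minimum off-diagonal distance.
#' @export
nearest_neighbor_distances <- function(lead, beats, znorm_segments = TRUE) {
  k <- nrow(beats)
  if (k < 2) stop("need at least two beats")
  segs <- lapply(seq_len(k),
                 function(i) beat_segments(lead, beats[i, ], znorm_segments))
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- sum(vapply(1:3, function(t) {
        dtw_distance(segs[[i]][[t]], segs[[j]][[t]])
      }, numeric(1)))
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  nn <- vapply(seq_len(k), function(i) min(D[i, -i]), numeric(1))
  list(distances = D, nearest_neighbor = nn)
}

#' Anomaly threshold: mean plus standard deviation
#'
#' Because most beats resemble each other, their comparison distances vary
#' little; a beat whose nearest-neighbour distance exceeds the mean plus one
#' (sample) standard deviation of the distance population stands apart.
#'
#' @param distances numeric vector (>= 2 values).
#' @export
anomaly_threshold <- function(distances) {
  if (length(distances) < 2) stop("need at least two distances")
  mean(distances) + stats::sd(distances)
}

#' Flag beats whose nearest-neighbour distance exceeds a threshold
#'
#' Strict inequality: a beat is new-anomalous only if its nearest-neighbour
#' distance is larger than the threshold.
#'
#' @param nn numeric vector of nearest-neighbour distances.
#' @param threshold numeric threshold.
#' @return integer vector of flagged beat indices (1-based).
#' @export
flag_new_anomalies <- function(nn, threshold) {
  which(nn > threshold)
}

#' Shift a candidate interval onto beat-span anchors
#'
#' The start snaps to the nearest P onset and the end to the nearest T end
#' so a candidate aligns with whole cardiac cycles; equidistant anchors
#' resolve to the earlier one.  If snapping empties or inverts the interval
#' it falls outward to the span of the beat nearest the candidate midpoint.
#'
#' @param candidate length-2 vector or one-row interval data.frame
#'   (0-based half-open).
#' @param beats a `beat_annotation` data.frame.
#' @return snapped interval as `c(start, end)`.
#' @export
shift_candidate <- function(candidate, beats) {
  if (is.data.frame(candidate)) candidate <- c(candidate$start, candidate$end)
  if (!nrow(beats)) stop("no beats to anchor on")
  ps <- beats$p_onset
  te <- beats$t_end
  start <- ps[nearest_anchor(ps, candidate[1])]
  end <- te[nearest_anchor(te, candidate[2])]
  if (end <= start) {
    mid <- mean(candidate)
    b <- nearest_anchor((ps + te) / 2, mid)
    start <- ps[b]
    end <- te[b]
  }
  c(start = start, end = end)
}

nearest_anchor <- function(anchors, x) {
  d <- abs(anchors - x)
  which(d == min(d))[1]  # earlier anchor on ties
}

#' Full anomaly-beat detection pipeline
#'
#' Runs band-pass preprocessing, cleanest-lead motif discovery, PQRST
#' delineation on the cleanest lead, fiducial propagation to every lead,
#' per-lead partial-DTW nearest-neighbour flagging, and candidate shifting;
#' the record-level result is the set of whole beat spans flagged either by
#' the distance test (combined across leads) or by motif exclusion on the
#' cleanest lead.
#'
#' A beat counts as belonging to the motif period when at least
#' `candidate_overlap` (default half) of its span is covered by motif member
#' windows; the remaining beats are the non-motif anomaly candidates.
#'
#' @param record an [ecg_record()].
#' @param low_cut,high_cut,order band-pass parameters (see
#'   [bandpass_filter()]).
#' @param combine how per-lead distance flags form the record-level set:
#'   `"union"`, `"majority"`, or `"cleanest"` (cleanest lead only).
#' @param threshold_on population the mean-plus-sd threshold is computed
#'   over: `"pairwise"` (all off-diagonal beat-pair distances, the default)
#'   or `"nearest"` (the nearest-neighbour distances themselves).
#' @param znorm_segments z-normalise beat segments before DTW.
#' @param candidate_overlap motif-period coverage fraction.
#' @param max_factor,step,bits motif discovery controls (see
#'   [discover_proper_length_motif()]).
#' @return an `anomaly_result` list: `cleanest_lead`, `motif_length`,
#'   `beats` (fiducials), `per_lead_flags`, `flagged_beats`, `provenance`
#'   (`"distance_flagged"` / `"nonmotif_candidate"` / `"both"`),
#'   `record_intervals` (flagged whole-beat spans), `candidate_intervals`
#'   (shifted motif-stage candidates), `thresholds` (per lead).
#' @export
detect_anomalies <- function(record, low_cut = 2, high_cut = 20, order = 2,
                             combine = c("union", "majority", "cleanest"),
                             threshold_on = c("pairwise", "nearest"),
                             znorm_segments = TRUE, candidate_overlap = 0.5,
                             max_factor = 2, step = NULL, bits = 8) {
  combine <- match.arg(combine)
  threshold_on <- match.arg(threshold_on)
  fs <- record$sampling_rate
  filtered <- bandpass_filter(record, low_cut, high_cut, order)
  cl <- cleanest_lead(filtered, max_factor = max_factor, step = step,
                      bits = bits)
  motif <- cl$groups[[cl$lead]]
  lead_sig <- filtered$signals[, cl$lead]
  beats <- segment_lead(lead_sig, fs)
  spans <- beat_spans(beats)
  k <- nrow(beats)

  # motif-period membership of each beat (coverage of its span)
  cov <- interval_union(cbind(motif$members, motif$members + motif$length))
  covered_frac <- vapply(seq_len(k), function(i) {
    overlap_length(c(spans$start[i], spans$end[i]), cov) /
      (spans$end[i] - spans$start[i])
  }, numeric(1))
  nonmotif <- which(covered_frac < candidate_overlap)

  # raw candidates (complement of motif coverage), shifted onto beat spans
  cands <- anomaly_candidates(n_samples(record), motif)
  shifted <- if (nrow(cands)) {
    t(apply(cands, 1, shift_candidate, beats = beats))
  } else {
    matrix(numeric(0), ncol = 2)
  }

  # per-lead distance flagging (identical fiducials on every lead)
  per_lead <- vector("list", n_leads(record))
  thresholds <- numeric(n_leads(record))
  for (l in seq_len(n_leads(record))) {
    nnd <- nearest_neighbor_distances(filtered$signals[, l], beats,
                                      znorm_segments)
    thr <- anomaly_threshold(
      if (threshold_on == "pairwise") {
        nnd$distances[upper.tri(nnd$distances)]
      } else {
        nnd$nearest_neighbor
      })
    thresholds[l] <- thr
    per_lead[[l]] <- flag_new_anomalies(nnd$nearest_neighbor, thr)
  }
  dist_flags <- switch(combine,
    union = sort(unique(unlist(per_lead))),
    majority = {
      tab <- table(unlist(per_lead))
      as.integer(names(tab)[tab > n_leads(record) / 2])
    },
    cleanest = per_lead[[cl$lead]])

  flagged <- sort(unique(c(dist_flags, nonmotif)))
  provenance <- vapply(flagged, function(b) {
    d <- b %in% dist_flags
    nm <- b %in% nonmotif
    if (d && nm) "both" else if (d) "distance_flagged" else "nonmotif_candidate"
  }, character(1))
  names(provenance) <- as.character(flagged)

  structure(list(
    record_id = record$record_id,
    sampling_rate = fs,
    cleanest_lead = cl$lead,
    motif_length = motif$length,
    motif_bitsave = motif$bitsave,
    beats = beats,
    per_lead_flags = per_lead,
    flagged_beats = flagged,
    provenance = provenance,
    record_intervals = if (length(flagged)) {
      intervals(spans$start[flagged], spans$end[flagged])
    } else intervals(),
    candidate_intervals = if (nrow(shifted)) {
      intervals(shifted[, 1], shifted[, 2])
    } else intervals(),
    thresholds = thresholds
  ), class = "anomaly_result")
}

#' @export
print.anomaly_result <- function(x, ...) {
  cat(sprintf(
    "<anomaly_result '%s': cleanest lead %d, motif length %d, %d/%d beats flagged>\n",
    x$record_id, x$cleanest_lead, x$motif_length, length(x$flagged_beats),
    nrow(x$beats)))
  if (length(x$flagged_beats)) {
    iv <- x$record_intervals
    for (i in seq_along(x$flagged_beats)) {
      cat(sprintf("  beat %d: [%d, %d) %s\n", x$flagged_beats[i],
                  iv$start[i], iv$end[i], x$provenance[i]))
    }
  }
  invisible(x)
}

# union of possibly-overlapping [start, end) rows -> sorted disjoint matrix
interval_union <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[r, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[r, 2])
    } else {
      out <- rbind(out, iv[r, ])
    }
  }
  out
}

# total overlap of interval x = c(start, end) with a disjoint interval matrix
overlap_length <- function(x, iv) {
  if (!nrow(iv)) return(0)
  sum(pmax(0, pmin(iv[, 2], x[2]) - pmax(iv[, 1], x[1])))
}
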