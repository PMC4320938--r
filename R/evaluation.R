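#' Overlapping ratio between ground truth and detections
#'
#' Percentage of the ground-truth anomalous beat's data points covered by
#' the detected points: `|R intersect D| / |R| * 100`.
#'
#' @param R ground-truth interval(s): `c(start, end)` or an interval
#'   data.frame (0-based half-open).
#' @param D detected interval(s), same forms.
#' @return percentage in \[0, 100\].
#' @export
overlapping_ratio <- function(R, D) {
  R <- as_interval_matrix(R)
  D <- as_interval_matrix(D)
  len_R <- sum(R[, 2] - R[, 1])
  if (len_R <= 0) stop("empty ground-truth interval")
  Du <- interval_union(D)
  inter <- sum(apply(R, 1, overlap_length, iv = Du))
  inter / len_R * 100
}

as_interval_matrix <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$start, x$end)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = TRUE)
  x[x[, 2] > x[, 1], , drop = FALSE]
}

#' Overlap-threshold match criterion
#'
#' At a 0% threshold a single overlapped data point counts (ratio strictly
#' above zero); positive thresholds require `ratio >= threshold`.
#'
#' @param ratio overlap percentage.
#' @param threshold percentage in \[0, 100\].
#' @export
matches_threshold <- function(ratio, threshold) {
  if (threshold == 0) ratio > 0 else ratio >= threshold
}

#' Cardiologist match criterion
#'
#' A detection is clinically usable only if it covers the anomalous beat's
#' full morphology `[m_s, m_e)` and does not bleed into adjacent beats,
#' i.e. stays within the beat bounds `[r_s, r_e)`.
#'
#' @param D a single detected interval `c(start, end)`.
#' @param beat a list/row with `m_s`, `m_e`, `r_s`, `r_e`.
#' @export
matches_cardiologist <- function(D, beat) {
  D[1] <= beat$m_s && D[2] >= beat$m_e &&
    D[1] >= beat$r_s && D[2] <= beat$r_e
}

#' Accuracy on detection (AoD)
#'
#' Mean, over the real anomalous beats, of the overlap percentage between
#' each beat's morphology and the union of detections intersecting it.
#' `NA` when no anomalous beats are present (not applicable).
#'
#' @param truth ground-truth beat table (see [confusion()]).
#' @param detections interval data.frame of detections.
#' @return percentage, or `NA` if there are no anomalous beats.
#' @export
aod <- function(truth, detections) {
  anom <- truth[truth$label == "anomalous", , drop = FALSE]
  if (!nrow(anom)) return(NA_real_)
  mean(vapply(seq_len(nrow(anom)), function(i) {
    overlapping_ratio(c(anom$m_s[i], anom$m_e[i]), detections)
  }, numeric(1)))
}

#' Beat-level confusion counts under an overlap criterion
#'
#' `truth` is a data.frame with one row per ground-truth beat: `label`
#' (`"normal"` / `"anomalous"`), morphology interval `m_s`, `m_e` and beat
#' bounds `r_s`, `r_e` (0-based half-open sample indices).  An anomalous
#' beat is a true positive when some detection matches it under the
#' criterion, otherwise a false negative.  A detection matching no
#' anomalous beat contributes one false positive for every normal beat
#' whose morphology it intersects (or a single false positive if it
#' intersects no beat at all); the remaining normal beats are true
#' negatives.
#'
#' @param truth ground-truth beat table.
#' @param detections interval data.frame (`start`, `end`).
#' @param criterion `list(type = "threshold", t = <pct>)` or
#'   `list(type = "cardiologist")`.
#' @return list of counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(truth, detections,
                      criterion = list(type = "threshold", t = 0)) {
  D <- as_interval_matrix(detections)
  anom <- which(truth$label == "anomalous")
  norm <- which(truth$label == "normal")
  det_matches_beat <- function(d, b) {
    if (criterion$type == "cardiologist") {
      matches_cardiologist(d, truth[b, ])
    } else {
      r <- overlapping_ratio(c(truth$m_s[b], truth$m_e[b]),
                             matrix(d, ncol = 2))
      matches_threshold(r, criterion$t)
    }
  }
  tp_beats <- logical(length(anom))
  det_used <- logical(nrow(D))
  if (nrow(D)) {
    for (di in seq_len(nrow(D))) {
      for (ai in seq_along(anom)) {
        if (det_matches_beat(D[di, ], anom[ai])) {
          tp_beats[ai] <- TRUE
          det_used[di] <- TRUE
        }
      }
    }
  }
  fp_norm <- logical(length(norm))
  fp_extra <- 0L
  if (nrow(D)) {
    for (di in which(!det_used)) {
      hit <- FALSE
      for (ni in seq_along(norm)) {
        b <- norm[ni]
        if (min(D[di, 2], truth$m_e[b]) > max(D[di, 1], truth$m_s[b])) {
          fp_norm[ni] <- TRUE
          hit <- TRUE
        }
      }
      # a detection intersecting an anomalous beat without matching the
      # criterion still counts against that beat, not against normals
      if (!hit) {
        hits_anom <- any(vapply(anom, function(b) {
          min(D[di, 2], truth$m_e[b]) > max(D[di, 1], truth$m_s[b])
        }, logical(1)))
        if (!hits_anom) fp_extra <- fp_extra + 1L
      }
    }
  }
  list(tp = sum(tp_beats), fn = sum(!tp_beats),
       fp = sum(fp_norm) + fp_extra, tn = sum(!fp_norm))
}

#' Confusion-matrix rates
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and false-alarm rate `FP/(FP+TN)`, all in percent.
#' A rate whose denominator is zero is reported as `NA` (not applicable),
#' never as 0 or 100.
#'
#' @param c confusion counts from [confusion()].
#' @export
sensitivity <- function(c) rate_pct(c$tp, c$tp + c$fn)

#' @rdname sensitivity
#' @export
specificity <- function(c) rate_pct(c$tn, c$tn + c$fp)

#' @rdname sensitivity
#' @export
ppv <- function(c) rate_pct(c$tp, c$tp + c$fp)

#' @rdname sensitivity
#' @export
false_alarm_rate <- function(c) rate_pct(c$fp, c$fp + c$tn)

rate_pct <- function(num, den) if (den > 0) num / den * 100 else NA_real_

#' Evaluate detections against ground truth under several criteria
#'
#' @param truth ground-truth beat table (see [confusion()]).
#' @param detections interval data.frame.
#' @param thresholds overlap thresholds in percent.
#' @param cardiologist include the cardiologist criterion.
#' @return an `evaluation_report`: per criterion, the confusion counts and
#'   rates, plus the overall AoD.
#' @export
evaluate_detection <- function(truth, detections,
                               thresholds = c(0, 30, 40, 80),
                               cardiologist = TRUE) {
  criteria <- c(
    lapply(thresholds, function(t) list(type = "threshold", t = t)),
    if (cardiologist) list(list(type = "cardiologist")))
  names(criteria) <- c(if (length(thresholds)) paste0("overlap_", thresholds),
                       if (cardiologist) "cardiologist")
  res <- lapply(criteria, function(cr) {
    cc <- confusion(truth, detections, cr)
    c(cc, list(sensitivity = sensitivity(cc), specificity = specificity(cc),
               ppv = ppv(cc), false_alarm_rate = false_alarm_rate(cc)))
  })
  structure(list(aod = aod(truth, detections), criteria = res),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: AoD = %s>\n",
              if (is.na(x$aod)) "n/a" else sprintf("%.2f%%", x$aod)))
  for (nm in names(x$criteria)) {
    r <- x$criteria[[nm]]
    fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f", v)
    cat(sprintf(
      "  %-13s tp=%d fp=%d fn=%d tn=%d  sens=%s spec=%s ppv=%s far=%s\n",
      nm, r$tp, r$fp, r$fn, r$tn, fmt(r$sensitivity), fmt(r$specificity),
      fmt(r$ppv), fmt(r$false_alarm_rate)))
  }
  invisible(x)
}
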