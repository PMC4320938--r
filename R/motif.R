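#' Starting subsequence length for proper-length motif discovery
#'
#' The initial window length corresponds to the systolic third of a cardiac
#' cycle at the fast end (100 bpm) of the normal resting heart-rate range:
#' `round((1/3) * (100/60) * sampling_rate)` samples.
#'
#' @param sampling_rate samples per second.
#' @return window length in samples (positive integer).
#' @export
starting_length <- function(sampling_rate) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be positive")
  max(1L, as.integer(round((1 / 3) * (100 / 60) * sampling_rate)))
}

#' Z-normalise a sample window
#'
#' Centres and scales by the population standard deviation so windows are
#' comparable regardless of amplitude scaling and offset; constant windows
#' map to the all-zero vector.
#'
#' @param window numeric vector of raw samples (length >= 2).
#' @export
znormalize <- function(window) {
  if (length(window) < 2) stop("window must have at least 2 samples")
  mu <- mean(window)
  sd_pop <- sqrt(mean((window - mu)^2))
  if (sd_pop <= 1e-12) return(rep(0, length(window)))
  (window - mu) / sd_pop
}

#' Extract all z-normalised subsequences of one length from a lead
#'
#' Sliding step is one sample, so a lead of `n` samples yields
#' `n - length + 1` subsequences with 0-based starts `0 .. n - length`.
#'
#' @param lead numeric vector of raw samples.
#' @param length window length in samples.
#' @return an `ecg_subsequences` list: `starts` (0-based), `values`
#'   (k x length matrix of z-normalised windows) and `length`.
#' @export
extract_subsequences <- function(lead, length) {
  n <- base::length(lead)
  if (length > n) stop("subsequence length exceeds lead length")
  if (length < 2) stop("subsequence length must be >= 2")
  starts <- 0:(n - length)
  structure(list(starts = starts, values = window_zmatrix(lead, length),
                 length = length),
            class = "ecg_subsequences")
}

#' Closest non-overlapping subsequence pair (motif candidate)
#'
#' Returns the pair of subsequences minimising the Euclidean distance between
#' z-normalised values, excluding trivial matches: two windows may pair only
#' if their starts differ by at least the window length.  Ties break to the
#' lexicographically smallest `(start_a, start_b)`.
#'
#' @param subseqs an `ecg_subsequences` object from [extract_subsequences()].
#' @return list with 0-based starts `a`, `b`, row indices and the distance.
#' @export
find_motif_candidate <- function(subseqs) {
  k <- length(subseqs$starts)
  if (k < 2) stop("need at least two subsequences")
  res <- cpp_brute_pair(subseqs$values, as.integer(subseqs$starts),
                        as.integer(subseqs$length))
  list(a = subseqs$starts[res$i + 1], b = subseqs$starts[res$j + 1],
       ia = res$i + 1L, ib = res$j + 1L, distance = sqrt(res$dist2))
}

# 8-bit (by default) discretisation of a z-normalised vector over [-4, 4].
discretize_z <- function(v, bits = 8) {
  levels <- 2^bits - 1
  as.integer(round((pmin(pmax(v, -4), 4) + 4) / 8 * levels))
}

# Description length in bits of an integer residual vector under the
# sign+magnitude code: cost(r) = log2(2*|r| + 1) + 1 per point.
dl_residual <- function(r) sum(log2(2 * abs(r) + 1) + 1)

#' Minimum-description-length bitsave score of a motif group
#'
#' Vectors are discretised to `bits`-bit integers over the z-score range
#' \[-4, 4\].  Each vector's standalone description length is its cost coded
#' against the isoelectric baseline (quantised zero); its conditional cost is
#' the residual against the group centre.  The score is
#' `sum(DL(member) - DL(member | center)) - DL(center)`: bits saved by
#' encoding the members through the shared centre rather than independently.
#' Higher means the group is more internally similar; a window that the
#' centre does not predict better than the baseline contributes negatively.
#'
#' @param members numeric matrix, one z-normalised member per row.
#' @param center z-normalised centre vector of the same length.
#' @param bits discretisation depth.
#' @return bitsave in bits.
#' @export
bitsave <- function(members, center, bits = 8) {
  if (is.vector(members)) members <- matrix(members, nrow = 1)
  m <- ncol(members)
  if (length(center) != m) stop("member/center length mismatch")
  qc <- discretize_z(center, bits)
  q0 <- discretize_z(0, bits)
  saved <- sum(apply(members, 1, function(v) {
    qv <- discretize_z(v, bits)
    dl_residual(qv - q0) - dl_residual(qv - qc)
  }))
  saved - dl_residual(qc - q0)
}

#' Grow a motif group from a candidate pair
#'
#' The centre is the average of the z-normalised candidate pair and is not
#' re-averaged as neighbours join.  Neighbours are visited in ascending
#' Euclidean distance to the centre; a neighbour overlapping any current
#' member is ineligible and skipped; an eligible neighbour is accepted iff
#' the group bitsave strictly increases, and growth stops at the first
#' rejection.
#'
#' @param candidate result of [find_motif_candidate()].
#' @param subseqs the `ecg_subsequences` the candidate came from.
#' @param bits discretisation depth for [bitsave()].
#' @return a `motif_group`: `length`, `members` (0-based starts), `center`,
#'   `bitsave`, `bitsave_trace` (score after each accepted addition).
#' @export
grow_motif <- function(candidate, subseqs, bits = 8) {
  Z <- subseqs$values
  d2 <- colSums((t(Z) - (Z[candidate$ia, ] + Z[candidate$ib, ]) / 2)^2)
  grow_motif_impl(function(i) Z[i, ], subseqs$starts, subseqs$length,
                  candidate$ia, candidate$ib, d2, bits)
}

# Shared growth engine.  get_z(i) returns the z-normalised window for
# subsequence row i; d2 holds squared distances of every window to the centre.
grow_motif_impl <- function(get_z, starts, m, ia, ib, d2, bits) {
  center <- (get_z(ia) + get_z(ib)) / 2
  group_idx <- c(ia, ib)
  bs <- bitsave(rbind(get_z(ia), get_z(ib)), center, bits)
  trace <- bs
  ord <- order(d2, starts)  # ascending distance, ties by start
  member_starts <- starts[group_idx]
  for (i in ord) {
    s <- starts[i]
    if (any(abs(s - member_starts) < m)) next  # trivial match / duplicate
    bs_new <- bs + bitsave_increment(get_z(i), center, bits)
    if (bs_new > bs) {
      group_idx <- c(group_idx, i)
      member_starts <- c(member_starts, s)
      bs <- bs_new
      trace <- c(trace, bs)
    } else {
      break
    }
  }
  ord_idx <- order(member_starts)
  structure(list(length = m, members = member_starts[ord_idx],
                 member_idx = group_idx[ord_idx], center = center,
                 bitsave = bs, bitsave_trace = trace),
            class = "motif_group")
}

# Bits saved by adding one member: DL(member) - DL(member | center).
bitsave_increment <- function(v, center, bits = 8) {
  qv <- discretize_z(v, bits)
  dl_residual(qv - discretize_z(0, bits)) -
    dl_residual(qv - discretize_z(center, bits))
}

#' Proper-length motif discovery on a single lead
#'
#' Runs candidate search and bitsave-greedy growth for every window length on
#' the grid from [starting_length()] to `max_factor` times it (step
#' `round(sampling_rate / 50)` samples by default) and returns the group with
#' maximum bitsave; ties go to the shorter length.
#'
#' For long leads the candidate pair is found with a sliding dot-product
#' scan over the raw lead (identical result to [find_motif_candidate()] on
#' the extracted subsequences, computed without materialising them).
#'
#' @param lead numeric vector of raw samples.
#' @param sampling_rate Hz.
#' @param max_factor upper end of the length grid, as a multiple of the
#'   starting length.
#' @param step length grid step in samples.
#' @param bits discretisation depth for [bitsave()].
#' @return the best `motif_group` (with a `$lead`-settable slot unset).
#' @export
discover_proper_length_motif <- function(lead, sampling_rate,
                                         max_factor = 2, step = NULL,
                                         bits = 8) {
  n <- length(lead)
  l0 <- starting_length(sampling_rate)
  if (n < l0) stop("lead shorter than the starting motif length")
  if (is.null(step)) step <- max(1L, as.integer(round(sampling_rate / 50)))
  lengths <- seq(l0, min(as.integer(round(max_factor * l0)), n), by = step)
  best <- NULL
  for (m in lengths) {
    if (n - m + 1 < m + 1) next  # no non-overlapping pair can exist
    pair <- tryCatch(cpp_pair_search(lead, as.integer(m)),
                     error = function(e) NULL)
    if (is.null(pair)) next
    starts <- 0:(n - m)
    get_z <- function(i) znormalize(lead[(starts[i] + 1):(starts[i] + m)])
    center <- (get_z(pair$i + 1L) + get_z(pair$j + 1L)) / 2
    d2 <- cpp_dists_to_center(lead, as.integer(m), center)
    grp <- grow_motif_impl(get_z, starts, m, pair$i + 1L, pair$j + 1L,
                           d2, bits)
    if (is.null(best) || grp$bitsave > best$bitsave) best <- grp
  }
  if (is.null(best)) stop("no motif found on this lead")
  best
}

# k x m matrix of z-normalised windows (vectorised; avoids per-window R calls)
window_zmatrix <- function(lead, m) {
  n <- length(lead)
  k <- n - m + 1
  idx <- outer(seq_len(k), 0:(m - 1), `+`)
  W <- matrix(lead[idx], nrow = k)
  mu <- rowMeans(W)
  W <- W - mu
  sd_pop <- sqrt(rowMeans(W^2))
  sd_pop[sd_pop <= 1e-12] <- Inf  # constant windows -> all zeros
  W / sd_pop
}

#' Cleanest-lead discovery
#'
#' Runs [discover_proper_length_motif()] on every lead and returns the lead
#' whose motif attains the maximum bitsave (ties to the lowest lead index):
#' the lead with the most mutually similar beats is the least contaminated
#' and is used as the segmentation reference for all leads.
#'
#' @param record an [ecg_record()].
#' @param ... passed to [discover_proper_length_motif()].
#' @return list with `lead` (1-based index) and `groups` (per-lead motifs).
#' @export
cleanest_lead <- function(record, ...) {
  groups <- lapply(seq_len(n_leads(record)), function(l) {
    g <- discover_proper_length_motif(record$signals[, l],
                                      record$sampling_rate, ...)
    g$lead <- l
    g
  })
  scores <- vapply(groups, function(g) g$bitsave, numeric(1))
  list(lead = which.max(scores), groups = groups)
}

#' Anomaly-candidate intervals from a lead's motif
#'
#' The candidates are the maximal stretches of the lead not covered by any
#' motif member window; fragments shorter than half the motif length are
#' discarded as boundary slack (they cannot contain a full beat).
#'
#' @param lead_length lead length in samples.
#' @param motif a `motif_group`.
#' @return interval table (0-based half-open) from [intervals()].
#' @export
anomaly_candidates <- function(lead_length, motif) {
  m <- motif$length
  cov <- cbind(motif$members, motif$members + m)
  cov <- cov[order(cov[, 1]), , drop = FALSE]
  gaps <- list()
  cursor <- 0
  for (r in seq_len(nrow(cov))) {
    if (cov[r, 1] > cursor) gaps[[length(gaps) + 1]] <- c(cursor, cov[r, 1])
    cursor <- max(cursor, cov[r, 2])
  }
  if (cursor < lead_length)
    gaps[[length(gaps) + 1]] <- c(cursor, lead_length)
  if (!length(gaps)) return(intervals())
  g <- do.call(rbind, gaps)
  keep <- (g[, 2] - g[, 1]) >= m / 2
  intervals(g[keep, 1], g[keep, 2])
}
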