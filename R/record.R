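#' Construct a multi-lead ECG record
#'
#' An `ecg_record` holds a time-aligned matrix of voltage samples (one column
#' per lead, in millivolts) together with its sampling rate.  All leads share
#' the same length and sampling rate because every lead observes the same
#' cardiac electrical activity.
#'
#' All sample positions in this package are 0-based, half-open `[start, end)`
#' intervals; conversion to 1-based printed positions happens only at I/O
#' boundaries.
#'
#' @param signals numeric matrix (or vector for a single lead),
#'   `n_samples x n_leads`, voltages in mV.
#' @param sampling_rate samples per second (positive).
#' @param lead_names optional character vector of lead labels.
#' @param record_id free-text identifier.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signals, sampling_rate, lead_names = NULL,
                       record_id = "record") {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("signals must be numeric")
  if (nrow(signals) < 1 || ncol(signals) < 1)
    stop("record must have at least one sample and one lead")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (is.null(lead_names)) {
    lead_names <- colnames(signals)
    if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(signals)))
  }
  if (length(lead_names) != ncol(signals))
    stop("lead_names length must match the number of leads")
  colnames(signals) <- lead_names
  structure(
    list(signals = signals, lead_names = lead_names,
         sampling_rate = sampling_rate, record_id = record_id),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples x %d leads @ %g Hz (%.2f s)>\n",
              x$record_id, n_samples(x), n_leads(x), x$sampling_rate,
              n_samples(x) / x$sampling_rate))
  invisible(x)
}

#' @rdname ecg_record
#' @param record an `ecg_record`.
#' @export
n_samples <- function(record) nrow(record$signals)

#' @rdname ecg_record
#' @export
n_leads <- function(record) ncol(record$signals)

#' Read an ECG record from disk
#'
#' CSV records have one column per lead (comma-separated, optional single
#' header row of lead names) and require an explicit sampling rate.  WFDB
#' (PhysioNet header/signal) input is not supported by this build; records
#' exported from such archives should be converted to CSV first.
#'
#' @param path file path.
#' @param format `"csv"` or `"wfdb"`.
#' @param sampling_rate sampling rate in Hz (required for CSV).
#' @param record_id identifier; defaults to the file name.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), sampling_rate = NULL,
                        record_id = NULL) {
  format <- match.arg(format)
  if (format == "wfdb")
    stop("WFDB input is not supported; convert the record to CSV")
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sampling_rate))
    stop("sampling_rate must be given for CSV records")
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  first <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character", check.names = FALSE)
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(df))
  if (anyNA(mat)) stop("non-numeric sample in ", path)
  lead_names <- if (has_header) trimws(first) else
    paste0("lead", seq_len(ncol(mat)))
  ecg_record(mat, sampling_rate, lead_names = lead_names,
             record_id = record_id)
}

#' Write an ECG record as CSV (one column per lead, header of lead names)
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @export
write_record_csv <- function(record, path) {
  utils::write.table(record$signals, path, sep = ",", row.names = FALSE,
                     col.names = record$lead_names, quote = FALSE)
  invisible(path)
}

#' Extract a time slice of a record
#'
#' @param record an [ecg_record()].
#' @param t_start,t_end slice bounds in seconds; the returned record covers
#'   sample indices `[round(t_start * fs), round(t_end * fs))`.
#' @export
slice_record <- function(record, t_start, t_end) {
  fs <- record$sampling_rate
  dur <- n_samples(record) / fs
  if (t_start < 0 || t_end > dur || t_start >= t_end)
    stop("invalid slice range [", t_start, ", ", t_end, ")")
  i0 <- round(t_start * fs)
  i1 <- round(t_end * fs)
  if (i1 <= i0) stop("empty slice range")
  ecg_record(record$signals[(i0 + 1):i1, , drop = FALSE], fs,
             lead_names = record$lead_names, record_id = record$record_id)
}

#' Serialise detection results (and optional evaluation report) to JSON
#'
#' The file stores per-lead and record-level anomalous intervals both as
#' 0-based sample indices and in seconds, the beat fiducials used, the
#' cleanest-lead index and per-beat provenance.  [read_results()] restores
#' the structure losslessly.
#'
#' @param result an `anomaly_result` as returned by [detect_anomalies()].
#' @param path output path.
#' @param report optional evaluation report (from [evaluate_detection()]).
#' @export
write_results <- function(result, path, report = NULL) {
  fs <- result$sampling_rate
  out <- list(
    schema_version = 1L,
    record_id = result$record_id,
    sampling_rate = fs,
    cleanest_lead = result$cleanest_lead,
    motif_length = result$motif_length,
    record_intervals = interval_df_json(result$record_intervals, fs),
    candidate_intervals = interval_df_json(result$candidate_intervals, fs),
    beats = result$beats,
    per_lead_flags = lapply(result$per_lead_flags, as.integer),
    flagged_beats = as.integer(result$flagged_beats),
    provenance = as.list(result$provenance),
    thresholds = result$thresholds
  )
  if (!is.null(report)) out$report <- report
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

interval_df_json <- function(iv, fs) {
  if (is.null(iv) || nrow(iv) == 0)
    return(list(start_sample = integer(0), end_sample = integer(0),
                start_s = numeric(0), end_s = numeric(0)))
  list(start_sample = as.integer(iv$start), end_sample = as.integer(iv$end),
       start_s = iv$start / fs, end_s = iv$end / fs)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("record_intervals", "candidate_intervals")) {
    x[[f]] <- data.frame(start = as.integer(x[[f]]$start_sample),
                         end = as.integer(x[[f]]$end_sample))
  }
  x$beats <- as.data.frame(x$beats)
  x
}

#' Build a 0-based half-open interval table
#'
#' @param start,end integer vectors of 0-based inclusive starts and exclusive
#'   ends; every interval must satisfy `0 <= start < end`.
#' @export
intervals <- function(start = integer(0), end = integer(0)) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(start < 0) || any(end <= start))
    stop("intervals must satisfy 0 <= start < end")
  data.frame(start = start, end = end)
}
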