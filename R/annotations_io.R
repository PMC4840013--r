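#' Record metadata table
#'
#' Construct and validate the per-record metadata table describing each EEG
#' recording in a cohort: which baby it belongs to, how long it is, and
#' whether the baby is in the seizure or the non-seizure group.
#' One baby may contribute several records; the group label is fixed per baby.
#'
#' @param record_id character vector of unique record identifiers.
#' @param baby_id character vector of patient identifiers (non-empty).
#' @param duration_hours numeric vector of record durations in hours (> 0).
#' @param group character vector, each element `"seizure"` or `"non-seizure"`.
#'
#' @return A `data.frame` with columns `record_id`, `baby_id`,
#'   `duration_hours`, `group`.
#' @examples
#' record_meta("rec1", "baby1", 63.1, "seizure")
#' @export
record_meta <- function(record_id, baby_id, duration_hours, group) {
  record_id <- as.character(record_id)
  baby_id <- as.character(baby_id)
  duration_hours <- as.numeric(duration_hours)
  group <- as.character(group)
  n <- length(record_id)
  stopifnot(length(baby_id) == n, length(duration_hours) == n,
            length(group) == n)
  if (anyDuplicated(record_id))
    stop("duplicate record_id in record metadata")
  if (any(!nzchar(baby_id)) || anyNA(baby_id))
    stop("baby_id must be non-empty")
  if (anyNA(duration_hours) || any(duration_hours <= 0))
    stop("duration_hours must be > 0")
  bad <- setdiff(unique(group), c("seizure", "non-seizure"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  data.frame(record_id = record_id, baby_id = baby_id,
             duration_hours = duration_hours, group = group,
             stringsAsFactors = FALSE)
}

#' Gold-standard seizure annotation list
#'
#' Construct a validated table of expert seizure annotations. Intervals are
#' half-open `[start, end)` in seconds from record start; `end > start` is
#' required, and when record metadata is supplied every interval must lie
#' within the declared record duration.
#'
#' @param record_id character vector of record identifiers.
#' @param start,end numeric vectors, seconds from record start (`start >= 0`,
#'   `end > start`).
#' @param annotator optional character vector naming the annotator.
#' @param records optional [record_meta()] table used to check that intervals
#'   fall inside their record.
#'
#' @return A `data.frame` with columns `record_id`, `start`, `end`,
#'   `annotator`, sorted by `(record_id, start)`.
#' @export
seizure_annotations <- function(record_id, start, end, annotator = NA_character_,
                                records = NULL) {
  record_id <- as.character(record_id)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(record_id)
  stopifnot(length(start) == n, length(end) == n)
  annotator <- rep_len(as.character(annotator), max(n, 1L))[seq_len(n)]
  if (anyNA(start) || anyNA(end) || any(start < 0))
    stop("annotation start/end must be non-negative numbers")
  bad <- which(end <= start)
  if (length(bad))
    stop("annotation end <= start at row(s): ", paste(bad, collapse = ", "))
  out <- data.frame(record_id = record_id, start = start, end = end,
                    annotator = annotator, stringsAsFactors = FALSE)
  if (!is.null(records)) check_within_records(out, records, "annotation")
  out <- out[order(out$record_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detector event list
#'
#' Construct a validated table of seizure-detection-algorithm (SDA) output
#' events at one sensitivity threshold: onset, duration and channel of peak
#' detection, as exported by the detector.
#'
#' @param record_id character vector of record identifiers.
#' @param start numeric vector, onset in seconds from record start.
#' @param duration numeric vector, event duration in seconds (> 0).
#' @param peak_channel character vector, channel of peak detection (e.g.
#'   `"F4-C4"`).
#' @param threshold single sensitivity threshold in `[0, 1]` tagged onto all
#'   events.
#' @param records optional [record_meta()] table for bounds checking.
#'
#' @return A `data.frame` with columns `record_id`, `threshold`, `start`,
#'   `duration`, `end`, `peak_channel`, sorted by `(record_id, start)`.
#' @export
detection_events <- function(record_id, start, duration, peak_channel = NA_character_,
                             threshold, records = NULL) {
  record_id <- as.character(record_id)
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  n <- length(record_id)
  stopifnot(length(start) == n, length(duration) == n)
  peak_channel <- rep_len(as.character(peak_channel), max(n, 1L))[seq_len(n)]
  check_threshold(threshold)
  if (anyNA(start) || any(start < 0))
    stop("event start must be non-negative")
  bad <- which(is.na(duration) | duration <= 0)
  if (length(bad))
    stop("event duration must be > 0 at row(s): ", paste(bad, collapse = ", "))
  out <- data.frame(record_id = record_id, threshold = rep(threshold, n),
                    start = start, duration = duration, end = start + duration,
                    peak_channel = peak_channel, stringsAsFactors = FALSE)
  if (!is.null(records)) check_within_records(out, records, "detection")
  out <- out[order(out$record_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_threshold <- function(threshold) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  invisible(threshold)
}

check_within_records <- function(x, records, what) {
  m <- match(x$record_id, records$record_id)
  if (anyNA(m))
    stop(what, " refers to unknown record(s): ",
         paste(unique(x$record_id[is.na(m)]), collapse = ", "))
  dur_s <- records$duration_hours[m] * 3600
  bad <- which(x$end > dur_s + 1e-9)
  if (length(bad))
    stop(what, " interval extends past record end at row(s): ",
         paste(bad, collapse = ", "))
  invisible(x)
}

#' Convert clock times to seconds from record start
#'
#' Exported annotation lists often carry wall-clock times; analyses here use
#' seconds from record start. Times crossing midnight are unwrapped (a clock
#' time earlier than the record start is taken to fall on a following day).
#'
#' @param clock character vector of `"HH:MM:SS"` clock times.
#' @param record_start single `"HH:MM:SS"` clock time of record start.
#'
#' @return Numeric vector of seconds elapsed since `record_start`.
#' @examples
#' clock_to_seconds(c("12:00:30", "00:10:00"), record_start = "11:59:00")
#' @export
clock_to_seconds <- function(clock, record_start) {
  parse_hms <- function(x) {
    p <- strsplit(x, ":", fixed = TRUE)
    vapply(p, function(v) {
      if (length(v) != 3L || anyNA(suppressWarnings(as.numeric(v))))
        stop("malformed clock time: ", paste(v, collapse = ":"))
      sum(as.numeric(v) * c(3600, 60, 1))
    }, numeric(1))
  }
  s <- parse_hms(clock) - parse_hms(record_start)
  ifelse(s < 0, s + 86400 * ceiling(-s / 86400), s)
}

read_delim_checked <- function(path, required, delim = ",", what = "file") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "", quote = "\"")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Read a gold-standard seizure annotation file
#'
#' Reads a delimited text file of expert seizure annotations (one row per
#' seizure) and returns a validated, sorted annotation table. Column names
#' are configurable to accommodate differing export layouts; start/end may be
#' given either in seconds or as clock times (with `record_start`).
#'
#' @param path path to a delimited text file with a header row.
#' @param delim field delimiter (default comma).
#' @param cols named character vector mapping the canonical names
#'   `record_id`, `start`, `end` (and optionally `annotator`) to the file's
#'   column names.
#' @param record_start optional `"HH:MM:SS"` record start; when given, the
#'   start/end columns are parsed as clock times via [clock_to_seconds()].
#' @param records optional [record_meta()] table for bounds checking.
#'
#' @return A seizure annotation `data.frame`; see [seizure_annotations()].
#' @export
read_annotations <- function(path, delim = ",",
                             cols = c(record_id = "record_id",
                                      start = "start", end = "end"),
                             record_start = NULL, records = NULL) {
  need <- unname(cols[c("record_id", "start", "end")])
  df <- read_delim_checked(path, need, delim, "annotation file")
  if (nrow(df) == 0)
    return(seizure_annotations(character(), numeric(), numeric()))
  to_sec <- function(x) {
    if (!is.null(record_start)) return(clock_to_seconds(as.character(x), record_start))
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop("malformed numeric time at line(s): ",
           paste(which(is.na(v)) + 1L, collapse = ", "))
    v
  }
  annot <- if ("annotator" %in% names(cols) && cols[["annotator"]] %in% names(df))
    as.character(df[[cols[["annotator"]]]]) else NA_character_
  seizure_annotations(df[[cols[["record_id"]]]], to_sec(df[[cols[["start"]]]]),
                      to_sec(df[[cols[["end"]]]]), annot, records = records)
}

#' Read a detector event file for one sensitivity threshold
#'
#' Reads the delimited text export of SDA detections (onset time, duration,
#' channel of peak detection) and tags every event with the stated threshold.
#'
#' @param path path to a delimited text file with a header row.
#' @param threshold sensitivity threshold in `[0, 1]` of this export.
#' @param delim field delimiter (default comma).
#' @param cols named character vector mapping canonical names `record_id`,
#'   `start`, `duration` (and optionally `peak_channel`) to file columns.
#' @param record_start optional `"HH:MM:SS"` record start for clock-time
#'   onset columns.
#' @param records optional [record_meta()] table for bounds checking.
#'
#' @return A detection event `data.frame`; see [detection_events()].
#' @export
read_detections <- function(path, threshold, delim = ",",
                            cols = c(record_id = "record_id", start = "start",
                                     duration = "duration",
                                     peak_channel = "peak_channel"),
                            record_start = NULL, records = NULL) {
  check_threshold(threshold)
  need <- unname(cols[c("record_id", "start", "duration")])
  df <- read_delim_checked(path, need, delim, "detection file")
  if (nrow(df) == 0)
    return(detection_events(character(), numeric(), numeric(),
                            threshold = threshold))
  start <- if (!is.null(record_start))
    clock_to_seconds(as.character(df[[cols[["start"]]]]), record_start)
  else suppressWarnings(as.numeric(df[[cols[["start"]]]]))
  if (anyNA(start))
    stop("malformed onset time at line(s): ",
         paste(which(is.na(start)) + 1L, collapse = ", "))
  pc <- if ("peak_channel" %in% names(cols) && cols[["peak_channel"]] %in% names(df))
    as.character(df[[cols[["peak_channel"]]]]) else NA_character_
  detection_events(df[[cols[["record_id"]]]], start,
                   as.numeric(df[[cols[["duration"]]]]), pc,
                   threshold = threshold, records = records)
}

#' Write annotation or detection tables back to delimited text
#'
#' Round-trip companions to [read_annotations()] and [read_detections()]:
#' all fields are preserved exactly on a write/read cycle.
#'
#' @param x a table as returned by [seizure_annotations()] or
#'   [detection_events()].
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path, delim = ",") {
  utils::write.table(x, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the analysis report tables
#'
#' Writes the standard set of delimited report tables from a completed audit:
#' per-threshold performance metrics, the univariate/multivariate odds-ratio
#' table, and the false-detection category table.
#'
#' @param results a named list with any of the components `metrics` (from
#'   [threshold_sweep()]), `or_table` (from [detectability_analysis()] /
#'   [univariate_screen()]), and `fd_table` (from [aggregate_fd()], a single
#'   table or a list of per-threshold tables).
#' @param outdir output directory, created if needed.
#' @param delim field delimiter.
#'
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(results, outdir, delim = ",") {
  if (!is.list(results) || is.null(names(results)) ||
      !any(nzchar(names(results))))
    stop("results must be a named list of analysis components")
  known <- c("metrics", "or_table", "fd_table")
  if (!any(known %in% names(results)))
    stop("no analysis component found; expected one of: ",
         paste(known, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = delim, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(results$metrics)) put(results$metrics, "threshold_metrics.csv")
  if (!is.null(results$or_table)) put(results$or_table, "odds_ratio_table.csv")
  if (!is.null(results$fd_table)) {
    fd <- results$fd_table
    if (is.data.frame(fd)) fd <- list(fd)
    for (tab in fd) {
      thr <- unique(tab$threshold)
      put(tab, sprintf("fd_categories_thr%s.csv",
                       gsub("[^0-9]", "", format(thr[1]))))
    }
  }
  invisible(written)
}
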