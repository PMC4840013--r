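#' Match detector events against gold-standard seizure annotations
#'
#' Core event-based matching for one record at one sensitivity threshold,
#' using the detection-anywhere rule: a gold seizure counts as detected if at
#' least one detector event overlaps it in time, on any channel, by any
#' nonzero amount; a detector event that overlaps no gold seizure is a false
#' detection. Every detector event is classified exactly once (matched or
#' false detection), and an event straddling two gold seizures marks both
#' detected without becoming a false detection.
#'
#' Intervals are half-open `[start, end)`; touching intervals (one ending
#' exactly where the other starts) do not overlap. `tolerance` optionally
#' dilates each detector event by that many seconds on both sides before
#' overlap testing (default 0: strict coincidence).
#'
#' @param gold annotation table from [seizure_annotations()] for one record.
#' @param detections event table from [detection_events()] for the same
#'   record at one threshold. May be empty.
#' @param tolerance non-negative seconds of temporal slack (default 0).
#'
#' @return An object of class `"sda_match"`: a list with `detected` (logical,
#'   one flag per gold seizure in `gold` order), `false_detections` (the
#'   subset of `detections` overlapping no gold seizure), `n_gold`,
#'   `n_events`, `threshold`, and `record_id`.
#' @examples
#' gold <- seizure_annotations("r1", 10, 60)
#' det <- detection_events("r1", 50, 20, "F4-C4", threshold = 0.4)
#' m <- match_events(gold, det)
#' m$detected
#' @export
match_events <- function(gold, detections, tolerance = 0) {
  stopifnot(is.data.frame(gold), is.data.frame(detections), tolerance >= 0)
  rid <- unique(c(gold$record_id, detections$record_id))
  if (length(rid) > 1)
    stop("match_events expects a single record; got: ",
         paste(rid, collapse = ", "))
  thr <- unique(detections$threshold)
  if (length(thr) > 1)
    stop("detections mix thresholds: ", paste(thr, collapse = ", "))
  ng <- nrow(gold); ne <- nrow(detections)
  if (ng == 0) {
    detected <- logical(0)
    matched <- rep(FALSE, ne)
  } else if (ne == 0) {
    detected <- rep(FALSE, ng)
    matched <- logical(0)
  } else {
    ds <- detections$start - tolerance
    de <- detections$end + tolerance
    # half-open overlap: [a,b) meets [c,d) iff a < d and c < b
    ov <- outer(gold$start, de, `<`) & outer(gold$end, ds, `>`)
    detected <- apply(ov, 1L, any)
    matched <- apply(ov, 2L, any)
  }
  structure(list(
    detected = detected,
    false_detections = detections[!matched, , drop = FALSE],
    n_gold = ng, n_events = ne,
    threshold = if (length(thr)) thr else NA_real_,
    record_id = if (length(rid)) rid else NA_character_
  ), class = "sda_match")
}

#' @export
print.sda_match <- function(x, ...) {
  cat(sprintf("<sda_match> record %s, threshold %s: %d/%d seizures detected, %d false detections\n",
              x$record_id, format(x$threshold), sum(x$detected), x$n_gold,
              nrow(x$false_detections)))
  invisible(x)
}

#' Seizure detection rate
#'
#' Percentage of gold-standard seizures overlapped by at least one detector
#' event. Undefined when there are no gold seizures, in which case `NA` is
#' returned with a warning rather than a misleading 0 or 100.
#'
#' @param detected logical vector of per-seizure detection flags (e.g.
#'   `match_events(...)$detected`).
#' @return Percentage in `[0, 100]`, or `NA_real_` if `detected` is empty.
#' @examples
#' seizure_detection_rate(c(TRUE, TRUE, FALSE, TRUE))
#' @export
seizure_detection_rate <- function(detected) {
  stopifnot(is.logical(detected), !anyNA(detected))
  if (length(detected) == 0) {
    warning("seizure detection rate undefined: no gold seizures")
    return(NA_real_)
  }
  100 * sum(detected) / length(detected)
}

#' False detections per hour
#'
#' @param false_detections either a detection-event table of false detections
#'   or a single non-negative count.
#' @param total_hours total recording duration in hours (> 0); false
#'   detection rates are computed over the whole recording, seizure time
#'   included.
#' @return Events per hour.
#' @examples
#' fd_rate(3, total_hours = 1.5)
#' @export
fd_rate <- function(false_detections, total_hours) {
  if (length(total_hours) != 1 || is.na(total_hours) || total_hours <= 0)
    stop("total_hours must be a single positive number")
  n <- if (is.data.frame(false_detections)) nrow(false_detections)
       else as.numeric(false_detections)
  if (length(n) != 1 || is.na(n) || n < 0) stop("invalid false detection count")
  n / total_hours
}

#' Epoch-based sensitivity and specificity
#'
#' Tiles a record into non-overlapping epochs and labels each epoch positive
#' for the gold standard (resp. the detector) if it overlaps any annotated
#' (resp. detected) interval. Sensitivity is the percentage of gold-positive
#' epochs flagged by the detector (seizure burden captured); specificity the
#' percentage of gold-negative epochs left unflagged.
#'
#' @param gold annotation table for one record.
#' @param detections event table for the same record.
#' @param duration_hours record duration in hours.
#' @param epoch_len epoch length in seconds (default 1).
#' @return A list with `sensitivity` and `specificity` (percent; `NA` when
#'   the denominator class is absent), and the confusion counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
epoch_metrics <- function(gold, detections, duration_hours, epoch_len = 1) {
  stopifnot(epoch_len > 0, duration_hours > 0)
  dur_s <- duration_hours * 3600
  n_ep <- floor(dur_s / epoch_len)
  if (n_ep < 1) stop("record shorter than one epoch")
  lab <- function(iv) {
    pos <- logical(n_ep)
    for (i in seq_len(nrow(iv))) {
      first <- floor(iv$start[i] / epoch_len) + 1L
      last <- ceiling(iv$end[i] / epoch_len)
      pos[max(1L, first):min(n_ep, last)] <- TRUE
    }
    pos
  }
  g <- lab(gold); d <- lab(detections)
  tp <- sum(g & d); fn <- sum(g & !d); fp <- sum(!g & d); tn <- sum(!g & !d)
  list(sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Per-threshold performance sweep across a cohort
#'
#' Runs [match_events()] record by record for each sensitivity threshold and
#' pools the results: cohort seizure detection rate, false detections per
#' hour (total false detections over total recorded hours, i.e. weighted by
#' record duration), and pooled epoch-based sensitivity/specificity.
#'
#' @param gold annotation table covering all records (may span records).
#' @param detections_by_threshold named list of detection-event tables, one
#'   per threshold; names are the thresholds (e.g. `"0.4"`), and each table
#'   must carry a single matching `threshold` value.
#' @param records [record_meta()] table for every record analysed; records
#'   with no detections and no annotations still contribute duration to the
#'   false-detection denominator.
#' @param epoch_len epoch length in seconds for epoch metrics (default 1).
#' @param tolerance matching tolerance in seconds (default 0).
#'
#' @return An object of class `"sda_sweep"`: list with `metrics` (one row per
#'   threshold: `threshold`, `n_gold`, `n_detected`, `sdr_pct`, `n_fd`,
#'   `fd_per_hour`, `epoch_sensitivity_pct`, `epoch_specificity_pct`),
#'   `per_record` (record-level detail), and `false_detections` (named list
#'   of false-detection event tables per threshold).
#' @export
threshold_sweep <- function(gold, detections_by_threshold, records,
                            epoch_len = 1, tolerance = 0) {
  if (!is.list(detections_by_threshold) || length(detections_by_threshold) < 1)
    stop("detections_by_threshold must be a non-empty named list")
  thr <- vapply(detections_by_threshold, function(d) {
    t <- unique(d$threshold)
    if (length(t) != 1) stop("each detection table must have one threshold")
    t
  }, numeric(1))
  total_hours <- sum(records$duration_hours)
  metrics <- NULL; per_record <- NULL; fds <- list()
  for (k in seq_along(thr)) {
    det <- detections_by_threshold[[k]]
    flags <- logical(0); n_fd <- 0L
    tp <- fp <- tn <- fn <- 0
    fd_k <- det[0, , drop = FALSE]
    for (r in records$record_id) {
      g_r <- gold[gold$record_id == r, , drop = FALSE]
      d_r <- det[det$record_id == r, , drop = FALSE]
      m <- match_events(g_r, d_r, tolerance = tolerance)
      flags <- c(flags, m$detected)
      fd_k <- rbind(fd_k, m$false_detections)
      n_fd <- n_fd + nrow(m$false_detections)
      em <- epoch_metrics(g_r, d_r,
                          records$duration_hours[records$record_id == r],
                          epoch_len = epoch_len)
      tp <- tp + em$tp; fp <- fp + em$fp; tn <- tn + em$tn; fn <- fn + em$fn
      per_record <- rbind(per_record, data.frame(
        threshold = thr[k], record_id = r, n_gold = m$n_gold,
        n_detected = sum(m$detected), n_fd = nrow(m$false_detections),
        fd_per_hour = nrow(m$false_detections) /
          records$duration_hours[records$record_id == r],
        stringsAsFactors = FALSE))
    }
    metrics <- rbind(metrics, data.frame(
      threshold = thr[k], n_gold = length(flags), n_detected = sum(flags),
      sdr_pct = if (length(flags)) 100 * mean(flags) else NA_real_,
      n_fd = n_fd, fd_per_hour = n_fd / total_hours,
      epoch_sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      epoch_specificity_pct = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_))
    fds[[format(thr[k])]] <- fd_k
  }
  metrics <- metrics[order(metrics$threshold), , drop = FALSE]
  structure(list(metrics = metrics, per_record = per_record,
                 false_detections = fds, total_hours = total_hours),
            class = "sda_sweep")
}

#' @export
print.sda_sweep <- function(x, ...) {
  cat(sprintf("<sda_sweep> %d thresholds over %.1f h\n",
              nrow(x$metrics), x$total_hours))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
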