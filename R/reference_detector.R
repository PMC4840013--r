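#' Reference detector configuration
#'
#' A minimal, fully transparent seizure detector used to exercise the audit
#' pipeline end to end. Per channel the EEG is epoched (8 s windows, 50%
#' overlap), a small feature vector is computed per epoch (log RMS
#' amplitude, spectral concentration around the dominant in-band peak,
#' normalized spectral entropy), a fixed linear score is squashed through a
#' sigmoid into a seizure probability, and the probability sequence is
#' smoothed by a moving-average filter. The cross-channel probability is the
#' per-epoch maximum; events are maximal runs above a threshold. Epochs of
#' extreme signal energy (gross movement artefact) are pre-masked to zero
#' probability. The score weights are fixed documented constants, not
#' trained: the point of the detector is to be auditable, not clinical.
#'
#' @param epoch_len epoch length in seconds (default 8).
#' @param overlap fractional epoch overlap in `[0, 1)` (default 0.5).
#' @param smooth_epochs moving-average window in epochs (default 3).
#' @param band analysis band in Hz (default 0.3--12).
#' @param peak_halfwidth halfwidth in Hz of the spectral-concentration
#'   window around the peak (default 0.4).
#' @param weights named numeric: `intercept`, `log_rms` (per log-µV above
#'   the 25 µV reference), `concentration`, `entropy` (applied to
#'   1 - normalized entropy).
#' @param mask_rms epoch RMS in µV above which the epoch is treated as
#'   high-energy artefact and masked (default 300).
#' @param thresholds sensitivity grid for event extraction.
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(epoch_len = 8, overlap = 0.5, smooth_epochs = 3,
                            band = c(0.3, 12), peak_halfwidth = 0.4,
                            weights = c(intercept = -4.2, log_rms = 1.9,
                                        concentration = 5.2, entropy = 3.0),
                            mask_rms = 300,
                            thresholds = c(0.4, 0.5, 0.6)) {
  stopifnot(epoch_len > 0, overlap >= 0, overlap < 1, smooth_epochs >= 1,
            length(band) == 2, band[1] > 0, band[2] > band[1],
            all(c("intercept", "log_rms", "concentration", "entropy") %in%
                  names(weights)),
            mask_rms > 0)
  structure(as.list(environment()), class = "detector_config")
}

epoch_features <- function(x, fs, band, peak_halfwidth) {
  n <- length(x)
  rms <- sqrt(mean(x^2))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))
  spec <- Mod(stats::fft((x - mean(x)) * w))^2
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= band[1] & freq <= band[2]
  p <- spec[keep]
  if (sum(p) == 0)
    return(c(rms = rms, concentration = 0, entropy = 1))
  f <- freq[keep]
  pk <- which.max(p)
  conc <- sum(p[abs(f - f[pk]) <= peak_halfwidth]) / sum(p)
  q <- p / sum(p)
  H <- -sum(ifelse(q > 0, q * log(q), 0)) / log(length(q))
  c(rms = rms, concentration = conc, entropy = H)
}

#' Run the reference detector on a multichannel EEG segment
#'
#' @param eeg an `sda_eeg` object from [synthesize_eeg()], or a list with
#'   `data` (samples x channels), `fs`, and `channels`.
#' @param config a [detector_config()].
#' @param record_id record identifier stamped on the output events.
#' @return A list of class `"sda_detector_run"`: `trace` (class
#'   `"sda_prob_trace"`: per-channel and combined smoothed probabilities per
#'   epoch, epoch start `times`, `epoch_step`, `epoch_len`) and `events`
#'   (named list of [detection_events()] tables, one per threshold).
#' @examples
#' eeg <- synthesize_eeg(eeg_segment_spec("seizure", duration = 60,
#'                                        amplitude = 150, seed = 2))
#' run <- reference_detector(eeg)
#' run$events[["0.4"]]
#' @export
reference_detector <- function(eeg, config = detector_config(),
                               record_id = "synthetic") {
  stopifnot(inherits(config, "detector_config"))
  data <- eeg$data; fs <- eeg$fs
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  chan <- if (!is.null(eeg$channels)) eeg$channels
          else colnames(data)
  if (is.null(chan)) stop("unknown channel labels")
  n <- nrow(data)
  len <- round(config$epoch_len * fs)
  step <- max(1, round(len * (1 - config$overlap)))
  if (n < len) stop("segment shorter than one epoch")
  starts <- seq(1, n - len + 1, by = step)
  wts <- config$weights
  prob <- matrix(NA_real_, length(starts), ncol(data))
  for (ch in seq_len(ncol(data))) {
    feats <- t(vapply(starts, function(s)
      epoch_features(data[s:(s + len - 1), ch], fs, config$band,
                     config$peak_halfwidth), numeric(3)))
    score <- wts[["intercept"]] +
      wts[["log_rms"]] * log(pmax(feats[, "rms"], 1e-6) / 25) +
      wts[["concentration"]] * feats[, "concentration"] +
      wts[["entropy"]] * (1 - feats[, "entropy"])
    p <- stats::plogis(score)
    p[feats[, "rms"] > config$mask_rms] <- 0 # high-energy artefact mask
    k <- min(config$smooth_epochs, length(p))
    prob[, ch] <- stats::filter(p, rep(1 / k, k), sides = 2)
  }
  # moving-average edges: fall back to the unsmoothed tails
  prob[is.na(prob)] <- 0
  colnames(prob) <- chan
  trace <- structure(list(record_id = record_id,
                          times = (starts - 1) / fs,
                          epoch_step = step / fs,
                          epoch_len = config$epoch_len,
                          values = prob,
                          combined = apply(prob, 1, max)),
                     class = "sda_prob_trace")
  events <- lapply(config$thresholds, function(t)
    trace_events(trace, t, record_id = record_id))
  names(events) <- format(config$thresholds)
  structure(list(trace = trace, events = events, config = config),
            class = "sda_detector_run")
}

#' @export
print.sda_prob_trace <- function(x, ...) {
  cat(sprintf("<sda_prob_trace> %s: %d epochs x %d channels (step %gs), combined max %.2f\n",
              x$record_id, nrow(x$values), ncol(x$values), x$epoch_step,
              max(x$combined)))
  invisible(x)
}

#' @export
print.sda_detector_run <- function(x, ...) {
  print(x$trace)
  for (t in names(x$events))
    cat(sprintf("  threshold %s: %d event(s)\n", t, nrow(x$events[[t]])))
  invisible(x)
}

#' Extract detection events from a probability trace
#'
#' Maximal runs of the combined (cross-channel maximum) probability at or
#' above the threshold become events; each is reported with onset, duration
#' and the channel holding the peak probability within the run.
#'
#' @param trace an `"sda_prob_trace"`.
#' @param threshold sensitivity threshold in `[0, 1]`.
#' @param record_id record identifier for the event table.
#' @return A [detection_events()] table.
#' @export
trace_events <- function(trace, threshold, record_id = trace$record_id) {
  check_threshold(threshold)
  above <- trace$combined >= threshold
  if (!any(above))
    return(detection_events(character(), numeric(), numeric(),
                            threshold = threshold))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  on <- which(r$values)
  ev <- lapply(on, function(k) {
    i <- begins[k]; j <- ends[k]
    pk <- i - 1 + which.max(apply(trace$values[i:j, , drop = FALSE], 1, max))
    data.frame(start = trace$times[i],
               duration = trace$times[j] - trace$times[i] + trace$epoch_len,
               peak_channel = colnames(trace$values)[
                 which.max(trace$values[pk, ])],
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  detection_events(rep(record_id, nrow(ev)), ev$start, ev$duration,
                   ev$peak_channel, threshold = threshold)
}

#' Adaptive local-baseline correction of a probability trace
#'
#' Artefacts such as respiration, pulse or sweat often run for long
#' stretches, raising the detector's probability baseline and causing
#' sustained false detections. This correction compares the probability at
#' each epoch with the local preceding baseline — the trailing-window median
#' — subtracts it, and rescales the remainder to `[0, 1]`: prolonged
#' elevations are suppressed while transient excursions (true seizures)
#' stand clear of the local baseline and are preserved.
#'
#' @param trace an `"sda_prob_trace"`.
#' @param window_minutes trailing baseline window (default 30 min); traces
#'   shorter than the window use whatever history is available, with a
#'   warning.
#' @return A corrected `"sda_prob_trace"` (per-channel and combined values
#'   replaced).
#' @export
adaptive_baseline <- function(trace, window_minutes = 30) {
  stopifnot(inherits(trace, "sda_prob_trace"), window_minutes > 0)
  w <- max(1L, round(window_minutes * 60 / trace$epoch_step))
  n_ep <- nrow(trace$values)
  if (n_ep < w)
    warning("trace shorter than the baseline window; using available history")
  v <- trace$values
  out <- v
  for (ch in seq_len(ncol(v))) {
    x <- v[, ch]
    m <- vapply(seq_len(n_ep), function(i)
      stats::median(x[max(1L, i - w + 1L):i]), numeric(1))
    # rescale the headroom above the local baseline back towards [0, 1];
    # the floor keeps a near-saturated baseline from amplifying its own
    # fluctuations
    out[, ch] <- pmax(0, x - m) / pmax(1 - m, 0.5)
  }
  out <- pmin(out, 1)
  trace$values <- out
  trace$combined <- apply(out, 1, max)
  trace
}
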