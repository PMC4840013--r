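#' Seizure assessment schema: category levels
#'
#' Closed vocabularies for the visual scores in the ten-criterion seizure
#' assessment schema. Morphology of the discharge is coded as rhythmic
#' discharges of delta (RDD), theta (RDT) or alpha (RDA), spikes/sharp waves
#' (SH), or sharp-and-slow-wave / spike-and-wave complexes (SH+W/SP+W). At
#' seizure onset all five levels occur; at seizure peak the RDA level is
#' rarely seen and a four-level variant is available.
#'
#' @param variant `"onset"` (five levels) or `"peak"` (four levels, no RDA).
#' @return Character vector of allowed morphology codes.
#' @examples
#' morphology_levels()
#' morphology_levels("peak")
#' @export
morphology_levels <- function(variant = c("onset", "peak")) {
  variant <- match.arg(variant)
  lev <- c("RDD", "RDT", "RDA", "SH", "SH+W/SP+W")
  if (variant == "peak") lev <- setdiff(lev, "RDA")
  lev
}

#' @rdname morphology_levels
#' @export
rhythmicity_levels <- function() {
  c("1" = "significant dysrhythmia", "2" = "minimal dysrhythmia",
    "3" = "highly rhythmic")
}

#' @rdname morphology_levels
#' @export
background_levels <- function() {
  c("1" = "normal", "2" = "moderate abnormality", "3" = "severe abnormality")
}

#' Frequency variability over the span of a seizure
#'
#' The discharge frequency is read at three points — over the first 5 s of
#' the seizure, at mid seizure, and over the last 5 s — and the frequency
#' variability is their sample standard deviation (n − 1 denominator), in Hz.
#'
#' @param f_start,f_peak,f_end discharge frequencies in Hz (> 0) at seizure
#'   start, peak (mid seizure) and end.
#' @return Sample standard deviation in Hz.
#' @examples
#' frequency_variability(1, 2, 3) # 1 Hz
#' @export
frequency_variability <- function(f_start, f_peak, f_end) {
  f <- c(f_start, f_peak, f_end)
  if (length(f) != 3 || anyNA(f) || any(f <= 0))
    stop("all three frequencies must be positive")
  stats::sd(f)
}

#' Peak-to-trough seizure amplitude
#'
#' Quantifies the maximum seizure amplitude as the peak-to-trough excursion
#' (max minus min, in the input's units, conventionally microvolts) over a
#' window centred on the supplied segment's midpoint — emulating the manual
#' graticule measurement on the highest-amplitude discharge at mid seizure.
#' The measure is invariant to DC offset and to sign flips of the signal.
#'
#' @param segment numeric vector, single-channel EEG samples centred on the
#'   seizure midpoint.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds around the segment midpoint over
#'   which the excursion is taken; `NULL` (default) uses the whole segment.
#' @return Peak-to-trough amplitude (same units as `segment`).
#' @examples
#' t <- seq(0, 2, by = 1 / 256)
#' peak_amplitude(50 * sin(2 * pi * 2 * t), fs = 256) # ~100
#' @export
peak_amplitude <- function(segment, fs = NULL, window = NULL) {
  if (length(segment) == 0 || anyNA(segment))
    stop("segment must be non-empty with no missing samples")
  x <- segment
  if (!is.null(window)) {
    if (is.null(fs)) stop("fs is required when window is given")
    half <- round(window * fs / 2)
    mid <- ceiling(length(segment) / 2)
    x <- segment[max(1, mid - half):min(length(segment), mid + half)]
  }
  max(x) - min(x)
}

#' Dominant discharge frequency of an EEG segment
#'
#' Estimates the discharge frequency as the location of the periodogram peak
#' within a band (default 0.3–8 Hz, spanning neonatal delta–theta–alpha
#' discharge rates). A peak-prominence check flags estimates from segments
#' with no clear spectral peak (e.g. broadband noise or background EEG) as
#' low confidence. An autocorrelation-based method is available as an
#' alternative.
#'
#' @param segment numeric vector of single-channel EEG samples (>= 5 s).
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, search band in Hz.
#' @param method `"spectrum"` (periodogram peak, default) or `"acf"`
#'   (first dominant autocorrelation peak).
#' @param min_prominence ratio of peak power to mean in-band power below
#'   which the estimate is flagged low confidence (default 4).
#' @return A list with `frequency` (Hz), `prominence`, and `confident`
#'   (logical). An all-zero or constant segment gives `frequency = NA` with
#'   a warning.
#' @examples
#' t <- seq(0, 10, by = 1 / 256)
#' dominant_frequency(sin(2 * pi * 2 * t), fs = 256)$frequency # 2 Hz
#' @export
dominant_frequency <- function(segment, fs, band = c(0.3, 8),
                               method = c("spectrum", "acf"),
                               min_prominence = 4) {
  method <- match.arg(method)
  if (length(segment) < 5 * fs)
    stop("segment must be at least 5 s long")
  if (stats::sd(segment) == 0) {
    warning("constant segment: dominant frequency undefined")
    return(list(frequency = NA_real_, prominence = NA_real_, confident = FALSE))
  }
  x <- segment - mean(segment)
  if (method == "spectrum") {
    n <- length(x)
    spec <- Mod(stats::fft(x * 0.5 * (1 - cos(2 * pi * seq_len(n) / n))))^2
    freq <- (seq_len(n) - 1) * fs / n
    keep <- freq >= band[1] & freq <= band[2]
    if (!any(keep)) stop("band contains no Fourier frequencies")
    # whiten by f (EEG background is near 1/f) and smooth over 5 bins so a
    # broadband segment does not fake a prominent peak by chance
    p <- spec[keep] * freq[keep]
    k <- min(5, length(p))
    ps <- stats::filter(p, rep(1 / k, k), sides = 2)
    ps[is.na(ps)] <- p[is.na(ps)]
    pk <- which.max(ps)
    f_hat <- freq[keep][pk]
    prom <- ps[pk] / mean(ps)
  } else {
    a <- stats::acf(x, lag.max = round(fs / band[1]), plot = FALSE)$acf[-1]
    lags <- seq_along(a)
    # first local maximum of the acf beyond the zero-crossing
    cand <- which(diff(sign(diff(a))) < 0) + 1L
    cand <- cand[lags[cand] >= fs / band[2]]
    if (!length(cand)) {
      warning("no autocorrelation peak in band")
      return(list(frequency = NA_real_, prominence = NA_real_, confident = FALSE))
    }
    best <- cand[which.max(a[cand])]
    f_hat <- fs / lags[best]
    prom <- max(0, a[best]) * 2 * min_prominence # map r≈0.5 to the default cut
  }
  list(frequency = f_hat, prominence = prom,
       confident = is.finite(prom) && prom >= min_prominence)
}

#' Change in seizure morphology from onset to peak
#'
#' TRUE when the dominant discharge morphology at seizure peak differs from
#' the morphology at onset (e.g. rhythmic delta discharges evolving into
#' sharp-and-slow-wave complexes), capturing within-seizure evolution.
#'
#' @param onset,peak morphology codes; see [morphology_levels()].
#' @return Logical.
#' @examples
#' morphology_change("RDD", "SH+W/SP+W")
#' @export
morphology_change <- function(onset, peak) {
  lev <- morphology_levels("onset")
  bad <- setdiff(c(onset, peak), lev)
  if (length(bad))
    stop("unknown morphology code(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(lev, collapse = ", "), ")")
  onset != peak
}

#' Validate a seizure feature table
#'
#' Checks a per-seizure feature table against the assessment-schema
#' invariants: positive amplitude and duration, ordinal scores in 1..3,
#' morphology codes in the closed vocabulary, non-negative frequency
#' variability, and channel counts in `1..n_channels`. Issues are collected
#' and reported, never thrown, so a partially scored table can be inspected.
#' A seizure involving more channels at onset than at peak is unusual and
#' flagged as a warning rather than an error.
#'
#' @param records data.frame with (a subset of) the columns `seizure_id`,
#'   `baby_id`, `peak_amplitude`, `rhythmicity`, `background_score`,
#'   `morphology_onset`, `morphology_peak`, `duration`,
#'   `frequency_variability`, `morphology_change`, `n_channels_onset`,
#'   `n_channels_peak`, plus any `detected_*` flag columns.
#' @param n_channels number of EEG channels in the montage (default 8).
#' @param peak_variant morphology vocabulary at peak: `"peak"` (4 levels,
#'   default) or `"onset"` (5 levels).
#' @return A list with `data` (the input) and `issues` (data.frame with
#'   `row`, `column`, `severity`, `message`; zero rows when clean).
#' @export
validate_feature_table <- function(records, n_channels = 8,
                                   peak_variant = c("peak", "onset")) {
  peak_variant <- match.arg(peak_variant)
  stopifnot(is.data.frame(records))
  issues <- data.frame(row = integer(), column = character(),
                       severity = character(), message = character(),
                       stringsAsFactors = FALSE)
  flag <- function(rows, column, severity, message) {
    if (length(rows))
      issues <<- rbind(issues, data.frame(row = rows, column = column,
                                          severity = severity,
                                          message = message,
                                          stringsAsFactors = FALSE))
  }
  has <- function(col) col %in% names(records)
  if (has("peak_amplitude"))
    flag(which(!(records$peak_amplitude > 0)), "peak_amplitude", "error",
         "peak amplitude must be > 0 microvolts")
  if (has("duration"))
    flag(which(!(records$duration > 0)), "duration", "error",
         "seizure duration must be > 0 s")
  if (has("frequency_variability"))
    flag(which(records$frequency_variability < 0), "frequency_variability",
         "error", "frequency variability must be >= 0 Hz")
  for (col in c("rhythmicity", "background_score"))
    if (has(col))
      flag(which(!(records[[col]] %in% 1:3)), col, "error",
           "ordinal score must be 1, 2 or 3")
  if (has("morphology_onset"))
    flag(which(!(records$morphology_onset %in% morphology_levels("onset"))),
         "morphology_onset", "error", "unknown morphology code")
  if (has("morphology_peak"))
    flag(which(!(records$morphology_peak %in% morphology_levels(peak_variant))),
         "morphology_peak", "error", "unknown morphology code")
  for (col in c("n_channels_onset", "n_channels_peak"))
    if (has(col))
      flag(which(!(records[[col]] %in% seq_len(n_channels))), col, "error",
           sprintf("channel count must be an integer in 1..%d", n_channels))
  if (has("n_channels_onset") && has("n_channels_peak"))
    flag(which(records$n_channels_onset > records$n_channels_peak),
         "n_channels_onset", "warning",
         "more channels at onset than at peak (unusual; check scoring)")
  if (has("morphology_change") && has("morphology_onset") &&
      has("morphology_peak")) {
    ok <- records$morphology_onset %in% morphology_levels("onset") &
      records$morphology_peak %in% morphology_levels("onset")
    expect <- records$morphology_onset != records$morphology_peak
    flag(which(ok & (records$morphology_change != expect)),
         "morphology_change", "warning",
         "flag disagrees with onset/peak morphology codes")
  }
  list(data = records, issues = issues[order(issues$row), , drop = FALSE])
}
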