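#' Default neonatal bipolar montage labels
#'
#' Eight-channel bipolar montage over the neonatal 10:20 electrode set.
#' @return Character vector of channel labels.
#' @export
bipolar_montage <- function() {
  c("F4-C4", "C4-O2", "F3-C3", "C3-O1", "T4-C4", "C4-Cz", "Cz-C3", "C3-T3")
}

#' Specification of a synthetic EEG segment
#'
#' @param kind one of `"seizure"`, `"background"`, `"respiration_artefact"`,
#'   `"sweat_artefact"`, `"pulse_artefact"`, `"movement_artefact"`.
#' @param duration segment length in seconds (> 0).
#' @param fs sampling rate in Hz (default 256).
#' @param n_channels montage size (default 8, labels from
#'   [bipolar_montage()]).
#' @param channels_involved how many channels carry the seizure/artefact
#'   waveform (remaining channels show background only).
#' @param amplitude peak-to-trough amplitude of the planted waveform in µV
#'   (> 0).
#' @param base_frequency fundamental discharge/artefact frequency in Hz.
#' @param rhythmicity 1 (significant dysrhythmia) to 3 (highly rhythmic);
#'   controls the per-second jitter of the instantaneous frequency
#'   (lower score = more jitter).
#' @param evolution if `TRUE` a seizure's harmonic content evolves from
#'   near-sinusoidal delta discharges at onset to spike-and-slow-wave
#'   complexes at the peak.
#' @param background_rms RMS of the pink-noise background in µV (default 25).
#' @param event_start,event_end onset/offset in seconds of the planted
#'   waveform within the segment; defaults leave 10% padding each side.
#' @param seed integer seed.
#' @return A list of class `"eeg_segment_spec"`.
#' @export
eeg_segment_spec <- function(kind = c("seizure", "background",
                                      "respiration_artefact", "sweat_artefact",
                                      "pulse_artefact", "movement_artefact"),
                             duration = 120, fs = 256, n_channels = 8,
                             channels_involved = n_channels, amplitude = 100,
                             base_frequency = NULL, rhythmicity = 3,
                             evolution = FALSE, background_rms = 25,
                             event_start = NULL, event_end = NULL,
                             seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, amplitude > 0, fs > 0, n_channels >= 1,
            channels_involved >= 1, channels_involved <= n_channels,
            rhythmicity %in% 1:3, background_rms >= 0)
  if (is.null(base_frequency))
    base_frequency <- switch(kind, seizure = 1.5, respiration_artefact = 0.9,
                             sweat_artefact = 0.35, pulse_artefact = 2.2,
                             movement_artefact = NA_real_,
                             background = NA_real_)
  if (is.null(event_start)) event_start <- 0.1 * duration
  if (is.null(event_end)) event_end <- 0.9 * duration
  stopifnot(event_start >= 0, event_end <= duration, event_end > event_start)
  structure(as.list(environment()), class = "eeg_segment_spec")
}

pink_noise <- function(n, fs, rms) {
  # 1/f-power background via spectral shaping of white noise
  if (rms == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + fs / n)
  spec <- spec / sqrt(pmax(f, 0.1))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

jittered_phase <- function(duration, fs, base_frequency, rhythmicity) {
  # instantaneous frequency resampled every second; jitter SD (relative)
  # falls with the rhythmicity score
  rel_sd <- c(`1` = 0.35, `2` = 0.15, `3` = 0.04)[[as.character(rhythmicity)]]
  n_sec <- ceiling(duration)
  f_sec <- base_frequency * pmax(0.2, 1 + stats::rnorm(n_sec, 0, rel_sd))
  f_inst <- rep(f_sec, each = fs)[seq_len(round(duration * fs))]
  list(phase = cumsum(2 * pi * f_inst / fs), f_sec = f_sec)
}

spike_wave <- function(phase) {
  # sharpened waveform: fundamental plus decaying harmonics, peak-normalized
  w <- sin(phase) + 0.55 * sin(2 * phase + 0.7) + 0.30 * sin(3 * phase + 1.1)
  w / max(abs(w))
}

taper <- function(n, frac = 0.15) {
  # cosine ramp-up/down envelope (Tukey window)
  k <- max(1, round(frac * n))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(k) / k))
  env[seq_len(k)] <- ramp
  env[n - seq_len(k) + 1] <- ramp
  env
}

#' Synthesize a multichannel EEG segment with known ground truth
#'
#' Generates toy multichannel EEG: a pink-noise background on every channel,
#' plus (depending on `kind`) a planted seizure discharge or artefact
#' waveform on the first `channels_involved` channels. Seizures are
#' amplitude-enveloped oscillations whose per-second frequency jitter is
#' inversely tied to the rhythmicity score and whose morphology morphs from
#' near-sinusoidal delta to spike-and-slow-wave when `evolution` is set.
#' Artefact kinds: respiration is a sustained low-frequency rhythmic
#' sinusoid; sweat an intermittent slow semi-rhythmic drift; pulse an
#' impulse train at cardiac rate leaking delta; movement high-amplitude
#' broadband bursts.
#'
#' @param spec an [eeg_segment_spec()].
#' @return A list of class `"sda_eeg"`: `data` (samples x channels matrix,
#'   µV), `fs`, `channels` (labels), `annotation` (ground-truth event
#'   interval with `start`/`end` seconds, empty for background), and `spec`.
#' @examples
#' eeg <- synthesize_eeg(eeg_segment_spec("seizure", duration = 30, seed = 1))
#' dim(eeg$data)
#' @export
synthesize_eeg <- function(spec = eeg_segment_spec()) {
  stopifnot(inherits(spec, "eeg_segment_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  chan <- rep_len(bipolar_montage(), spec$n_channels)
  if (spec$n_channels > length(bipolar_montage()))
    chan <- sprintf("ch%02d", seq_len(spec$n_channels))
  data <- vapply(seq_len(spec$n_channels),
                 function(i) pink_noise(n, spec$fs, spec$background_rms),
                 numeric(n))
  ev_idx <- seq(max(1, round(spec$event_start * spec$fs) + 1),
                min(n, round(spec$event_end * spec$fs)))
  m <- length(ev_idx)
  ev_dur <- m / spec$fs
  half <- spec$amplitude / 2 # amplitude is peak-to-trough
  wave <- switch(spec$kind,
    background = NULL,
    seizure = {
      jp <- jittered_phase(ev_dur, spec$fs, spec$base_frequency,
                           spec$rhythmicity)
      ph <- jp$phase[seq_len(m)]
      if (spec$evolution) {
        a <- seq(0, 1, length.out = m) # delta -> spike-and-slow-wave
        (1 - a) * sin(ph) + a * spike_wave(ph)
      } else sin(ph)
    },
    respiration_artefact = sin(2 * pi * spec$base_frequency *
                                 seq_len(m) / spec$fs),
    sweat_artefact = {
      jp <- jittered_phase(ev_dur, spec$fs, spec$base_frequency, 2)
      gate <- rep(stats::runif(ceiling(ev_dur / 8)) < 0.6,
                  each = 8 * spec$fs)[seq_len(m)]
      sin(jp$phase[seq_len(m)]) * ifelse(gate, 1, 0.15)
    },
    pulse_artefact = {
      period <- round(spec$fs / spec$base_frequency)
      imp <- numeric(m)
      imp[seq(1, m, by = period)] <- 1
      kern <- exp(-seq(0, 0.35, by = 1 / spec$fs) * 12) *
        sin(2 * pi * 3 * seq(0, 0.35, by = 1 / spec$fs))
      w <- stats::filter(imp, kern, sides = 1)
      w[is.na(w)] <- 0
      as.numeric(w) / max(abs(w))
    },
    movement_artefact = {
      gate <- rep(stats::runif(ceiling(ev_dur / 2)) < 0.5,
                  each = 2 * spec$fs)[seq_len(m)]
      stats::rnorm(m) * ifelse(gate, 1, 0.05) / 3
    })
  if (!is.null(wave)) {
    wave <- wave * taper(m) * half
    for (i in seq_len(spec$channels_involved)) {
      gain <- if (spec$kind == "seizure" && i > 1)
        stats::runif(1, 0.6, 0.95) else 1
      data[ev_idx, i] <- data[ev_idx, i] + wave * gain
    }
  }
  annotation <- if (spec$kind == "seizure")
    data.frame(start = spec$event_start, end = spec$event_end)
  else data.frame(start = numeric(), end = numeric())
  colnames(data) <- chan
  structure(list(data = data, fs = spec$fs, channels = chan,
                 annotation = annotation, spec = spec),
            class = "sda_eeg")
}

#' @export
print.sda_eeg <- function(x, ...) {
  cat(sprintf("<sda_eeg> %s: %.0f s x %d channels @ %g Hz\n",
              x$spec$kind, nrow(x$data) / x$fs, ncol(x$data), x$fs))
  invisible(x)
}
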