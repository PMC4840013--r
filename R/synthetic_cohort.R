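#' Configuration for a synthetic seizure cohort
#'
#' Bundles every knob of the cohort generator: cohort size, per-baby seizure
#' counts, feature distributions, the planted detectability model and the
#' sensitivity-threshold grid. The defaults emulate a neonatal monitoring
#' cohort of term babies (half with seizures, half seizure-free, ~60 h of
#' EEG each) with a planted model in which seizure duration, peak amplitude,
#' rhythmicity and the number of channels at seizure peak carry the signal
#' and the remaining features are null.
#'
#' The planted fixed effects are log odds ratios on the features' natural
#' scales: `duration` per second (default `log(1.02)`), `peak_amplitude` per
#' microvolt (`log(1.02)`), `rhythmicity2`/`rhythmicity3` against
#' significant dysrhythmia (`log(2.5)`, `log(8)`), and `n_channels_peak` per
#' channel (`log(1.5)`). Effects are applied to mean-centred features so
#' `intercept` sets the central log-odds of detection directly.
#'
#' @param n_babies number of babies WITH seizures (>= 2).
#' @param n_nonseizure_babies seizure-free babies added to the record table.
#' @param seizures_per_baby mean of the (zero-truncated) Poisson seizure
#'   count per seizure baby.
#' @param thresholds strictly increasing sensitivity grid in (0, 1).
#' @param betas named list of planted log odds ratios (see Details); any
#'   feature not named is null.
#' @param intercept central log-odds of the latent detectability.
#' @param random_intercept_sd SD of the per-baby random intercept (>= 0).
#' @param mean_record_hours,sd_log_record_hours lognormal record-duration
#'   parameters (hours).
#' @param duration_meanlog,duration_sdlog lognormal seizure duration (s).
#' @param amplitude_meanlog,amplitude_sdlog lognormal peak amplitude (µV).
#' @param rhythmicity_probs,background_probs level probabilities (length 3).
#' @param morphology_onset_probs probabilities over
#'   `morphology_levels("onset")`.
#' @param morphology_evolution_prob chance that a seizure evolves, i.e. that
#'   the peak morphology is redrawn (biased to sharp-and-slow-wave) instead
#'   of staying at its onset morphology.
#' @param n_channels number of montage channels.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_babies = 10, n_nonseizure_babies = 10,
                          seizures_per_baby = 40,
                          thresholds = c(0.4, 0.5, 0.6),
                          betas = list(duration = log(1.02),
                                       peak_amplitude = log(1.02),
                                       rhythmicity2 = log(2.5),
                                       rhythmicity3 = log(8),
                                       n_channels_peak = log(1.5)),
                          intercept = 0.4, random_intercept_sd = 1,
                          mean_record_hours = 63.1, sd_log_record_hours = 0.35,
                          duration_meanlog = log(60), duration_sdlog = 0.8,
                          amplitude_meanlog = log(70), amplitude_sdlog = 0.5,
                          rhythmicity_probs = c(0.25, 0.35, 0.40),
                          background_probs = c(0.30, 0.50, 0.20),
                          morphology_onset_probs = c(0.45, 0.20, 0.05, 0.15, 0.15),
                          morphology_evolution_prob = 0.45,
                          n_channels = 8, seed = NULL) {
  stopifnot(n_babies >= 2, n_nonseizure_babies >= 0, seizures_per_baby > 0,
            random_intercept_sd >= 0, n_channels >= 1)
  if (length(thresholds) < 1 || any(thresholds <= 0) || any(thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing within (0, 1)")
  stopifnot(length(rhythmicity_probs) == 3, length(background_probs) == 3,
            length(morphology_onset_probs) == 5)
  structure(as.list(environment()), class = "cohort_config")
}

rtpois <- function(n, lambda) {
  # zero-truncated Poisson via rejection (lambda moderate here)
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

#' Generate a synthetic cohort with a planted detectability model
#'
#' Draws a cohort of babies, per-baby records, and per-seizure feature
#' records carrying detected/non-detected flags at every threshold of the
#' grid. Each seizure gets a latent detection probability
#' `p = logistic(eta + u)` where `eta` is the planted linear predictor
#' (intercept + per-baby random intercept + planted effects on the centred
#' features) and `u` is standard-logistic noise; the seizure is detected at
#' threshold `t` iff `p >= t`. This single-draw construction guarantees that
#' the detected sets are nested across thresholds, and makes the detection
#' indicator at each threshold follow exactly the random-intercept logistic
#' model with intercept shifted by `-logit(t)` — so a GLMM fitted to the
#' generated table should recover the planted feature effects.
#'
#' @param config a [cohort_config()].
#' @return A list of class `"sda_cohort"`: `records` ([record_meta()] table
#'   for seizure and non-seizure babies), `features` (one row per seizure
#'   with the ten schema features plus `detected_<t>` flag columns), and
#'   `truth` (planted betas, centres used, per-baby intercepts, latent
#'   probabilities).
#' @examples
#' coh <- generate_cohort(cohort_config(n_babies = 4, seizures_per_baby = 5,
#'                                      seed = 42))
#' head(coh$features)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  n_all <- cfg$n_babies + cfg$n_nonseizure_babies
  baby_id <- sprintf("baby%02d", seq_len(n_all))
  grp <- rep(c("seizure", "non-seizure"),
             c(cfg$n_babies, cfg$n_nonseizure_babies))
  records <- record_meta(
    record_id = sprintf("rec%02d", seq_len(n_all)),
    baby_id = baby_id,
    duration_hours = stats::rlnorm(n_all,
                                   log(cfg$mean_record_hours) -
                                     cfg$sd_log_record_hours^2 / 2,
                                   cfg$sd_log_record_hours),
    group = grp)
  sz_babies <- baby_id[grp == "seizure"]
  n_sz <- rtpois(cfg$n_babies, cfg$seizures_per_baby)
  bid <- rep(sz_babies, n_sz)
  n <- length(bid)

  duration <- stats::rlnorm(n, cfg$duration_meanlog, cfg$duration_sdlog)
  amplitude <- stats::rlnorm(n, cfg$amplitude_meanlog, cfg$amplitude_sdlog)
  rhythmicity <- sample(1:3, n, TRUE, cfg$rhythmicity_probs)
  background <- sample(1:3, n, TRUE, cfg$background_probs)
  onset_lev <- morphology_levels("onset")
  morph_on <- sample(onset_lev, n, TRUE, cfg$morphology_onset_probs)
  # evolution redraws the peak morphology, biased towards sharp-and-slow-wave
  evolves <- stats::runif(n) < cfg$morphology_evolution_prob
  peak_lev <- morphology_levels("peak")
  morph_pk <- morph_on
  morph_pk[morph_pk == "RDA"] <- "RDT" # RDA rarely persists to peak
  redraw <- sample(peak_lev, n, TRUE, prob = c(0.10, 0.10, 0.20, 0.60))
  morph_pk[evolves] <- redraw[evolves]
  morph_change <- morph_on != morph_pk
  n_ch_peak <- 1L + stats::rbinom(n, cfg$n_channels - 1L, 0.45)
  n_ch_onset <- pmax(1L, n_ch_peak - stats::rbinom(n, 2, 0.45))
  f3 <- matrix(stats::rlnorm(3 * n, log(1.2), 0.45), ncol = 3)
  freq_var <- apply(f3, 1, stats::sd)

  x <- data.frame(duration = duration, peak_amplitude = amplitude,
                  rhythmicity2 = as.numeric(rhythmicity == 2),
                  rhythmicity3 = as.numeric(rhythmicity == 3),
                  background2 = as.numeric(background == 2),
                  background3 = as.numeric(background == 3),
                  morphology_change = as.numeric(morph_change),
                  frequency_variability = freq_var,
                  n_channels_onset = n_ch_onset,
                  n_channels_peak = n_ch_peak)
  beta <- stats::setNames(numeric(ncol(x)), names(x))
  for (nm in names(cfg$betas)) {
    if (!nm %in% names(beta)) stop("unknown planted effect: ", nm)
    beta[nm] <- cfg$betas[[nm]]
  }
  centres <- colMeans(x)
  b_baby <- stats::setNames(stats::rnorm(cfg$n_babies, 0,
                                         cfg$random_intercept_sd), sz_babies)
  eta <- cfg$intercept + b_baby[bid] +
    as.numeric(as.matrix(sweep(x, 2, centres)) %*% beta)
  u <- stats::rlogis(n)
  p_latent <- stats::plogis(eta + u)

  features <- data.frame(seizure_id = sprintf("sz%04d", seq_len(n)),
                         baby_id = bid,
                         peak_amplitude = amplitude,
                         rhythmicity = rhythmicity,
                         background_score = background,
                         morphology_onset = morph_on,
                         morphology_peak = morph_pk,
                         duration = duration,
                         frequency_variability = freq_var,
                         morphology_change = morph_change,
                         n_channels_onset = n_ch_onset,
                         n_channels_peak = n_ch_peak,
                         stringsAsFactors = FALSE)
  for (t in cfg$thresholds)
    features[[paste0("detected_", format(t))]] <- as.numeric(p_latent >= t)

  structure(list(records = records, features = features,
                 truth = list(betas = beta, centres = centres,
                              intercept = cfg$intercept, b_baby = b_baby,
                              eta = eta, p_latent = p_latent),
                 config = cfg),
            class = "sda_cohort")
}

#' @export
print.sda_cohort <- function(x, ...) {
  cat(sprintf("<sda_cohort> %d babies (%d with seizures), %d seizures, thresholds %s\n",
              nrow(x$records), x$config$n_babies, nrow(x$features),
              paste(x$config$thresholds, collapse = "/")))
  invisible(x)
}

#' Configuration for a synthetic false-detection stream
#'
#' @param rates_per_hour named per-category false-detection rates (events per
#'   hour at the most sensitive threshold); names from [fd_categories()].
#'   Defaults are scaled from an audited cohort's per-category totals over
#'   ~1263 h of EEG.
#' @param survival matrix (category x threshold) of non-increasing retention
#'   probabilities; first column must be 1. Row defaults encode that
#'   sustained rhythmic artefacts (respiration, ECG/pulse) survive threshold
#'   raises while intermittent semi-rhythmic ones (sweat, movement) drop
#'   sharply.
#' @param thresholds increasing sensitivity grid matching `survival` columns.
#' @param concentration Dirichlet concentration of the per-patient spread of
#'   each category (small values concentrate a category in few patients).
#' @param subcategory_probs background-description probabilities for
#'   `no_artefact` events, over [fd_background_subcategories()].
#' @param seed integer seed.
#' @return A list of class `"fd_stream_config"`.
#' @export
fd_stream_config <- function(rates_per_hour = c(respiration = 0.22,
                                                ecg_pulse = 0.027,
                                                chewing_sucking = 0.008,
                                                bad_electrode = 0.017,
                                                movement_handling = 0.045,
                                                electronic_equipment = 0.008,
                                                sweat = 0.127,
                                                unclassified_artefact = 0.023,
                                                no_artefact = 0.175),
                             survival = NULL,
                             thresholds = c(0.4, 0.5, 0.6),
                             concentration = 0.3,
                             subcategory_probs = c(normal_background = 0.30,
                                                   highly_rhythmic = 0.60,
                                                   sharp_waves = 0.09,
                                                   low_amplitude = 0.01),
                             seed = NULL) {
  bad <- setdiff(names(rates_per_hour), fd_categories())
  if (length(bad)) stop("unknown category in rates: ", paste(bad, collapse = ", "))
  if (any(rates_per_hour < 0)) stop("rates must be >= 0")
  if (is.null(survival)) {
    survival <- rbind(respiration = c(1, 0.90, 0.80),
                      ecg_pulse = c(1, 0.95, 0.90),
                      chewing_sucking = c(1, 0.60, 0.30),
                      bad_electrode = c(1, 0.52, 0.19),
                      movement_handling = c(1, 0.28, 0.07),
                      electronic_equipment = c(1, 0.60, 0.33),
                      sweat = c(1, 0.61, 0.09),
                      unclassified_artefact = c(1, 0.66, 0.34),
                      no_artefact = c(1, 0.43, 0.21))[names(rates_per_hour), ,
                                                      drop = FALSE]
  }
  survival <- as.matrix(survival)
  if (ncol(survival) != length(thresholds))
    stop("survival needs one column per threshold")
  if (any(survival[, 1] != 1))
    stop("survival profiles must start at 1 at the most sensitive threshold")
  if (any(t(apply(survival, 1, diff)) > 1e-12))
    stop("survival profiles must be non-increasing in threshold")
  stopifnot(concentration > 0, abs(sum(subcategory_probs) - 1) < 1e-6)
  structure(as.list(environment())[c("rates_per_hour", "survival",
                                     "thresholds", "concentration",
                                     "subcategory_probs", "seed")],
            class = "fd_stream_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Generate a patient-clustered false-detection stream
#'
#' Simulates categorized false detections over a cohort of records with
#' known ground truth. Per category, the event count is Poisson with the
#' configured rate over the total recorded hours; events are spread over
#' patients by a Dirichlet-multinomial draw (low concentration reproduces
#' the real-world pattern of single patients dominating a category); and
#' each event carries a latent detector-probability level so that the event
#' lists at higher thresholds are exact subsets of the lists at lower ones,
#' with per-category marginal retention given by the survival profile.
#'
#' @param config an [fd_stream_config()].
#' @param records a [record_meta()] table (durations set the exposure).
#' @return A list of class `"sda_fd_stream"`: `by_threshold` (named list of
#'   labelled false-detection tables, one per threshold), `records`, and
#'   `truth` (the config plus realized per-category counts).
#' @export
generate_fd_stream <- function(config = fd_stream_config(), records) {
  stopifnot(inherits(config, "fd_stream_config"), is.data.frame(records))
  if (!is.null(config$seed)) set.seed(config$seed)
  total_hours <- sum(records$duration_hours)
  npat <- nrow(records)
  all_ev <- NULL
  for (cat in names(config$rates_per_hour)) {
    n_cat <- stats::rpois(1, config$rates_per_hour[[cat]] * total_hours)
    if (n_cat == 0) next
    w <- rdirichlet1(rep(config$concentration, npat))
    pat_idx <- sample.int(npat, n_cat, TRUE, prob = w)
    dur <- stats::runif(n_cat, 20, 120)
    start <- stats::runif(n_cat) *
      pmax(1, records$duration_hours[pat_idx] * 3600 - dur)
    lev <- stats::runif(n_cat)
    sub <- rep(NA_character_, n_cat)
    if (cat == "no_artefact")
      sub <- sample(fd_background_subcategories(), n_cat, TRUE,
                    config$subcategory_probs)
    all_ev <- rbind(all_ev, data.frame(
      record_id = records$record_id[pat_idx],
      patient_id = records$baby_id[pat_idx],
      start = start, duration = dur,
      category = cat, subcategory = sub, level = lev,
      stringsAsFactors = FALSE))
  }
  by_threshold <- list()
  for (j in seq_along(config$thresholds)) {
    t <- config$thresholds[j]
    if (is.null(all_ev)) {
      keep <- data.frame(record_id = character(), patient_id = character(),
                         start = numeric(), duration = numeric(),
                         category = character(), subcategory = character(),
                         stringsAsFactors = FALSE)
    } else {
      surv <- config$survival[all_ev$category, j]
      keep <- all_ev[all_ev$level <= surv, names(all_ev) != "level",
                     drop = FALSE]
    }
    keep$threshold <- rep(t, nrow(keep))
    by_threshold[[format(t)]] <- fd_records(keep, keep$category,
                                            keep$subcategory,
                                            keep$patient_id)
  }
  structure(list(by_threshold = by_threshold, records = records,
                 truth = list(config = config,
                              n_events = if (is.null(all_ev)) 0
                                         else nrow(all_ev),
                              total_hours = total_hours)),
            class = "sda_fd_stream")
}

#' @export
print.sda_fd_stream <- function(x, ...) {
  cat(sprintf("<sda_fd_stream> %d base events over %.0f h at thresholds %s\n",
              x$truth$n_events, x$truth$total_hours,
              paste(names(x$by_threshold), collapse = "/")))
  invisible(x)
}
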