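# Shared fixtures and independent oracles for the test suite.

# Brute-force O(n*m) interval-overlap matcher: the independent oracle for
# match_events(). Half-open intervals, optional symmetric tolerance.
bf_match <- function(gold, det, tol = 0) {
  ng <- nrow(gold); ne <- nrow(det)
  detected <- rep(FALSE, ng)
  matched <- rep(FALSE, max(ne, 0))
  if (ng && ne) {
    for (i in seq_len(ng)) for (j in seq_len(ne)) {
      if (gold$start[i] < det$end[j] + tol &&
          det$start[j] - tol < gold$end[i]) {
        detected[i] <- TRUE
        matched[j] <- TRUE
      }
    }
  }
  list(detected = detected, fd_idx = which(!matched))
}

# Random small matching instance on one record.
random_instance <- function(n_gold, n_det, horizon = 1000, threshold = 0.5) {
  gs <- sort(runif(n_gold, 0, horizon))
  gold <- seizure_annotations(rep("r", n_gold), gs, gs + runif(n_gold, 1, 60))
  ds <- runif(n_det, 0, horizon)
  det <- detection_events(rep("r", n_det), ds, runif(n_det, 1, 40),
                          threshold = threshold)
  rownames(gold) <- NULL
  rownames(det) <- NULL
  list(gold = gold, det = det)
}

# Labelled false-detection fixture holding exactly the printed per-category
# counts of an audited cohort at its least sensitive threshold (0.6), with
# the no-artefact events broken down by EEG background.
fd_fixture_thr06 <- function() {
  counts <- c(respiration = 221, ecg_pulse = 43, bad_electrode = 4,
              movement_handling = 4, sweat = 14, unclassified_artefact = 10)
  sub <- c(highly_rhythmic = 30, normal_background = 11, sharp_waves = 5)
  category <- c(rep(names(counts), counts), rep("no_artefact", sum(sub)))
  subcategory <- c(rep(NA_character_, sum(counts)), rep(names(sub), sub))
  ev <- data.frame(record_id = "pooled", threshold = 0.6,
                   stringsAsFactors = FALSE)[rep(1, length(category)), ,
                                             drop = FALSE]
  fd_records(ev, category, subcategory, patient_id = "pooled")
}

# Per-patient concentration fixtures at the most sensitive threshold:
# 232 of 278 respiration false detections from one patient, and 104 of 149
# sweat false detections from another.
fd_fixture_concentration <- function() {
  resp_pat <- c(rep("patient2", 232), sprintf("patient%02d", 1:46 %% 9 + 3))
  sweat_pat <- c(rep("patient15", 104), sprintf("patient%02d", 1:45 %% 8 + 3))
  pat <- c(resp_pat, sweat_pat)
  category <- rep(c("respiration", "sweat"), c(278, 149))
  ev <- data.frame(record_id = pat, threshold = 0.4,
                   stringsAsFactors = FALSE)
  fd_records(ev, category, NA_character_, patient_id = pat)
}

# Twenty-record cohort metadata totalling 1262.9 h of EEG.
records_fixture <- function() {
  record_meta(sprintf("rec%02d", 1:20), sprintf("baby%02d", 1:20),
              seq(33.145, 93.145, length.out = 20),
              rep(c("seizure", "non-seizure"), each = 10))
}
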