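test_that("cohort generation is deterministic and threshold-nested", {
  cfg <- cohort_config(n_babies = 6, seizures_per_baby = 10, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$records, b$records)

  flags <- a$features[, paste0("detected_", c("0.4", "0.5", "0.6"))]
  # single latent draw: higher-threshold detections nest in lower ones
  expect_true(all(flags[, 1] >= flags[, 2] & flags[, 2] >= flags[, 3]))
  expect_true(all(diff(colSums(flags)) <= 0))
})

test_that("planted marginal detection rates match the latent model", {
  # all effects null, intercept 0: latent p = plogis(logistic noise),
  # i.e. Uniform(0,1), so P(detected at t) = 1 - t
  cfg <- cohort_config(n_babies = 20, seizures_per_baby = 100,
                       betas = list(duration = 0), intercept = 0,
                       random_intercept_sd = 0, seed = 33)
  coh <- generate_cohort(cfg)
  n <- nrow(coh$features)
  for (t in c(0.4, 0.5, 0.6)) {
    phat <- mean(coh$features[[paste0("detected_", format(t))]])
    se <- sqrt(t * (1 - t) / n)
    expect_lt(abs(phat - (1 - t)), 3 * se + 0.005)
  }
})

test_that("zero random-intercept variance leaves only binomial spread", {
  cfg <- cohort_config(n_babies = 40, seizures_per_baby = 60,
                       betas = list(duration = 0), intercept = 0,
                       random_intercept_sd = 0, seed = 35)
  coh <- generate_cohort(cfg)
  rates <- tapply(coh$features$detected_0.5, coh$features$baby_id, mean)
  ns <- tapply(coh$features$detected_0.5, coh$features$baby_id, length)
  p <- mean(coh$features$detected_0.5)
  # between-baby variance of the rate consistent with binomial sampling only
  expect_lt(var(rates), 3 * mean(p * (1 - p) / ns))
})

test_that("feature table from the generator passes schema validation", {
  coh <- generate_cohort(cohort_config(n_babies = 8, seizures_per_baby = 20,
                                       seed = 37))
  v <- validate_feature_table(coh$features)
  expect_equal(sum(v$issues$severity == "error"), 0)
  expect_error(generate_cohort(cohort_config(n_babies = 4, seed = 1,
                                             betas = list(nope = 1))),
               "unknown planted effect")
  expect_error(cohort_config(thresholds = c(0.6, 0.4)), "increasing")
})

test_that("FD stream: determinism, nesting, planted retention and clustering", {
  rec <- records_fixture()
  cfg <- fd_stream_config(seed = 39)
  s1 <- generate_fd_stream(cfg, rec)
  s2 <- generate_fd_stream(cfg, rec)
  expect_identical(s1$by_threshold, s2$by_threshold)

  # higher-threshold lists are subsets of the most sensitive list
  key <- function(d) paste(d$record_id, d$start, d$category)
  expect_true(all(key(s1$by_threshold[["0.5"]]) %in%
                    key(s1$by_threshold[["0.4"]])))
  expect_true(all(key(s1$by_threshold[["0.6"]]) %in%
                    key(s1$by_threshold[["0.5"]])))

  # empirical per-category retention within 3 SE of the survival profile
  cfg2 <- fd_stream_config(
    rates_per_hour = c(respiration = 0.8, sweat = 0.8),
    survival = rbind(respiration = c(1, 0.9, 0.8), sweat = c(1, 0.6, 0.1)),
    seed = 41)
  s3 <- generate_fd_stream(cfg2, rec)
  n04 <- table(s3$by_threshold[["0.4"]]$category)
  n06 <- table(s3$by_threshold[["0.6"]]$category)
  for (cat in c("respiration", "sweat")) {
    p <- cfg2$survival[cat, 3]
    ret <- n06[cat] / n04[cat]
    expect_lt(abs(ret - p), 3 * sqrt(p * (1 - p) / n04[cat]))
  }
  expect_gt(n06["respiration"] / n04["respiration"],
            n06["sweat"] / n04["sweat"])

  # strong clustering concentrates a category in one patient
  cfg3 <- fd_stream_config(rates_per_hour = c(respiration = 0.5),
                           concentration = 0.05, seed = 43)
  s4 <- generate_fd_stream(cfg3, rec)
  conc <- patient_concentration(s4$by_threshold[["0.4"]], "respiration")
  expect_gt(conc$share_pct, 50)

  # zero rates give an empty stream at every threshold
  s0 <- generate_fd_stream(fd_stream_config(
    rates_per_hour = c(respiration = 0), seed = 45), rec)
  expect_equal(nrow(s0$by_threshold[["0.4"]]), 0)

  expect_error(fd_stream_config(survival = rbind(respiration = c(1, 0.5, 0.7))),
               "non-increasing")
})

test_that("FD pipeline closure: aggregate shares match planted rates", {
  rec <- records_fixture()
  cfg <- fd_stream_config(rates_per_hour = c(respiration = 0.5, sweat = 0.25),
                          survival = rbind(respiration = c(1, 1, 1),
                                           sweat = c(1, 1, 1)),
                          seed = 47)
  s <- generate_fd_stream(cfg, rec)
  agg <- aggregate_fd(s$by_threshold[["0.4"]])
  share <- agg$categories$pct[agg$categories$category == "respiration"] / 100
  se <- sqrt(2 / 3 * 1 / 3 / agg$n_total)
  expect_lt(abs(share - 2 / 3), 3 * se)
  expect_equal(sum(agg$categories$pct), 100)
})

test_that("synthetic EEG respects its spec and seeds", {
  sp <- eeg_segment_spec("seizure", duration = 30, amplitude = 90, seed = 49)
  a <- synthesize_eeg(sp)
  b <- synthesize_eeg(sp)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(30 * 256, 8))
  expect_equal(a$channels[1], "F4-C4")
  expect_equal(a$annotation$start, 3)
  expect_equal(a$annotation$end, 27)

  bg <- synthesize_eeg(eeg_segment_spec("background", duration = 20,
                                        background_rms = 25, seed = 51))
  expect_equal(sd(bg$data[, 1]), 25, tolerance = 0.15)
  expect_equal(nrow(bg$annotation), 0)

  # rhythmicity controls per-second frequency jitter by construction
  set.seed(53)
  j1 <- sdaudit:::jittered_phase(60, 256, 1.5, 1)
  j3 <- sdaudit:::jittered_phase(60, 256, 1.5, 3)
  expect_gt(sd(j1$f_sec), sd(j3$f_sec))

  expect_error(eeg_segment_spec("seizure", amplitude = -5), "amplitude")
})
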