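test_that("overlap matching classifies every detector event exactly once", {
  gold <- seizure_annotations("r", 10, 60)
  det <- detection_events("r", 50, 20, threshold = 0.4)
  m <- match_events(gold, det)
  expect_true(m$detected)
  expect_equal(nrow(m$false_detections), 0)

  m0 <- match_events(gold, detection_events(character(), numeric(),
                                            numeric(), threshold = 0.4))
  expect_false(m0$detected)
  expect_equal(seizure_detection_rate(m0$detected), 0)

  # three events inside one seizure plus one outside: detected once, 1 FD
  det4 <- detection_events(rep("r", 4), c(12, 20, 40, 200), c(5, 5, 5, 5),
                           threshold = 0.4)
  m4 <- match_events(gold, det4)
  expect_equal(sum(m4$detected), 1)
  expect_equal(nrow(m4$false_detections), 1)
  expect_equal(m4$false_detections$start, 200)

  # half-open semantics: touching intervals do not overlap
  mt <- match_events(gold, detection_events("r", 60, 10, threshold = 0.4))
  expect_false(mt$detected)
  # ... unless a tolerance is allowed
  expect_true(match_events(gold, detection_events("r", 60, 10,
                                                  threshold = 0.4),
                           tolerance = 1)$detected)

  # an event straddling two seizures marks both, and is no FD
  g2 <- seizure_annotations(c("r", "r"), c(0, 100), c(50, 150))
  ms <- match_events(g2, detection_events("r", 45, 60, threshold = 0.4))
  expect_equal(ms$detected, c(TRUE, TRUE))
  expect_equal(nrow(ms$false_detections), 0)

  expect_error(match_events(seizure_annotations("a", 1, 2),
                            detection_events("b", 1, 2, threshold = 0.4)),
               "single record")
})

test_that("matching agrees with the brute-force overlap oracle", {
  set.seed(101)
  for (i in 1:1000) {
    inst <- random_instance(sample(0:12, 1), sample(0:12, 1))
    tol <- sample(c(0, 0, 5), 1)
    m <- match_events(inst$gold, inst$det, tolerance = tol)
    o <- bf_match(inst$gold, inst$det, tol = tol)
    expect_identical(unname(m$detected), o$detected)
    expect_identical(as.integer(rownames(m$false_detections)),
                     o$fd_idx)
    # partition: matched + FD = all events
    expect_equal(nrow(m$false_detections) +
                   (m$n_events - nrow(m$false_detections)), m$n_events)
  }
})

test_that("detection and FD rates compute as documented", {
  expect_equal(seizure_detection_rate(rep(FALSE, 4)), 0)
  expect_equal(seizure_detection_rate(rep(TRUE, 4)), 100)
  expect_equal(seizure_detection_rate(c(rep(TRUE, 419), rep(FALSE, 2))),
               100 * 419 / 421) # 99.525%, exact arithmetic
  expect_warning(r <- seizure_detection_rate(logical(0)), "undefined")
  expect_true(is.na(r))

  expect_equal(fd_rate(3, 1.5), 2)
  expect_equal(fd_rate(0, 10), 0)
  expect_error(fd_rate(3, 0), "positive")

  # Poisson-planted FD stream: estimate within 3 SE of 1/hr over 100 h
  set.seed(7)
  n <- rpois(1, 100)
  expect_lt(abs(fd_rate(n, 100) - 1), 3 * sqrt(100) / 100)
})

test_that("epoch metrics match a hand-tallied confusion table", {
  # 10 epochs of 10 s; gold covers epochs 1-3, detector epochs 3-5
  gold <- seizure_annotations("r", 0, 30)
  det <- detection_events("r", 20, 30, threshold = 0.4)
  em <- epoch_metrics(gold, det, duration_hours = 100 / 3600, epoch_len = 10)
  expect_equal(c(em$tp, em$fn, em$fp, em$tn), c(1, 2, 2, 5))
  expect_equal(em$sensitivity, 100 / 3)
  expect_equal(em$specificity, 100 * 5 / 7)

  id <- epoch_metrics(gold, detection_events("r", 0, 30, threshold = 0.4),
                      duration_hours = 100 / 3600, epoch_len = 10)
  expect_equal(id$sensitivity, 100)
  expect_equal(id$specificity, 100)

  none <- epoch_metrics(gold, detection_events(character(), numeric(),
                                               numeric(), threshold = 0.4),
                        duration_hours = 100 / 3600, epoch_len = 10)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 100)
  expect_error(epoch_metrics(gold, det, duration_hours = 1 / 3600,
                             epoch_len = 10), "shorter than one epoch")
})

test_that("threshold sweep pools records and is monotone on nested sets", {
  rec <- record_meta(c("r1", "r2"), c("b1", "b2"), c(1, 2),
                     c("seizure", "seizure"))
  gold <- seizure_annotations(c("r1", "r1", "r2"), c(100, 500, 200),
                              c(160, 560, 260))
  # nested detections: each higher threshold keeps a subset
  d04 <- detection_events(c("r1", "r1", "r1", "r2", "r2"),
                          c(110, 505, 2000, 210, 4000),
                          rep(20, 5), threshold = 0.4)
  d05 <- detection_events(c("r1", "r1", "r2"), c(110, 505, 210), rep(20, 3),
                          threshold = 0.5)
  d06 <- detection_events("r1", 110, 20, threshold = 0.6)
  sw <- threshold_sweep(gold, list(d04, d05, d06), rec)
  expect_equal(sw$metrics$threshold, c(0.4, 0.5, 0.6))
  expect_true(all(diff(sw$metrics$n_detected) <= 0))
  expect_true(all(diff(sw$metrics$n_fd) <= 0))
  expect_equal(sw$metrics$n_fd[1], 2)
  expect_equal(sw$metrics$fd_per_hour[1], 2 / 3)
  expect_equal(sw$metrics$sdr_pct[1], 100)
  expect_equal(sw$metrics$sdr_pct[3], 100 / 3)

  # single threshold: sweep of length 1, matching an independent run
  sw1 <- threshold_sweep(gold, list(d04), rec)
  expect_equal(nrow(sw1$metrics), 1)
  m1 <- match_events(gold[gold$record_id == "r1", ],
                     d04[d04$record_id == "r1", ])
  m2 <- match_events(gold[gold$record_id == "r2", ],
                     d04[d04$record_id == "r2", ])
  expect_equal(sw1$metrics$n_detected, sum(m1$detected) + sum(m2$detected))
  expect_equal(sw1$metrics$n_fd,
               nrow(m1$false_detections) + nrow(m2$false_detections))
})
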