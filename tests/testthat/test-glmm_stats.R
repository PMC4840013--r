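test_that("odds ratios and Wald intervals follow the closed form", {
  o <- odds_ratio_ci(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$ci_lo, 0.822, tolerance = 1e-3)
  expect_equal(o$ci_hi, 1.217, tolerance = 1e-3)
  expect_equal(odds_ratio_ci(log(2), 0.3)$or, 2)
  # the per-second duration effect scale: log(1.02) exponentiates back
  expect_equal(odds_ratio_ci(0.0198026, 0.002)$or, 1.02, tolerance = 1e-6)
  expect_error(odds_ratio_ci(1, 0), "standard errors")
})

test_that("GLMM rejects degenerate inputs and flags separation", {
  coh <- generate_cohort(cohort_config(n_babies = 5, seizures_per_baby = 10,
                                       seed = 4))
  d <- coh$features
  d$const <- 1
  expect_error(fit_glmm(within(d, detected_0.5 <- 1), "detected_0.5",
                        "duration"), "constant")
  d2 <- d
  d2$sep <- as.numeric(d2$detected_0.5 > 0.5) * 10
  expect_error(fit_glmm(d2, "detected_0.5", "sep"), "separation.*sep")
  d3 <- d[, c("baby_id", "duration", "detected_0.5")]
  d3$duration[3] <- NA
  expect_error(fit_glmm(d3, "detected_0.5", "duration"), "missing values")
  expect_error(fit_glmm(d[d$baby_id == d$baby_id[1], ], "detected_0.5",
                        "duration"), "2 grouping units")
})

test_that("GLMM nests ordinary logistic regression and is quadrature-stable", {
  coh <- generate_cohort(cohort_config(n_babies = 20, seizures_per_baby = 20,
                                       random_intercept_sd = 0, seed = 6))
  feats <- c("duration", "peak_amplitude", "n_channels_peak")
  fit <- suppressWarnings(fit_glmm(coh$features, "detected_0.5", feats))
  g <- stats::glm(detected_0.5 ~ duration + peak_amplitude + n_channels_peak,
                  stats::binomial(), coh$features)
  # boundary optimum: the mixed model can never do worse than its nested glm
  expect_gte(fit$log_likelihood, as.numeric(stats::logLik(g)) - 1e-6)
  if (fit$random_intercept_sd < 1e-6)
    expect_equal(fit$coefficients$estimate, unname(stats::coef(g)),
                 tolerance = 1e-3)

  # estimates barely move when the quadrature grid is refined
  coh2 <- generate_cohort(cohort_config(n_babies = 12, seizures_per_baby = 15,
                                        seed = 7))
  f15 <- fit_glmm(coh2$features, "detected_0.5", feats, nagq = 15)
  f31 <- fit_glmm(coh2$features, "detected_0.5", feats, nagq = 31)
  expect_equal(f15$coefficients$estimate, f31$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("model AUC equals brute-force concordance counting", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(40:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    score <- rnorm(n) + 0.8 * y
    if (i == 3) score <- round(score) # force ties
    v <- sdaudit:::model_auc_values(y, score)
    pos <- score[y == 1]; neg <- score[y == 0]
    bf <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(v$auc, bf, tolerance = 1e-12)
  }
  # hand-computed 4-point ROC: pairs (3>1), (3>2), (5>1), (5>2) all concordant
  expect_equal(sdaudit:::model_auc_values(c(0, 0, 1, 1),
                                          c(1, 2, 3, 5))$auc, 1)
  expect_error(sdaudit:::model_auc_values(c(0, 1), c(1, 1)), "constant")
})

test_that("AUC of a fitted model behaves: separation, null score, CI", {
  coh <- generate_cohort(cohort_config(n_babies = 15, seizures_per_baby = 25,
                                       seed = 10))
  fit <- fit_glmm(coh$features, "detected_0.5",
                  c("duration", "peak_amplitude"))
  a <- model_auc(fit)
  expect_true(a$auc > 0.5 && a$auc <= 1)
  expect_true(a$ci_95[1] <= a$auc && a$auc <= a$ci_95[2])
  # a feature independent of the outcome scores near 0.5
  null_fit <- fit_glmm(coh$features, "detected_0.5", "background_score")
  expect_lt(abs(null_fit$auc - 0.5), 0.1)
})

test_that("paired AUC comparison: self vs self is exactly null", {
  coh <- generate_cohort(cohort_config(n_babies = 12, seizures_per_baby = 20,
                                       seed = 12))
  fit <- fit_glmm(coh$features, "detected_0.5", "duration")
  cmp <- compare_auc(fit, fit)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$auc_a, cmp$auc_b)

  fit2 <- fit_glmm(coh$features, "detected_0.5",
                   c("duration", "peak_amplitude", "rhythmicity"))
  cmp2 <- compare_auc(fit2, fit)
  expect_gte(cmp2$auc_a, cmp2$auc_b - 0.05)
  expect_true(cmp2$p_value >= 0 && cmp2$p_value <= 1)
})

test_that("collinearity filter keeps the highest-AUC member of a cluster", {
  coh <- generate_cohort(cohort_config(n_babies = 10, seizures_per_baby = 30,
                                       seed = 14))
  d <- coh$features
  d$dup <- d$duration # perfect collinearity
  aucs <- c(duration = 0.8, dup = 0.75, peak_amplitude = 0.7)
  res <- collinearity_filter(d, c("duration", "dup", "peak_amplitude"), aucs)
  expect_equal(res$retained, c("duration", "peak_amplitude"))
  expect_equal(res$decisions$dropped, "dup")

  # channels at onset vs peak are strongly correlated by construction;
  # the peak count (higher AUC) is the one retained
  scr_auc <- c(n_channels_onset = 0.66, n_channels_peak = 0.71)
  res2 <- collinearity_filter(d, names(scr_auc), scr_auc)
  expect_equal(res2$retained, "n_channels_peak")

  # orthogonal features all survive
  res3 <- collinearity_filter(d, c("duration", "background_score"),
                              c(duration = 0.8, background_score = 0.5))
  expect_equal(length(res3$retained), 2)
})

test_that("univariate screen and stepwise keep signal, drop noise", {
  coh <- generate_cohort(cohort_config(n_babies = 20, seizures_per_baby = 25,
                                       seed = 16))
  scr <- univariate_screen(coh$features, "detected_0.5",
                           c("duration", "background_score"))
  expect_equal(nrow(scr$table), 2)
  expect_true(scr$table$significant[scr$table$feature == "duration"])
  expect_gt(scr$table$auc[1], scr$table$auc[2]) # signal beats null's AUC

  one <- univariate_screen(coh$features, "detected_0.5", "duration")
  expect_equal(nrow(one$table), 1)

  # strong + null: stepwise drops the null, keeps the strong
  fit <- backward_stepwise(coh$features, "detected_0.5",
                           c("duration", "background_score"))
  expect_equal(attr(fit, "retained"), "duration")
  expect_equal(attr(fit, "removal_path"), "background_score")

  # all-null candidate set collapses to the intercept in most replicates
  # (each null feature still clears alpha = 0.05 about 5% of the time)
  kept <- vapply(1:9, function(s) {
    nullcoh <- generate_cohort(cohort_config(
      n_babies = 12, seizures_per_baby = 15,
      betas = list(duration = 0), seed = 100 + s))
    fit0 <- suppressWarnings(
      backward_stepwise(nullcoh$features, "detected_0.5",
                        c("background_score", "frequency_variability"),
                        nagq = 1))
    length(attr(fit0, "retained"))
  }, numeric(1))
  expect_gt(mean(kept == 0), 0.5)
})

test_that("Mann-Whitney matches full enumeration and handles ties", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p_value, 0.1) # 2/choose(6,3) * 2, by enumeration
  expect_true(mw$exact)

  tied <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(tied$U), 4.5) # n1 n2 / 2 under symmetry
  expect_gt(tied$p_value, 0.95)

  expect_error(mann_whitney(numeric(), 1:3), "non-empty")

  # cross-check the exact p against brute-force enumeration of orderings
  a <- c(1.2, 3.4, 2.2); b <- c(4.1, 0.3, 5.5)
  mw2 <- mann_whitney(a, b)
  pool <- c(a, b)
  combs <- combn(6, 3)
  u_obs <- sum(outer(a, b, ">"))
  u_all <- apply(combs, 2, function(idx)
    sum(outer(pool[idx], pool[-idx], ">")))
  # two-sided exact p: tail mass of |U - n1n2/2| at least as extreme
  p_bf <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(mw2$p_value, p_bf)
})

test_that("group FD-rate comparison has calibrated type-I behaviour", {
  set.seed(19)
  reps <- 200
  p_same <- replicate(reps, {
    compare_groups_fd(rlnorm(10, 0, 1), rlnorm(10, 0, 1))$p_value
  })
  rej <- mean(p_same < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
  p_shift <- replicate(50, {
    compare_groups_fd(rlnorm(10, 1.5, 0.5), rlnorm(10, 0, 0.5))$p_value
  })
  expect_gt(mean(p_shift < 0.05), 0.8) # power clearly above type-I level
})

test_that("full detectability pipeline assembles the odds-ratio table", {
  coh <- generate_cohort(cohort_config(n_babies = 16, seizures_per_baby = 30,
                                       seed = 21))
  res <- detectability_analysis(
    coh$features, "detected_0.5",
    c("duration", "peak_amplitude", "rhythmicity", "n_channels_onset",
      "n_channels_peak", "background_score"))
  expect_s3_class(res, "sda_detectability")
  expect_true(all(c("duration", "peak_amplitude") %in%
                    attr(res$final, "retained")))
  # collinear channel counts: only one enters the multivariate stage
  expect_false(all(c("n_channels_onset", "n_channels_peak") %in%
                     res$collinearity$retained))
  expect_true(all(res$or_table$uni_auc <= 1, na.rm = TRUE))
  expect_false(is.null(res$auc_comparison))
  expect_true(res$auc_comparison$p_value <= 1)
})
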