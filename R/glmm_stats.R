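#' Coding of seizure features for regression
#'
#' Prepares a feature table for modelling: rhythmicity and background become
#' ordered-entry factors with "significant dysrhythmia" (1) and "normal" (1)
#' as reference levels, morphology columns become factors with RDD as the
#' reference, and logical columns stay logical. Continuous features
#' (amplitude in microvolts, duration in seconds, frequency variability in
#' Hz, channel counts) are left on their natural scales, so odds ratios read
#' "per microvolt", "per second", etc.
#'
#' @param data seizure feature table.
#' @return The table with factor codings applied.
#' @export
code_features <- function(data) {
  if ("rhythmicity" %in% names(data) && !is.factor(data$rhythmicity))
    data$rhythmicity <- factor(data$rhythmicity, levels = 1:3)
  if ("background_score" %in% names(data) && !is.factor(data$background_score))
    data$background_score <- factor(data$background_score, levels = 1:3)
  for (col in intersect(c("morphology_onset", "morphology_peak"), names(data)))
    if (!is.factor(data[[col]]))
      data[[col]] <- factor(data[[col]],
                            levels = intersect(morphology_levels("onset"),
                                               unique(data[[col]])))
  data
}

check_glmm_inputs <- function(data, outcome, features, group) {
  cols <- c(outcome, features, group)
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop("column(s) not in data: ", paste(missing, collapse = ", "))
  used <- data[, cols, drop = FALSE]
  if (anyNA(used)) stop("missing values in modelling columns")
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1, TRUE, FALSE)))
    stop("outcome must be binary (0/1 or logical)")
  if (length(unique(data[[group]])) < 2)
    stop("need at least 2 grouping units (babies)")
  if (length(unique(y)) < 2)
    stop("outcome is constant: model undefined")
  invisible(TRUE)
}

warn_separation <- function(data, outcome, features, group) {
  # (quasi-)complete separation makes the GLMM likelihood unbounded in a
  # fixed effect; screen with a plain logistic fit before handing the data
  # to the quadrature machinery. Coefficients are scaled by the predictor
  # spread so the check does not depend on measurement units.
  f <- stats::reformulate(features, response = outcome)
  g <- suppressWarnings(stats::glm(f, data = data,
                                   family = stats::binomial()))
  eta <- stats::predict(g, type = "link")
  X <- stats::model.matrix(g)[, -1, drop = FALSE]
  cf <- stats::coef(g)[-1] * apply(X, 2, stats::sd)
  if (max(abs(eta)) > 12 && any(abs(cf) > 8, na.rm = TRUE)) {
    term <- names(cf)[which.max(abs(cf))]
    stop("complete (or quasi-complete) separation detected; term: ", term)
  }
  invisible(TRUE)
}

#' Fit a random-intercept logistic regression of seizure detection
#'
#' Fits a mixed-effects logistic regression with the listed seizure features
#' as fixed effects and a per-baby random intercept, the standard model for
#' asking which seizure characteristics drive automated detection while
#' accounting for the clustering of seizures within babies. The marginal
#' likelihood is integrated by adaptive Gauss--Hermite quadrature (15 nodes
#' by default); if that fails to converge the fit falls back to the Laplace
#' approximation (`nagq = 1`) with a warning.
#'
#' @param data feature table, one row per seizure; passed through
#'   [code_features()].
#' @param outcome name of the binary detected/non-detected column.
#' @param features character vector of fixed-effect column names.
#' @param group name of the clustering column (default `"baby_id"`).
#' @param nagq number of adaptive Gauss--Hermite quadrature nodes.
#' @param conditional_auc if `TRUE`, the reported AUC uses the conditional
#'   (random-effect-inclusive) linear predictor; the default is the
#'   population-level fixed-effects predictor, the honest choice when the
#'   model is to be applied to new babies.
#'
#' @return An object of class `"sda_glmm"`: list with `coefficients` (table
#'   of estimate, SE, OR, 95% CI, Wald z and p per term),
#'   `random_intercept_sd`, `log_likelihood`, `auc`, `auc_ci_95`, `n`,
#'   `n_groups`, `converged`, `nagq_used`, plus the underlying `model`
#'   (a `glmerMod`) and the call ingredients (`outcome`, `features`,
#'   `group`, `data`).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_babies = 6, seizures_per_baby = 12,
#'                                      seed = 1))
#' fit <- fit_glmm(coh$features, outcome = "detected_0.4",
#'                 features = c("duration", "peak_amplitude"))
#' fit$coefficients
#' }
#' @export
fit_glmm <- function(data, outcome, features, group = "baby_id", nagq = 15,
                     conditional_auc = FALSE) {
  data <- code_features(as.data.frame(data))
  check_glmm_inputs(data, outcome, features, group)
  warn_separation(data, outcome, features, group)
  data[[outcome]] <- as.numeric(data[[outcome]])
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(features, sprintf("(1 | %s)", group)),
                                     collapse = " + ")))
  fit_once <- function(nq) {
    lme4::glmer(f, data = data, family = stats::binomial(), nAGQ = nq,
                control = lme4::glmerControl(calc.derivs = FALSE))
  }
  nagq_used <- nagq
  model <- tryCatch(fit_once(nagq), error = function(e) e)
  if (inherits(model, "error") && nagq != 1) {
    warning("adaptive quadrature fit failed (", conditionMessage(model),
            "); falling back to Laplace")
    nagq_used <- 1
    model <- fit_once(1)
  } else if (inherits(model, "error")) {
    stop("GLMM did not converge: ", conditionMessage(model))
  }
  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  or <- odds_ratio_ci(beta, se)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), or = or$or, ci_lo = or$ci_lo,
                      ci_hi = or$ci_hi, z = unname(z), p = unname(p),
                      stringsAsFactors = FALSE)
  lp <- glmm_linear_predictor(model, data, conditional = conditional_auc)
  auc <- tryCatch(model_auc_values(data[[outcome]], lp),
                  error = function(e) list(auc = NA_real_,
                                           ci = c(NA_real_, NA_real_)))
  structure(list(
    coefficients = coefs,
    random_intercept_sd = unname(attr(lme4::VarCorr(model)[[group]], "stddev")),
    log_likelihood = as.numeric(stats::logLik(model)),
    auc = auc$auc, auc_ci_95 = auc$ci,
    n = nrow(data), n_groups = length(unique(data[[group]])),
    converged = length(model@optinfo$conv$lme4) == 0,
    nagq_used = nagq_used,
    model = model, outcome = outcome, features = features, group = group,
    data = data
  ), class = "sda_glmm")
}

#' @export
print.sda_glmm <- function(x, digits = 3, ...) {
  cat(sprintf("<sda_glmm> %s ~ %s + (1 | %s)\n", x$outcome,
              paste(x$features, collapse = " + "), x$group))
  cat(sprintf("  n = %d seizures in %d babies; random-intercept SD = %.3f; logLik = %.2f\n",
              x$n, x$n_groups, x$random_intercept_sd, x$log_likelihood))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci_95[1],
              x$auc_ci_95[2]))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

glmm_linear_predictor <- function(model, data, conditional = FALSE) {
  if (conditional)
    return(stats::predict(model, newdata = data, type = "link"))
  X <- stats::model.matrix(stats::delete.response(stats::terms(model)),
                           data = data)
  drop(X %*% lme4::fixef(model))
}

#' Odds ratio with 95% Wald confidence interval
#'
#' @param estimate log-odds estimate(s).
#' @param se standard error(s), > 0.
#' @return A list with `or`, `ci_lo`, `ci_hi` (`exp(estimate +/- 1.959964 se)`).
#' @examples
#' odds_ratio_ci(log(1.02), 0.002)
#' @export
odds_ratio_ci <- function(estimate, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("standard errors must be > 0")
  zq <- stats::qnorm(0.975)
  list(or = exp(estimate), ci_lo = exp(estimate - zq * se),
       ci_hi = exp(estimate + zq * se))
}

model_auc_values <- function(y, score) {
  if (stats::sd(score) == 0)
    stop("constant predictor: AUC undefined")
  r <- pROC::roc(response = y, predictor = score, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  # a degenerate (AUC = 1) curve draws a cautionary note from pROC
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)), ci = ci[c(1, 3)], roc = r)
}

#' AUC of a fitted detectability model
#'
#' Area under the ROC curve of the model's linear predictor against the
#' detection outcome, with a 95% DeLong confidence interval. By default the
#' population-level (fixed-effects-only) predictor is scored.
#'
#' @param fit an [fit_glmm()] object.
#' @param data optional data to score (default: the training data).
#' @param conditional use the random-effect-inclusive predictor.
#' @return List with `auc` and `ci_95`.
#' @export
model_auc <- function(fit, data = NULL, conditional = FALSE) {
  stopifnot(inherits(fit, "sda_glmm"))
  data <- if (is.null(data)) fit$data else code_features(as.data.frame(data))
  lp <- glmm_linear_predictor(fit$model, data, conditional = conditional)
  v <- model_auc_values(as.numeric(data[[fit$outcome]]), lp)
  list(auc = v$auc, ci_95 = v$ci)
}

#' Compare the AUCs of two models on the same observations
#'
#' Two-sided paired DeLong test for a difference in AUC between two fitted
#' detectability models scored on the same seizures (correlated ROC curves).
#'
#' @param fit_a,fit_b [fit_glmm()] objects fitted to the same outcome.
#' @param data optional common scoring data (default: `fit_a`'s data).
#' @return List with `auc_a`, `auc_b`, `statistic` and `p_value`.
#' @export
compare_auc <- function(fit_a, fit_b, data = NULL) {
  stopifnot(inherits(fit_a, "sda_glmm"), inherits(fit_b, "sda_glmm"))
  data <- if (is.null(data)) fit_a$data else code_features(as.data.frame(data))
  if (fit_a$outcome != fit_b$outcome)
    stop("models have different outcomes")
  y <- as.numeric(data[[fit_a$outcome]])
  lp_a <- glmm_linear_predictor(fit_a$model, data)
  lp_b <- glmm_linear_predictor(fit_b$model, data)
  if (length(lp_a) != length(lp_b))
    stop("models scored on differing observation sets")
  if (isTRUE(all.equal(lp_a, lp_b)) ||
      stats::cor(lp_a, lp_b) > 1 - 1e-12) {
    # identical rankings: AUC difference is exactly zero
    auc <- model_auc_values(y, lp_a)$auc
    return(list(auc_a = auc, auc_b = auc, statistic = 0, p_value = 1))
  }
  ra <- pROC::roc(y, lp_a, quiet = TRUE, direction = "<", levels = c(0, 1))
  rb <- pROC::roc(y, lp_b, quiet = TRUE, direction = "<", levels = c(0, 1))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       statistic = unname(tst$statistic), p_value = tst$p.value)
}

lr_block_p <- function(data, outcome, features, drop, group, nagq = 1) {
  # likelihood-ratio p for removing one (possibly multi-level) term
  f_full <- stats::as.formula(paste(outcome, "~",
    paste(c(features, sprintf("(1 | %s)", group)), collapse = " + ")))
  reduced <- setdiff(features, drop)
  f_red <- stats::as.formula(paste(outcome, "~",
    paste(c(if (length(reduced)) reduced else "1",
            sprintf("(1 | %s)", group)), collapse = " + ")))
  ctrl <- lme4::glmerControl(calc.derivs = FALSE)
  m_full <- lme4::glmer(f_full, data = data, family = stats::binomial(),
                        nAGQ = nagq, control = ctrl)
  m_red <- lme4::glmer(f_red, data = data, family = stats::binomial(),
                       nAGQ = nagq, control = ctrl)
  lr <- 2 * (as.numeric(stats::logLik(m_full)) -
             as.numeric(stats::logLik(m_red)))
  df <- attr(stats::logLik(m_full), "df") - attr(stats::logLik(m_red), "df")
  stats::pchisq(max(lr, 0), df = max(df, 1), lower.tail = FALSE)
}

term_p_values <- function(fit) {
  # one p per feature: Wald z for single-coefficient terms, block LR for
  # multi-level categorical terms
  data <- fit$data
  vapply(fit$features, function(feat) {
    if (is.factor(data[[feat]]) && nlevels(droplevels(data[[feat]])) > 2) {
      lr_block_p(data, fit$outcome, fit$features, feat, fit$group,
                 nagq = fit$nagq_used)
    } else {
      rows <- grep(paste0("^", gsub("([.|()\\^{}+$*?]|\\[|\\])", "\\\\\\1", feat)),
                   fit$coefficients$term)
      min(fit$coefficients$p[rows])
    }
  }, numeric(1))
}

#' Univariate screen of seizure features
#'
#' Fits one single-feature random-intercept logistic regression per feature
#' and tabulates odds ratios, 95% CIs, p-values (Wald for single-coefficient
#' terms, block likelihood-ratio for multi-level categorical terms) and the
#' model AUC. Features significant at `alpha` are the candidates for the
#' multivariate model. A feature whose fit fails is annotated, not fatal.
#'
#' @inheritParams fit_glmm
#' @param alpha significance level for the candidate flag (default 0.05).
#' @return An object of class `"sda_screen"`: list with `table` (one row per
#'   feature: `feature`, `or`, `ci_lo`, `ci_hi`, `p`, `auc`, `significant`,
#'   `error`) and `fits` (named list of `sda_glmm` objects).
#' @export
univariate_screen <- function(data, outcome, features, group = "baby_id",
                              nagq = 15, alpha = 0.05) {
  stopifnot(length(features) >= 1)
  fits <- list(); rows <- NULL
  for (feat in features) {
    res <- tryCatch(fit_glmm(data, outcome, feat, group = group, nagq = nagq),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows <- rbind(rows, data.frame(feature = feat, or = NA, ci_lo = NA,
                                     ci_hi = NA, p = NA, auc = NA,
                                     significant = NA,
                                     error = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      next
    }
    fits[[feat]] <- res
    p <- unname(term_p_values(res)[feat])
    cf <- res$coefficients[res$coefficients$term != "(Intercept)", , drop = FALSE]
    multi <- nrow(cf) > 1
    rows <- rbind(rows, data.frame(
      feature = feat,
      or = if (multi) NA_real_ else cf$or,
      ci_lo = if (multi) NA_real_ else cf$ci_lo,
      ci_hi = if (multi) NA_real_ else cf$ci_hi,
      p = p, auc = res$auc, significant = p < alpha, error = NA_character_,
      stringsAsFactors = FALSE))
  }
  structure(list(table = rows, fits = fits, outcome = outcome,
                 group = group, alpha = alpha), class = "sda_screen")
}

#' @export
print.sda_screen <- function(x, digits = 3, ...) {
  cat(sprintf("<sda_screen> outcome %s, %d features\n", x$outcome,
              nrow(x$table)))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Filter collinear candidate features
#'
#' Clusters candidate features whose pairwise absolute Spearman correlation
#' exceeds `threshold` (ordinal and categorical features enter via their
#' numeric codes) and keeps, from each cluster, the feature with the highest
#' univariate AUC.
#'
#' @param data feature table.
#' @param candidates character vector of candidate feature names.
#' @param univariate_aucs named numeric vector of univariate AUCs (e.g. from
#'   [univariate_screen()]).
#' @param threshold absolute Spearman correlation above which two features
#'   are treated as collinear (default 0.8).
#' @return List with `retained`, `dropped`, and `decisions` (data.frame
#'   logging each dropped feature, its cluster-mate kept, and the
#'   correlation).
#' @export
collinearity_filter <- function(data, candidates, univariate_aucs,
                                threshold = 0.8) {
  stopifnot(all(candidates %in% names(data)))
  if (length(candidates) < 2)
    return(list(retained = candidates, dropped = character(),
                decisions = NULL))
  num <- vapply(data[candidates], function(x) as.numeric(as.factor(x)),
                numeric(nrow(data)))
  rho <- stats::cor(num, method = "spearman")
  k <- length(candidates)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    if (abs(rho[i, j]) > threshold) parent[find(j)] <- find(i)
  comp <- vapply(seq_len(k), find, integer(1))
  retained <- character(); decisions <- NULL
  for (cl in unique(comp)) {
    members <- candidates[comp == cl]
    aucs <- univariate_aucs[members]
    keep <- members[which.max(aucs)]
    retained <- c(retained, keep)
    for (dropped in setdiff(members, keep))
      decisions <- rbind(decisions, data.frame(
        dropped = dropped, kept = keep,
        spearman = rho[match(dropped, candidates), match(keep, candidates)],
        auc_dropped = unname(univariate_aucs[dropped]),
        auc_kept = unname(univariate_aucs[keep]),
        stringsAsFactors = FALSE))
  }
  list(retained = retained[order(match(retained, candidates))],
       dropped = setdiff(candidates, retained), decisions = decisions)
}

#' Backward stepwise selection of the multivariate model
#'
#' Starting from all candidate features, repeatedly removes the feature with
#' the largest non-significant p-value (Wald z for single-coefficient terms,
#' block likelihood-ratio for multi-level categorical terms) and refits,
#' until every remaining feature is significant at `alpha`. If everything is
#' removed an intercept-only fit is returned with a warning.
#'
#' @inheritParams fit_glmm
#' @param alpha retention threshold (default 0.05).
#' @return The final `sda_glmm` fit, with attributes `removal_path`
#'   (features in removal order) and `retained`.
#' @export
backward_stepwise <- function(data, outcome, features, group = "baby_id",
                              nagq = 15, alpha = 0.05) {
  current <- features
  path <- character()
  repeat {
    if (!length(current)) {
      warning("all features removed; returning intercept-only model")
      data2 <- code_features(as.data.frame(data))
      data2$..one <- 1
      f <- stats::as.formula(paste(outcome, "~ 1 +", sprintf("(1 | %s)", group)))
      model <- lme4::glmer(f, data = data2, family = stats::binomial(),
                           nAGQ = nagq,
                           control = lme4::glmerControl(calc.derivs = FALSE))
      fit <- structure(list(
        coefficients = data.frame(term = "(Intercept)",
                                  estimate = unname(lme4::fixef(model))[1],
                                  se = sqrt(diag(as.matrix(stats::vcov(model))))[1],
                                  or = NA, ci_lo = NA, ci_hi = NA, z = NA, p = NA),
        random_intercept_sd = unname(attr(lme4::VarCorr(model)[[group]], "stddev")),
        log_likelihood = as.numeric(stats::logLik(model)),
        auc = NA_real_, auc_ci_95 = c(NA_real_, NA_real_),
        n = nrow(data2), n_groups = length(unique(data2[[group]])),
        converged = TRUE, nagq_used = nagq, model = model, outcome = outcome,
        features = character(), group = group, data = data2),
        class = "sda_glmm")
      attr(fit, "removal_path") <- path
      attr(fit, "retained") <- character()
      return(fit)
    }
    fit <- fit_glmm(data, outcome, current, group = group, nagq = nagq)
    p <- term_p_values(fit)
    worst <- names(p)[which.max(p)]
    if (p[worst] < alpha) {
      attr(fit, "removal_path") <- path
      attr(fit, "retained") <- current
      attr(fit, "term_p") <- p
      return(fit)
    }
    path <- c(path, worst)
    current <- setdiff(current, worst)
  }
}

#' Mann--Whitney U test
#'
#' Two-sided Mann--Whitney (Wilcoxon rank-sum) test, used to compare
#' per-patient false-detection-rate distributions between the seizure and
#' non-seizure groups. The exact null distribution is used for small
#' untied samples (both n <= 10, matching a 10-vs-10 cohort design); larger
#' or tied samples use the normal approximation with tie correction.
#'
#' @param a,b numeric samples (e.g. FD/hr per patient in each group).
#' @return List with `U` (number of (a, b) pairs with a > b, counting ties
#'   as 1/2 — the Mann--Whitney U of the first sample), `p_value`, and
#'   `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  exact <- length(a) <= 10 && length(b) <= 10 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Full detectability analysis: screen, filter, stepwise, AUC comparison
#'
#' Runs the complete feature-detectability procedure for one sensitivity
#' threshold: univariate screen of all features, collinearity filtering of
#' the significant candidates (highest univariate AUC kept), backward
#' stepwise deletion to the final multivariate model, and a paired DeLong
#' comparison of the multivariate AUC against the best univariate AUC.
#'
#' @inheritParams fit_glmm
#' @param collinearity_threshold passed to [collinearity_filter()].
#' @param alpha significance level throughout (default 0.05).
#' @return An object of class `"sda_detectability"`: list with `screen`,
#'   `collinearity`, `final` (the multivariate `sda_glmm`), `auc_comparison`,
#'   and `or_table` (combined univariate/multivariate odds-ratio table).
#' @export
detectability_analysis <- function(data, outcome, features,
                                   group = "baby_id", nagq = 15,
                                   collinearity_threshold = 0.8,
                                   alpha = 0.05) {
  scr <- univariate_screen(data, outcome, features, group = group,
                           nagq = nagq, alpha = alpha)
  ok <- scr$table[!is.na(scr$table$significant) & scr$table$significant, ]
  candidates <- ok$feature
  if (!length(candidates))
    stop("no feature significant in the univariate screen")
  aucs <- stats::setNames(scr$table$auc, scr$table$feature)
  col <- collinearity_filter(data, candidates, aucs,
                             threshold = collinearity_threshold)
  final <- backward_stepwise(data, outcome, col$retained, group = group,
                             nagq = nagq, alpha = alpha)
  best_uni <- names(which.max(aucs[candidates]))
  cmp <- if (length(attr(final, "retained")))
    compare_auc(final, scr$fits[[best_uni]])
  else NULL
  uni <- scr$table[, c("feature", "or", "ci_lo", "ci_hi", "p", "auc")]
  names(uni)[-1] <- paste0("uni_", names(uni)[-1])
  multi_p <- attr(final, "term_p")
  cf <- final$coefficients
  multi <- do.call(rbind, lapply(attr(final, "retained"), function(feat) {
    rows <- cf[grep(paste0("^", feat), cf$term), , drop = FALSE]
    data.frame(feature = feat,
               multi_or = if (nrow(rows) == 1) rows$or else NA_real_,
               multi_ci_lo = if (nrow(rows) == 1) rows$ci_lo else NA_real_,
               multi_ci_hi = if (nrow(rows) == 1) rows$ci_hi else NA_real_,
               multi_p = unname(multi_p[feat]), stringsAsFactors = FALSE)
  }))
  or_table <- merge(uni, multi, by = "feature", all.x = TRUE, sort = FALSE)
  structure(list(screen = scr, collinearity = col, final = final,
                 best_univariate = best_uni, auc_comparison = cmp,
                 or_table = or_table, outcome = outcome),
            class = "sda_detectability")
}

#' @export
print.sda_detectability <- function(x, digits = 3, ...) {
  cat(sprintf("<sda_detectability> outcome %s\n", x$outcome))
  cat("  retained features:",
      paste(attr(x$final, "retained"), collapse = ", "), "\n")
  if (!is.null(x$auc_comparison))
    cat(sprintf("  multivariate AUC %.3f vs best univariate (%s) AUC %.3f, p = %.4g\n",
                x$auc_comparison$auc_a, x$best_univariate,
                x$auc_comparison$auc_b, x$auc_comparison$p_value))
  tab <- x$or_table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
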