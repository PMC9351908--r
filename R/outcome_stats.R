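# Outcome statistics: univariate screen, logistic regression, ROC cutoff
# selection and the combined dichotomized predictor.

is_categorical <- function(x) {
  is.factor(x) || is.character(x) || is.logical(x) ||
    (is.numeric(x) && length(unique(x[!is.na(x)])) <= 2)
}

#' Univariate screen of cohort variables against a binary outcome
#'
#' Continuous variables: distribution normality is checked per group with
#' the Lilliefors-corrected Kolmogorov-Smirnov test at alpha = 0.05; if both
#' groups pass, a Student's t-test is used, otherwise the Mann-Whitney
#' U-test. Categorical variables: chi-squared test without continuity
#' correction, switching to Fisher's exact test when any expected cell
#' count is below 5. Constant variables are flagged and not tested.
#'
#' @param cohort data.frame with one row per patient.
#' @param variables character vector of columns to screen.
#' @param outcome name of a binary 0/1 outcome column; both classes must be
#'   present.
#' @param alpha_normal significance level of the normality check.
#' @return data.frame: `variable`, `type`, `test`, `statistic`, `p_value`,
#'   `summary_event`, `summary_noevent`.
#' @export
univariate_screen <- function(cohort, variables, outcome,
                              alpha_normal = 0.05) {
  y <- cohort[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop_fw("fw_bad_outcome", "outcome '%s' must be binary 0/1 with both classes present",
            outcome)
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop_fw("fw_bad_param", "no column '%s' in cohort", v)
    base <- data.frame(variable = v, type = NA_character_, test = NA_character_,
                       statistic = NA_real_, p_value = NA_real_,
                       summary_event = NA_character_,
                       summary_noevent = NA_character_,
                       stringsAsFactors = FALSE)
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; yy <- y[ok]
    if (length(unique(x)) < 2) {
      base$type <- "constant"; base$test <- "none"
      return(base)
    }
    if (is_categorical(x)) {
      tab <- table(x, yy)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        base$type <- "categorical"; base$test <- "fisher"
        base$p_value <- ft$p.value
      } else {
        ct <- chisq.test(tab, correct = FALSE)
        base$type <- "categorical"; base$test <- "chi-square"
        base$statistic <- unname(ct$statistic); base$p_value <- ct$p.value
      }
      cnt <- function(g) paste(sprintf("%s:%d", rownames(tab), tab[, g]),
                               collapse = " ")
      base$summary_event <- cnt("1"); base$summary_noevent <- cnt("0")
      return(base)
    }
    g1 <- x[yy == 1]; g0 <- x[yy == 0]
    lp <- function(g) {
      if (length(g) < 5 || sd(g) == 0) return(0)  # too small/degenerate: treat as nonnormal
      nortest::lillie.test(g)$p.value
    }
    normal <- lp(g1) > alpha_normal && lp(g0) > alpha_normal
    if (normal) {
      tt <- t.test(g1, g0, var.equal = TRUE)
      base$type <- "continuous"; base$test <- "t"
      base$statistic <- unname(tt$statistic); base$p_value <- tt$p.value
      base$summary_event <- sprintf("%.3g ± %.3g", mean(g1), sd(g1))
      base$summary_noevent <- sprintf("%.3g ± %.3g", mean(g0), sd(g0))
    } else {
      wt <- wilcox.test(g1, g0, exact = FALSE)
      base$type <- "continuous"; base$test <- "mann-whitney"
      base$statistic <- unname(wt$statistic); base$p_value <- wt$p.value
      qf <- function(g) sprintf("%.3g [%.3g-%.3g]", median(g),
                                quantile(g, .25, names = FALSE),
                                quantile(g, .75, names = FALSE))
      base$summary_event <- qf(g1); base$summary_noevent <- qf(g0)
    }
    base
  })
  do.call(rbind, rows)
}

#' Multivariable logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit; per-predictor odds ratio `exp(coef)`,
#' Wald 95% CI and Wald p-value. Perfect or quasi-perfect separation is
#' detected (diverging coefficients / fitted probabilities at the
#' boundary) and flags the fit non-reportable rather than printing a fake
#' CI.
#'
#' @param cohort data.frame.
#' @param predictors character vector of predictor columns.
#' @param outcome binary 0/1 outcome column.
#' @return object of class `logistic_fit`: data.frame `table` (`term`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`), plus `n`, `outcome`,
#'   `converged`, `separation`, and the underlying `glm` as `fit`.
#' @export
fit_logistic <- function(cohort, predictors, outcome) {
  y <- cohort[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1)))
    stop_fw("fw_bad_outcome", "outcome '%s' must be binary 0/1", outcome)
  dat <- cohort[, c(outcome, predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 10 * length(predictors))
    warning(sprintf("only %d observations for %d predictors (< 10 per predictor)",
                    nrow(dat), length(predictors)))
  f <- stats::reformulate(predictors, response = outcome)
  fit <- glm(f, family = binomial(), data = dat)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  eta <- fit$fitted.values
  separation <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) &&
    (any(eta > 1 - 1e-8) || any(eta < 1e-8))
  tab <- data.frame(term = rownames(sm),
                    odds_ratio = exp(sm[, "Estimate"]),
                    ci_low = exp(sm[, "Estimate"] - 1.959963984540054 * sm[, "Std. Error"]),
                    ci_high = exp(sm[, "Estimate"] + 1.959963984540054 * sm[, "Std. Error"]),
                    p_value = sm[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n = nrow(dat), outcome = outcome,
                 converged = fit$converged, separation = separation,
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> outcome %s, n = %d%s%s\n", x$outcome, x$n,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION: not reportable]" else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC curve with trapezoidal AUC (tie-aware, identical to the
#' Mann-Whitney U statistic scaled by n1*n2), DeLong 95% CI, and the cutoff
#' maximizing the Youden index J = sensitivity + specificity - 1 (ties
#' resolved toward higher sensitivity). `positive_direction` states which
#' way the score points at the positive class, so the reported AUC matches
#' the clinical framing (e.g. low amplitude predicting failure gives
#' AUC > 0.5).
#'
#' @param scores numeric predictor.
#' @param labels binary 0/1 outcome (1 = positive class).
#' @param positive_direction `"higher"` if larger scores indicate the
#'   positive class, `"lower"` otherwise.
#' @return object of class `roc_result`: `auc`, `ci95`, `cutoff`,
#'   `sensitivity`, `specificity`, `orientation`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive_direction = c("higher", "lower")) {
  positive_direction <- match.arg(positive_direction)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop_fw("fw_bad_outcome", "labels must be binary 0/1 with both classes present")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (min(n_pos, n_neg) < 5)
    warning("fewer than 5 observations in a class: CI unreliable")
  dir <- if (positive_direction == "higher") "<" else ">"
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = dir, quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)],
                 error = function(e) c(NA_real_, NA_real_))
  co <- pROC::coords(r, x = "best", best.method = "youden", transpose = FALSE)
  if (nrow(co) > 1) co <- co[which.max(co$sensitivity), , drop = FALSE]
  cutoff <- co$threshold
  # pROC can return an infinite threshold when the optimum sits at an end
  cutoff <- min(max(cutoff, min(scores)), max(scores))
  structure(list(auc = auc, ci95 = ci, cutoff = cutoff,
                 sensitivity = co$sensitivity, specificity = co$specificity,
                 orientation = positive_direction,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g (%s score = positive), sens %.3f spec %.3f\n",
    x$auc, x$ci95[1], x$ci95[2], x$cutoff, x$orientation,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Combined dichotomized predictor (low FWA V1 and high DF I)
#'
#' Builds the binary indicators `low_fwa_v1 = FWA_V1 < cutoff_fwa_v1`,
#' `high_df_i = DF_I > cutoff_df_i` and their conjunction, then fits two
#' logistic models for the outcome: one with both single indicators (plus
#' any covariates) and one with the conjunction (plus covariates). Default
#' cutoffs are the published 60.38 uV and 5.70 Hz.
#'
#' @param cohort data.frame with `fwa_v1` and `df_i` columns (overridable).
#' @param outcome binary 0/1 outcome column (1 = the predicted bad outcome).
#' @param cutoff_fwa_v1 FWA V1 cutoff (uV).
#' @param cutoff_df_i DF I cutoff (Hz).
#' @param covariates optional extra predictor columns (e.g. LA CT volume).
#' @param fwa_col,df_col column names of the two metrics.
#' @return list: `indicators` (data.frame of the three 0/1 columns),
#'   `fit_single` and `fit_combined` ([fit_logistic()] results), `cutoffs`.
#' @export
combined_predictor <- function(cohort, outcome,
                               cutoff_fwa_v1 = 60.38, cutoff_df_i = 5.70,
                               covariates = NULL,
                               fwa_col = "fwa_v1", df_col = "df_i") {
  for (cl in c(fwa_col, df_col))
    if (is.null(cohort[[cl]]))
      stop_fw("fw_bad_param", "no column '%s' in cohort", cl)
  d <- cohort
  d$low_fwa_v1 <- as.integer(d[[fwa_col]] < cutoff_fwa_v1)
  d$high_df_i <- as.integer(d[[df_col]] > cutoff_df_i)
  d$low_fwa_and_high_df <- as.integer(d$low_fwa_v1 == 1 & d$high_df_i == 1)
  if (sum(d$low_fwa_and_high_df) == 0 || sum(d$low_fwa_and_high_df) == nrow(d))
    warning("empty stratum: the conjunction indicator is constant")
  fit_single <- fit_logistic(d, c("low_fwa_v1", "high_df_i", covariates), outcome)
  fit_combined <- fit_logistic(d, c("low_fwa_and_high_df", covariates), outcome)
  list(indicators = d[, c("low_fwa_v1", "high_df_i", "low_fwa_and_high_df")],
       fit_single = fit_single, fit_combined = fit_combined,
       cutoffs = c(fwa_v1 = cutoff_fwa_v1, df_i = cutoff_df_i))
}

#' Run the full outcome study on a cohort
#'
#' Reproduces the statistical pipeline for one endpoint: univariate screen
#' of every metric (and covariate), multivariable logistic regression of
#' the variables passing the screen at p < alpha, ROC analysis with
#' Youden cutoffs for the significant complexity metrics (oriented to
#' predict the bad outcome), and -- for procedural termination failure --
#' the combined dichotomized predictor at the published cutoffs. No
#' multiplicity correction is applied, matching the original analysis; the
#' screen's family-wise behaviour is characterized in the package tests
#' rather than corrected.
#'
#' The analysis path contains no randomness: identical cohorts give
#' identical reports.
#'
#' @param cohort data.frame; must contain `termination` and/or `recurrence`
#'   binary columns plus metric columns.
#' @param endpoint `"termination_failure"` or `"recurrence"`.
#' @param variables columns to screen; defaults to every metric and
#'   covariate column present.
#' @param covariates covariate columns always offered to the multivariable
#'   model (e.g. `la_ct_volume`).
#' @param alpha screening significance level.
#' @param cutoffs named vector with `fwa_v1` (uV) and `df_i` (Hz) for the
#'   combined predictor.
#' @return object of class `fibwave_study`: `screen`, `logistic`,
#'   `roc` (named list of [roc_analysis()] results), `combined`,
#'   `endpoint`, `alpha`.
#' @export
run_study <- function(cohort, endpoint = c("termination_failure", "recurrence"),
                      variables = NULL, covariates = intersect("la_ct_volume", names(cohort)),
                      alpha = 0.05,
                      cutoffs = c(fwa_v1 = 60.38, df_i = 5.70)) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "termination_failure") {
    if (is.null(cohort$termination))
      stop_fw("fw_bad_outcome", "cohort lacks a 'termination' column")
    cohort$termination_failure <- 1L - cohort$termination
    ycol <- "termination_failure"
  } else {
    if (is.null(cohort$recurrence))
      stop_fw("fw_bad_outcome", "cohort lacks a 'recurrence' column")
    ycol <- "recurrence"
  }
  metric_cols <- grep("^(fwa|df|oi|se|sampen)_", names(cohort), value = TRUE)
  if (is.null(variables)) variables <- unique(c(metric_cols, covariates))
  screen <- univariate_screen(cohort, variables, ycol)
  sig <- screen$variable[!is.na(screen$p_value) & screen$p_value < alpha]
  logistic <- if (length(sig)) fit_logistic(cohort, sig, ycol) else NULL
  roc_vars <- intersect(sig, metric_cols)
  roc <- lapply(roc_vars, function(v) {
    g1 <- mean(cohort[[v]][cohort[[ycol]] == 1])
    g0 <- mean(cohort[[v]][cohort[[ycol]] == 0])
    dirn <- if (g1 >= g0) "higher" else "lower"
    roc_analysis(cohort[[v]], cohort[[ycol]], positive_direction = dirn)
  })
  names(roc) <- roc_vars
  combined <- NULL
  if (endpoint == "termination_failure" &&
      all(c("fwa_v1", "df_i") %in% names(cohort))) {
    combined <- combined_predictor(cohort, ycol,
                                   cutoff_fwa_v1 = cutoffs[["fwa_v1"]],
                                   cutoff_df_i = cutoffs[["df_i"]],
                                   covariates = covariates)
  }
  structure(list(screen = screen, logistic = logistic, roc = roc,
                 combined = combined, endpoint = endpoint, alpha = alpha),
            class = "fibwave_study")
}

#' @export
print.fibwave_study <- function(x, ...) {
  cat(sprintf("== fibwave study: endpoint %s (alpha = %g) ==\n", x$endpoint, x$alpha))
  cat("\n-- univariate screen --\n")
  print(x$screen, digits = 3)
  if (!is.null(x$logistic)) { cat("\n-- multivariable logistic --\n"); print(x$logistic) }
  for (v in names(x$roc)) { cat(sprintf("\n-- ROC: %s --\n", v)); print(x$roc[[v]]) }
  if (!is.null(x$combined)) {
    cat("\n-- combined dichotomized predictor --\n")
    print(x$combined$fit_single); print(x$combined$fit_combined)
  }
  invisible(x)
}

#' Write a study report bundle as CSVs plus a text summary
#'
#' @param study a `fibwave_study`.
#' @param dir output directory (created if needed).
#' @param header_lines optional provenance comment lines for the CSVs.
#' @export
write_study_report <- function(study, dir, header_lines = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    for (h in header_lines) writeLines(paste0("# ", h), con)
    write.csv(df, con, row.names = FALSE)
  }
  put(study$screen, "screen.csv")
  if (!is.null(study$logistic)) put(study$logistic$table, "logistic.csv")
  if (length(study$roc)) {
    roc_df <- do.call(rbind, lapply(names(study$roc), function(v) {
      r <- study$roc[[v]]
      data.frame(variable = v, auc = r$auc, ci_low = r$ci95[1],
                 ci_high = r$ci95[2], cutoff = r$cutoff,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 orientation = r$orientation, stringsAsFactors = FALSE)
    }))
    put(roc_df, "roc.csv")
  }
  if (!is.null(study$combined)) {
    put(study$combined$fit_single$table, "combined_single.csv")
    put(study$combined$fit_combined$table, "combined_conjunction.csv")
  }
  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w")
  sink(con)
  print(study)
  sink()
  close(con)
  invisible(dir)
}
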