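# univariate screen, logistic regression, ROC, combined predictor

make_cohort <- function(n = 130, seed = 50, metrics = c("fwa_v1", "df_i", "la_ct_volume")) {
  gen_cohort(cohort_sim_params(n_patients = n, seed = seed), metrics = metrics)
}

test_that("the screen picks the right test and reports sane summaries", {
  co <- make_cohort(seed = 60)
  co$termination_failure <- 1L - co$termination
  sc <- univariate_screen(co, c("fwa_v1", "la_ct_volume"), "termination_failure")
  expect_true(all(sc$test %in% c("t", "mann-whitney")))
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  # identical groups: location test cannot find a difference
  co2 <- data.frame(y = rep(c(0, 1), each = 40), x = rep(rnorm(40), 2))
  sc2 <- univariate_screen(co2, "x", "y")
  expect_gt(sc2$p_value, 0.9)
  # constant variable flagged, untested
  co2$z <- 1
  sc3 <- univariate_screen(co2, "z", "y")
  expect_equal(sc3$type, "constant")
  expect_true(is.na(sc3$p_value))
})

test_that("chi-square statistic matches the hand-computed 2x2 value", {
  co <- data.frame(y = rep(c(1, 0), each = 40),
                   g = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)))
  sc <- univariate_screen(co, "g", "y")
  expect_equal(sc$test, "chi-square")
  expect_equal(sc$statistic, 20, tolerance = 1e-12)
})

test_that("sparse tables switch to Fisher's exact test", {
  co <- data.frame(y = rep(c(1, 0), each = 8),
                   g = c(rep(1, 1), rep(0, 7), rep(1, 7), rep(0, 1)))
  sc <- univariate_screen(co, "g", "y")  # all expected cells = 4 < 5
  expect_equal(sc$test, "fisher")
})

test_that("logistic OR on a 2x2 design equals ad/bc to 6 significant digits", {
  co <- data.frame(y = rep(c(1, 0), each = 30),
                   x = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20)))
  fit <- fit_logistic(co, "x", "y")
  expect_equal(fit$table$odds_ratio, 4, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_lt(fit$table$ci_low, 4); expect_gt(fit$table$ci_high, 4)
})

test_that("logistic OR is consistent under a planted null at large n", {
  co <- withr::with_seed(90, data.frame(y = rbinom(10000, 1, 0.5),
                                        x = rnorm(10000)))
  fit <- fit_logistic(co, "x", "y")
  expect_gt(fit$table$odds_ratio, 0.95)
  expect_lt(fit$table$odds_ratio, 1.05)
})

test_that("rescaling a predictor rescales its coefficient reciprocally", {
  co <- withr::with_seed(91, {
    x <- rnorm(500)
    data.frame(x = x, y = rbinom(500, 1, plogis(0.8 * x)))
  })
  co$x10 <- co$x / 10
  b1 <- log(fit_logistic(co, "x", "y")$table$odds_ratio)
  b10 <- log(fit_logistic(co, "x10", "y")$table$odds_ratio)
  expect_equal(b10, 10 * b1, tolerance = 1e-6)
})

test_that("perfect separation is flagged non-reportable", {
  co <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  fit <- suppressWarnings(fit_logistic(co, "x", "y"))
  expect_true(fit$separation)
})

test_that("ROC handles perfect separation and matches the Mann-Whitney identity", {
  sep <- roc_analysis(c(rnorm(20, 10), rnorm(20, -10)),
                      rep(c(1, 0), each = 20), "higher")
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_gt(sep$cutoff, max(rnorm(20, -10)))
  # tie-aware AUC identity on data with heavy ties
  for (s in 1:5) {
    sc <- withr::with_seed(s, sample(1:6, 80, replace = TRUE))
    lb <- withr::with_seed(s + 100, rbinom(80, 1, 0.4))
    if (length(unique(lb)) < 2) next
    r <- suppressWarnings(roc_analysis(sc, lb, "higher"))
    expect_equal(r$auc, auc_mw(sc, lb), tolerance = 1e-12)
  }
})

test_that("the Youden cutoff survives monotone transforms of the score", {
  sc <- withr::with_seed(7, c(rnorm(60, 1), rnorm(60)))
  lb <- rep(c(1, 0), each = 60)
  a <- roc_analysis(sc, lb, "higher")
  b <- roc_analysis(exp(sc), lb, "higher")
  expect_equal(b$auc, a$auc, tolerance = 1e-12)
  expect_equal(b$sensitivity, a$sensitivity)
  expect_equal(b$specificity, a$specificity)
  # the transformed cutoff induces the same classification
  expect_equal(exp(sc) >= b$cutoff, sc >= a$cutoff)
})

test_that("one-class input is rejected", {
  expect_error(roc_analysis(rnorm(10), rep(1, 10), "higher"), "both classes")
})

test_that("the conjunction indicator is the elementwise AND of its parts", {
  co <- make_cohort(seed = 70)
  co$termination_failure <- 1L - co$termination
  cp <- combined_predictor(co, "termination_failure")
  expect_equal(cp$indicators$low_fwa_and_high_df,
               as.integer(cp$indicators$low_fwa_v1 & cp$indicators$high_df_i))
  expect_equal(unname(cp$cutoffs), c(60.38, 5.70))
})

test_that("a planted conjunction-driven outcome gives the conjunction the largest OR", {
  wins <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      n <- 400
      fwa <- runif(n, 20, 120); df <- runif(n, 4, 8)
      conj <- fwa < 60.38 & df > 5.7
      y <- rbinom(n, 1, ifelse(conj, 0.75, 0.15))
      co <- data.frame(fwa_v1 = fwa, df_i = df, y = y)
      cp <- suppressWarnings(combined_predictor(co, "y"))
      or_c <- cp$fit_combined$table$odds_ratio[1]
      or_c > max(cp$fit_single$table$odds_ratio)
    })
  }, NA)
  expect_gte(mean(wins), 0.5)
})

test_that("run_study produces a coherent, deterministic report", {
  co <- gen_cohort(cohort_sim_params(n_patients = 260, seed = 80))
  st1 <- suppressWarnings(run_study(co))
  st2 <- suppressWarnings(run_study(co))
  expect_identical(st1$screen, st2$screen)
  expect_s3_class(st1, "fibwave_study")
  expect_true(all(c("fwa_v1", "df_i") %in% st1$screen$variable))
  # ROC orientation is chosen so AUC >= 0.5 for the bad outcome
  for (r in st1$roc) expect_gte(r$auc, 0.5)
  d <- withr::local_tempdir()
  write_study_report(st1, d)
  expect_true(file.exists(file.path(d, "screen.csv")))
  expect_true(file.exists(file.path(d, "summary.txt")))
})
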