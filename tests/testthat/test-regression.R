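# OLS surrogate model, prediction intervals, group summaries.

test_that("exact lines are recovered with R^2 = 1", {
  x <- c(0.8, 1.4, 2.2, 3.1, 3.9)
  f <- fitRCvsSAV(x, 100 - 16 * x)
  expect_equal(fitSlope(f), -16, tolerance = 1e-12)
  expect_equal(fitIntercept(f), 100, tolerance = 1e-12)
  expect_equal(fitRSquared(f), 1)
  expect_error(fitRCvsSAV(rep(2, 5), rnorm(5)), "degenerate")
  expect_error(fitRCvsSAV(1:2, 1:2), "3 points")
})

test_that("fit matches the standard linear-model machinery", {
  set.seed(4)
  x <- runif(20, 0.8, 3.9)
  y <- 99 - 15 * x + rnorm(20, sd = 2)
  f <- fitRCvsSAV(x, y)
  lmfit <- lm(y ~ x)
  expect_equal(fitSlope(f), unname(coef(lmfit)[2]))
  expect_equal(fitIntercept(f), unname(coef(lmfit)[1]))
  expect_equal(fitRSquared(f), summary(lmfit)$r.squared)
  expect_equal(fitResidualSd(f), summary(lmfit)$sigma)
  # residuals orthogonal to the predictor
  res <- y - predictRC(f, x)
  expect_lt(abs(sum(res * x)), 1e-9 * sum(abs(y)) * max(x))
})

test_that("predictRC reproduces arithmetic from the published coefficients", {
  pub <- new("RegressionFit", slope = -16.1, intercept = 99.8, rSquared = 0.96,
             residualSd = 3, n = 20L, meanX = 2.15, sxx = 17)
  expect_equal(predictRC(pub, 0.8), 86.92)
  expect_equal(predictRC(pub, 3.0), 51.5)
  expect_equal(predictRC(pub, 0), 99.8)
})

test_that("prediction intervals follow the Student-t closed form", {
  set.seed(9)
  x <- runif(20, 1, 4)
  y <- 100 - 16 * x + rnorm(20)
  f <- fitRCvsSAV(x, y)
  # at the predictor mean the half width collapses to t * s * sqrt(1 + 1/n)
  pi_mean <- predictionInterval(f, mean(x), 0.95)
  expect_equal(pi_mean$half_width,
               qt(0.975, 18) * fitResidualSd(f) * sqrt(1 + 1 / 20))
  # agreement with predict.lm's machinery
  lmfit <- lm(y ~ x)
  pl <- predict(lmfit, data.frame(x = c(1.2, 3.6)), interval = "prediction")
  pp <- predictionInterval(f, c(1.2, 3.6))
  expect_equal(pp$low, unname(pl[, "lwr"]))
  expect_equal(pp$high, unname(pl[, "upr"]))
  # width grows away from the mean; vanishing residuals shrink it to zero
  wid <- predictionInterval(f, c(mean(x), max(x) + 1))$half_width
  expect_lt(wid[1], wid[2])
  f0 <- fitRCvsSAV(x, 100 - 16 * x)
  expect_lt(predictionInterval(f0, 2)$half_width, 1e-9)
  expect_error(predictionInterval(fitRCvsSAV(1:3, c(1, 2, 3.1)), 2), "n >= 4")
})

test_that("simulated cohorts recover the generating line", {
  # slope/intercept within 2 standard errors in the bulk of seeded runs
  hits <- 0; runs <- 60
  for (s in seq_len(runs)) {
    set.seed(1000 + s)
    x <- runif(20, 0.8, 3.9)
    y <- 99.8 - 16.1 * x + rnorm(20, sd = 1.5)
    lmfit <- summary(lm(y ~ x))
    seSlope <- lmfit$coefficients[2, 2]
    f <- fitRCvsSAV(x, y)
    if (abs(fitSlope(f) + 16.1) <= 2 * seSlope) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.85)
})

test_that("group summaries reproduce printed AVG rows and rounding", {
  rc <- loadRCTable()
  p10 <- rc$rc_percent[rc$kind == "whole-parenchyma" & rc$iterations == 36 &
                       rc$tbr == "10:1"]
  s <- groupSummary(p10)
  expect_equal(s$mean_display, 76.3)
  expect_equal(s$sd_display, 1.5)
  c36 <- rc$rc_percent[rc$kind == "cortex-only" & rc$iterations == 36 &
                       rc$tbr == "infinity"]
  s2 <- groupSummary(c36)
  expect_equal(s2$mean_display, 48.4)
  # the printed column's own sample SD (the printed 8.3 summarizes
  # unrounded data; see extdata/anomalies.md)
  expect_equal(s2$sd_display, 8.2)
  s1 <- groupSummary(5.25)
  expect_true(s1$single_value)
  expect_equal(s1$sd, 0)
  expect_error(groupSummary(numeric(0)), "empty")
})
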