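test_that("rolling windows tile integer starts over the age range", {
  ages <- seq(18.5, 88.92, length.out = 250)
  set.seed(51)
  fi <- rnorm(250)
  met <- rnorm(250)
  rc <- rollingCorrelation(ages, met, fi, nBoot = 50, seed = 1)
  expect_identical(nrow(rc), 62L)
  expect_identical(rc$age_start, as.numeric(18:79))
  expect_true(all(rc$age_end - rc$age_start == 10))
  # membership is half-open [start, start + width)
  expect_identical(rc$n[1], sum(ages >= 18 & ages < 28))
  # interior subjects appear in exactly width/step windows
  inWin <- vapply(ages, function(a)
    sum(a >= rc$age_start & a < rc$age_end), numeric(1))
  interior <- ages >= 28 & ages < 79
  expect_true(all(inWin[interior] == 10))
  expect_error(rollingCorrelation(ages, met, fi, width = 0), "width")
})

test_that("perfectly linear windows give r = 1 with a collapsed CI", {
  ages <- seq(20, 40, length.out = 60)
  met <- ages * 2 + 1
  fi <- ages * 0.5 - 3
  rc <- rollingCorrelation(ages, met, fi, nBoot = 60, seed = 2)
  expect_true(all(abs(rc$r[rc$n >= 3] - 1) < 1e-12))
  expect_true(all(abs(rc$ci_low[rc$n >= 3] - 1) < 1e-6))
})

test_that("BCa collapses on constant data and tracks the percentile CI", {
  x <- rep(4.2, 20)
  expect_equal(bcaInterval(x, mean, nBoot = 100, seed = 3), c(4.2, 4.2))
  # symmetric statistic on symmetric data: z0 ~ 0, a ~ 0, so BCa is close
  # to the plain percentile interval from the same resamples
  set.seed(4)
  y <- rnorm(80)
  ci <- bcaInterval(y, mean, nBoot = 2000, seed = 5)
  set.seed(5)
  tb <- replicate(2000, mean(y[sample.int(80, 80, replace = TRUE)]))
  perc <- unname(quantile(tb, c(0.025, 0.975)))
  expect_lt(max(abs(ci - perc)), 0.05)
  expect_lt(ci[1], mean(y))
  expect_gt(ci[2], mean(y))
})

test_that("t tests match hand evaluation and handle identical pairs", {
  r <- tTests(c(3, 3, 3), c(3, 3, 3), paired = TRUE)
  expect_identical(r$t, 0)
  expect_identical(r$p, 1)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 2, 5, 3, 6)
  r2 <- tTests(a, b, paired = TRUE)
  d <- a - b
  tManual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r2$t, tManual, tolerance = 1e-10)
  expect_identical(r2$df, 4)
  expect_equal(r2$p, 2 * pt(-abs(tManual), 4), tolerance = 1e-10)
  # pooled df is n1 + n2 - 2, Welch df generally is not
  set.seed(52)
  x <- rnorm(10); y <- rnorm(14, 0, 3)
  expect_identical(tTests(x, y, pooled = TRUE)$df, 22)
  expect_lt(tTests(x, y)$df, 22)
  expect_error(tTests(1, c(1, 2)), "at least 2")
})

fakeMetrics <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("m%03d", 1:n), age = runif(n, 20, 85),
             sex = sample(c("F", "M"), n, replace = TRUE),
             fluid_intelligence = rnorm(n, 30, 5),
             group = sample(c("YA", "OA"), n, replace = TRUE),
             missing_behavior = FALSE,
             small_worldness = runif(n, 1, 3),
             sc_total = runif(n, 5, 20),
             mean_sc_distance = runif(n, 20, 60),
             stringsAsFactors = FALSE)
}

test_that("noiseless regression recovers planted coefficients exactly", {
  met <- fakeMetrics(80, seed = 53)
  met$le_001 <- 2 * met$age + 0 * (met$sex == "M")
  fit <- fitLocalEfficiencyModels(met, modelId = 1, group = "all",
                                  regionSet = 1)
  expect_equal(fit$estimate[fit$term == "Age"], 2, tolerance = 1e-10)
  expect_equal(attr(fit, "r.squared"), 1, tolerance = 1e-10)
  expect_identical(fit$term,
                   c("Intercept", "Age", "Sex (male)", "Small-worldness",
                     "SC total"))
})

test_that("OLS estimates equal the normal-equations oracle", {
  met <- fakeMetrics(120, seed = 54)
  met$le_001 <- 0.01 * met$age + 0.3 * met$small_worldness +
    0.05 * met$sc_total - 0.02 * met$mean_sc_distance + rnorm(120, 0, 0.5)
  fit <- fitLocalEfficiencyModels(met, modelId = 3, group = "all",
                                  regionSet = 1)
  Xd <- cbind(1, met$age, met$sex == "M", met$small_worldness,
              met$sc_total, met$mean_sc_distance)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% met$le_001)
  expect_equal(fit$estimate, as.numeric(beta), tolerance = 1e-8)
  # residuals orthogonal to the design
  res <- met$le_001 - Xd %*% beta
  expect_lt(max(abs(t(Xd) %*% res)), 1e-6)
  # CI construction
  expect_equal(fit$ci_high - fit$estimate,
               qt(0.975, 120 - 6) * fit$se, tolerance = 1e-10)
})

test_that("collinear designs are refused with the term named", {
  met <- fakeMetrics(50, seed = 55)
  met$sc_total <- 2 * met$small_worldness
  met$le_001 <- rnorm(50)
  expect_error(fitLocalEfficiencyModels(met, modelId = 1, group = "all",
                                        regionSet = 1), "collinear")
})

test_that("CI-overlap comparison follows the stated rule", {
  mk <- function(lo, hi) data.frame(term = "Age", estimate = (lo + hi) / 2,
                                    ci_low = lo, ci_high = hi, se = 1,
                                    t = 1, p = 0.5)
  expect_identical(compareGroupEstimates(mk(1, 2), mk(3, 4), "Age")$verdict,
                   "different")
  expect_identical(compareGroupEstimates(mk(1, 3), mk(2, 4), "Age")$verdict,
                   "not different")
  expect_error(compareGroupEstimates(mk(1, 2), mk(3, 4), "Sex"), "term")
})
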