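test_that("translation activity is the control-normalised luciferase ratio", {
  df <- data.frame(compound = c("DMSO", "PR20"), concentration = c(0, 2),
                   conc_units = c("pct", "uM"), replicate = 1,
                   luc_activity = c(100, 50), luc_mrna = c(100, 100),
                   target = "t1", target_abundance = 1)
  act <- translationActivity(df)
  expect_equal(act$activity[act$compound == "DMSO"], 1)
  expect_equal(act$activity[act$compound == "PR20"], 0.5)
  expect_equal(act$repression[act$compound == "PR20"], 1)
  # doubling both luciferase readings leaves activity unchanged
  df2 <- df
  df2$luc_activity <- df2$luc_activity * 2
  df2$luc_mrna <- df2$luc_mrna * 2
  expect_equal(translationActivity(df2)$activity, act$activity)
  expect_error(translationActivity(df[df$compound == "PR20", , drop = FALSE]),
               "control")
})

test_that("zero-intercept fit matches closed forms and the SSE minimiser", {
  f1 <- fitZeroIntercept(c(1, 2), c(2, 4))
  expect_equal(f1@slope, 2)
  expect_equal(f1@rss, 0)
  f2 <- fitZeroIntercept(c(1, 2), c(1, 3))
  expect_equal(f2@slope, 7 / 5)
  # property: the closed form minimises the SSE (numeric oracle)
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(3:20, 1)
      x <- rnorm(n); y <- rnorm(n, 2 * x, 1)
      beta <- fitZeroIntercept(x, y)@slope
      oracle <- stats::optimize(function(b) sum((y - b * x)^2),
                                c(-10, 10), tol = 1e-10)$minimum
      expect_lt(abs(beta - oracle), 1e-6)
    }
  })
  expect_error(fitZeroIntercept(c(0, 0), c(1, 2)), "all x are zero")
  expect_error(fitZeroIntercept(1, 2), "at least two")
})

test_that("fraction explained is the slope ratio with its invariances", {
  fPr <- fitZeroIntercept(c(1, 2, 3), c(1.1, 2.0, 2.9), target = "t1")
  fChx <- fitZeroIntercept(c(1, 2, 3), c(1.0, 2.1, 3.0), target = "t1")
  fe <- fractionExplained(fPr, fChx)
  expect_equal(fe$fraction_pct, 100 * fPr@slope / fChx@slope)
  # identical fits give exactly 100%
  expect_equal(fractionExplained(fChx, fChx)$fraction_pct, 100)
  # zero test slope gives 0%
  f0 <- fitZeroIntercept(c(1, 2, 3), c(0, 0, 0), target = "t1")
  expect_equal(fractionExplained(f0, fChx)$fraction_pct, 0)
  # scale invariance: rescaling both x-axes by c > 0 leaves F unchanged
  sc <- 3.7
  fPrS <- fitZeroIntercept(sc * c(1, 2, 3), c(1.1, 2.0, 2.9), target = "t1")
  fChxS <- fitZeroIntercept(sc * c(1, 2, 3), c(1.0, 2.1, 3.0), target = "t1")
  expect_equal(fractionExplained(fPrS, fChxS)$fraction_pct, fe$fraction_pct)
  # degenerate reference slope errors
  expect_error(fractionExplained(fPr, f0), "zero")
  # bootstrap CI brackets the point estimate and is seed-stable
  ci1 <- fractionExplained(fPr, fChx, nBoot = 200, seed = 99)
  ci2 <- fractionExplained(fPr, fChx, nBoot = 200, seed = 99)
  expect_equal(ci1$ci_lower, ci2$ci_lower)
  expect_lte(ci1$ci_lower, fe$fraction_pct)
  expect_gte(ci1$ci_upper, fe$fraction_pct)
})

test_that("noise-free pipeline recovers the generating slope ratio exactly", {
  sim <- simulateDoseResponse(seed = 3, betaPr = 0.9, betaChx = 1,
                              noiseSd = 0, lucNoiseSd = 0)
  res <- doseResponsePipeline(sim$points)
  expect_equal(res$fractions$fraction_pct, rep(90, 3), tolerance = 1e-9)
  # pipeline equals manual composition of its parts
  act <- translationActivity(sim$points)
  tg <- sim$points[sim$points$target == "nmd_target_1", ]
  key <- function(d) paste(d$compound, d$concentration, d$replicate)
  tg$repression <- act$repression[match(key(tg), key(act))]
  isCtrl <- tg$concentration == 0 | tolower(tg$compound) == "dmso"
  y <- log2(tg$target_abundance) - mean(log2(tg$target_abundance[isCtrl]))
  fPr <- fitZeroIntercept(tg$repression[tg$compound == "PR20" & !isCtrl],
                          y[tg$compound == "PR20" & !isCtrl], target = "t")
  fChx <- fitZeroIntercept(tg$repression[tg$compound == "CHX" & !isCtrl],
                           y[tg$compound == "CHX" & !isCtrl], target = "t")
  expect_equal(res$fractions$fraction_pct[1],
               fractionExplained(fPr, fChx)$fraction_pct, tolerance = 1e-12)
  # reference compound must be present
  noChx <- sim$points[sim$points$compound != "CHX", ]
  expect_error(doseResponsePipeline(noChx), "missing compound")
})

test_that("per-replicate fitting mode averages replicate slopes", {
  sim <- simulateDoseResponse(seed = 8, noiseSd = 0.05)
  pooled <- doseResponsePipeline(sim$points)
  perRep <- doseResponsePipeline(sim$points, perReplicate = TRUE)
  # the two estimators agree closely on well-behaved data
  expect_equal(perRep$fractions$fraction_pct, pooled$fractions$fraction_pct,
               tolerance = 0.1)
})
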