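plateOf <- function(df, control = "control", ref = "GAPDH")
  QpcrPlate(df, referenceTarget = ref, controlCondition = control)

test_that("technical replicates average with a spread warning", {
  w <- data.frame(sample_id = "s1", condition = "treated", target = "t1",
                  replicate = 1:2, ct = c(24.9, 25.1))
  avg <- averageTechnicalReplicates(plateOf(w, "treated"))
  expect_equal(wells(avg)$ct, 25)
  # single replicate passes through unchanged
  one <- plateOf(w[1, ], "treated")
  expect_equal(wells(averageTechnicalReplicates(one))$ct, 24.9)
  # spread above half a cycle warns but still averages
  w$ct <- c(20, 30)
  expect_warning(avg2 <- averageTechnicalReplicates(plateOf(w, "treated")),
                 "spread")
  expect_equal(wells(avg2)$ct, 25)
})

test_that("delta-delta-Ct fold changes follow the textbook example", {
  w <- rbind(
    data.frame(sample_id = "ctrl1", condition = "control",
               target = c("t1", "GAPDH"), replicate = 1, ct = c(26, 20)),
    data.frame(sample_id = "trt1", condition = "treated",
               target = c("t1", "GAPDH"), replicate = 1, ct = c(25, 20)))
  res <- relativeExpression(plateOf(w))
  trt <- res[res$condition == "treated", ]
  expect_equal(trt$fold_change, 2)       # ddCt = -1
  ctrl <- res[res$condition == "control", ]
  expect_equal(ctrl$fold_change, 1)      # control is 1 by construction
  # treated == control Cts -> fold change 1
  w2 <- w; w2$ct[3] <- 26
  res2 <- relativeExpression(plateOf(w2))
  expect_equal(res2$fold_change, c(1, 1))
  # missing reference well errors naming the sample
  expect_error(relativeExpression(plateOf(w[c(1, 2, 3), ])), "trt1")
})

test_that("zero-noise synthetic plates round-trip fold changes exactly", {
  truth <- matrix(c(3, 0.25, 1.7, 1), 2, 2,
                  dimnames = list(c("GR", "PR"), c("t1", "t2")))
  sim <- simulateQpcr(seed = 4, trueFold = truth, ctNoiseSd = 0)
  res <- relativeExpression(sim$plate)
  merged <- merge(res, sim$truth, by = c("condition", "target"))
  expect_equal(merged$fold_change, merged$fold, tolerance = 1e-12)
})

test_that("ratio t-test matches the closed form and its symmetries", {
  got <- ratioTTest(c(0.8, 1.0, 1.2))
  expect_equal(got$t, 1 / (0.2 / sqrt(3)), tolerance = 1e-6)
  expect_equal(got$df, 2)
  expect_equal(got$p.value, 2 * stats::pt(-abs(got$t), 2), tolerance = 1e-12)
  # zero mean -> t = 0, p = 1
  z <- ratioTTest(c(-0.5, 0, 0.5))
  expect_equal(z$t, 0)
  expect_equal(z$p.value, 1)
  # sign flip preserves p and negates t
  flip <- ratioTTest(-c(0.8, 1.0, 1.2))
  expect_equal(flip$t, -got$t)
  expect_equal(flip$p.value, got$p.value)
  # closed form on random inputs
  withr::with_seed(9, {
    for (i in 1:25) {
      x <- rnorm(sample(3:10, 1))
      got <- ratioTTest(x)
      tRef <- mean(x) / (sd(x) / sqrt(length(x)))
      expect_equal(got$t, tRef, tolerance = 1e-12)
      expect_equal(got$p.value, 2 * stats::pt(-abs(tRef), length(x) - 1),
                   tolerance = 1e-12)
    }
  })
  expect_error(ratioTTest(c(1, 1, 1)), "degenerate")
  expect_error(ratioTTest(0.5), "at least two")
})

test_that("nuclear fractions follow 2^-Ct pooling and stay in [0,1]", {
  mkPlate <- function(ct, cond = "GFP") plateOf(
    data.frame(sample_id = paste0(cond, "_r", seq_along(ct)), condition = cond,
               target = "t1", replicate = 1, ct = ct), control = "GFP")
  # A_nuc = 3 x A_cyt: nuclear Ct log2(3) cycles lower -> fraction 3/4
  nuc <- mkPlate(25 - log2(3))
  cyt <- mkPlate(25)
  expect_warning(res <- nuclearFraction(nuc, cyt), NA)
  expect_equal(res$mean_fraction, 0.75)
  # equal Cts give exactly one half
  res2 <- nuclearFraction(mkPlate(25), mkPlate(25))
  expect_equal(res2$mean_fraction, 0.5)
  # U1-like: nuclear Ct five cycles lower -> 32/33
  res3 <- nuclearFraction(mkPlate(20), mkPlate(25))
  expect_equal(res3$mean_fraction, 32 / 33)
  # monotone decreasing in nuclear Ct
  fr <- vapply(20:30, function(ct)
    nuclearFraction(mkPlate(ct), mkPlate(25))$mean_fraction, numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr >= 0 & fr <= 1))
})
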