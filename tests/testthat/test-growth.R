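test_that("growth AUC matches hand geometry and validates inputs", {
  expect_equal(aucTrapezoid(c(0, 1, 2), c(0.1, 0.1, 0.1)), 0.2)
  expect_equal(aucTrapezoid(c(0, 1, 2), c(0, 1, 0)), 1)
  expect_error(aucTrapezoid(0, 0.5), "at least 2")
  expect_error(aucTrapezoid(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("growth AUC is additive over intervals and linear in OD", {
  t <- seq(0, 10, by = 0.5)
  set.seed(2)
  od <- runif(length(t))
  full <- aucTrapezoid(t, od)
  split <- aucTrapezoid(t[1:11], od[1:11]) + aucTrapezoid(t[11:21], od[11:21])
  expect_equal(full, split, tolerance = 1e-12)
  expect_equal(aucTrapezoid(t, 3 * od), 3 * full, tolerance = 1e-12)
})

test_that("growth boost of identical curve sets is exactly 1", {
  curves <- rampCurves(c(1, 1.1, 0.9))
  gb <- growthBoost(curves, curves)
  expect_identical(gb$boost, 1)
  expect_equal(gb$p, 1)
  expect_false(gb$significant)
})

test_that("a doubled-AUC fixture yields boost 2 and a significant Student t-test", {
  treated <- rampCurves(c(1.99, 2.00, 2.01))
  control <- rampCurves(c(0.99, 1.00, 1.01), condition = "NA")
  gb <- growthBoost(treated, control)
  expect_equal(gb$boost, 2, tolerance = 1e-10)
  expect_lt(gb$p, 0.05)
  expect_length(c(gb$auc_treated, gb$auc_control), 6)
})

test_that("simulated substrate-boosted growth beats the no-growth baseline", {
  treated <- simulateGrowthCurves(boosted = TRUE, noiseSd = 0.01, seed = 1)
  control <- simulateGrowthCurves(boosted = FALSE, noiseSd = 0.01, seed = 2)
  gb <- growthBoost(treated, control)
  expect_gt(gb$boost, 2)
  expect_true(gb$significant)
  # degenerate control: zero mean AUC flagged as undefined boost
  flat <- rampCurves(c(0, 0, 0))
  expect_true(is.na(growthBoost(treated, flat)$boost))
})

test_that("standard curves recover slope, efficiency and invert exactly", {
  run <- simulateQpcrSeries(copies = 10^(0:6), slope = -3.3219,
                            intercept = 40, noiseSd = 0)
  fit <- fitStandardCurve(run)
  expect_equal(fit$efficiency, 1, tolerance = 1e-4) # 100%
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  back <- quantifyCopies(run$cq, fit)
  expect_equal(back, run$copies, tolerance = 1e-6)
  expect_equal(quantifyCopies(fit$intercept, fit), 1, tolerance = 1e-10)
  expect_equal(quantifyCopies(fit$intercept + fit$slope, fit), 10,
               tolerance = 1e-9)
  expect_error(fitStandardCurve(data.frame(copies = c(1, 10), cq = c(40, 37))),
               "3 distinct")
  bad <- data.frame(copies = 10^(0:3), cq = c(30, 33, 36, 39))
  expect_error(fitStandardCurve(bad), "non-negative")
})

test_that("log2 fold change handles pseudocounts and is antisymmetric", {
  expect_equal(log2FoldChange(5, 5), 0)
  expect_equal(log2FoldChange(16, 2), 3)
  expect_equal(log2FoldChange(0, 100, 1), log2(1 / 101))
  expect_equal(log2FoldChange(7, 3), -log2FoldChange(3, 7))
  expect_error(log2FoldChange(-1, 2), "non-negative")
})

test_that("coculture analysis contrasts arms and detects cross-feeding", {
  mk <- function(c0, c24) data.frame(
    timepoint_h = rep(c(0, 24), each = 3),
    copies = c(c0, c24)
  )
  flat <- mk(c(100, 101, 99), c(100, 101, 99))
  same <- cocultureAnalysis(flat, flat)
  expect_equal(same$l2fc_co - same$l2fc_mono, 0)
  expect_false(same$significant)
  # monoculture flat, coculture 8-fold up: within-arm L2FC 3, significant
  co <- mk(c(100, 101, 99), c(799, 800, 801))
  res <- cocultureAnalysis(flat, co, pseudocount = 0)
  expect_equal(res$l2fc_co, 3, tolerance = 0.01)
  expect_true(res$significant)
  # degrader suppressed when lower in coculture than monoculture
  res2 <- cocultureAnalysis(flat, co,
                            degraderMono = mk(c(1, 1, 1) * 1e4, c(1.0, 1.1, 0.9) * 1e5),
                            degraderCo = mk(c(1, 1, 1) * 1e4, c(0.5, 0.55, 0.45) * 1e5))
  expect_true(res2$degrader_suppressed)
  expect_lt(res2$degrader_l2fc, 0)
  expect_error(cocultureAnalysis(flat, flat[flat$timepoint_h == 0, ]),
               "24")
})
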