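test_that("simulated spectra carry their ground-truth %CD in the noise-free band ratio", {
  for (cd in c(0, 12.5, 30, 50, 80, 100)) {
    sp <- simulateSpectrum(cdFraction = cd, noiseSd = 0)
    got <- computeCdFraction(sp)
    if (cd == 0) {
      expect_lt(got, 1e-9)
    } else {
      expect_lt(abs(got - cd) / cd, 1e-6)
    }
  }
})

test_that("spectrum generator is reproducible under a seed and honours baselines", {
  a <- simulateSpectrum(30, noiseSd = 0.05, seed = 11)
  b <- simulateSpectrum(30, noiseSd = 0.05, seed = 11)
  c <- simulateSpectrum(30, noiseSd = 0.05, seed = 12)
  expect_identical(intensities(a), intensities(b))
  expect_false(identical(intensities(a), intensities(c)))
  # linear baseline does not change the baseline-corrected score
  flat <- simulateSpectrum(40, noiseSd = 0)
  tilted <- simulateSpectrum(40, noiseSd = 0, baselineSlope = 0.01,
                             baselineIntercept = 5)
  expect_equal(computeCdFraction(flat), computeCdFraction(tilted),
               tolerance = 1e-9)
})

test_that("spectrum generator rejects ranges that miss required bands", {
  expect_error(simulateSpectrum(10, wavenumberRange = c(1200, 3200)),
               "phenylalanine")
  expect_error(simulateSpectrum(10, wavenumberRange = c(400, 2500)), "C-H")
})

test_that("community generator: sample totals equal depth, metadata complete, seeded", {
  ae <- simulateCommunity(nDonors = 4, nGenera = 8, depth = 3000,
                          enrichedGenera = c(1, 3), effectMultiplier = 4,
                          timepoints = c(0, 6), seed = 5)
  cnt <- SummarizedExperiment::assay(ae, "counts")
  expect_true(all(colSums(cnt) == 3000))
  expect_equal(ncol(cnt), 4 * 2 * 2) # donors x timepoints x (AG, NA)
  meta <- SummarizedExperiment::colData(ae)
  expect_false(anyNA(meta$donor) || anyNA(meta$treatment))
  ae2 <- simulateCommunity(nDonors = 4, nGenera = 8, depth = 3000,
                           enrichedGenera = c(1, 3), effectMultiplier = 4,
                           timepoints = c(0, 6), seed = 5)
  expect_identical(cnt, SummarizedExperiment::assay(ae2, "counts"))
  expect_error(
    simulateCommunity(nGenera = 5, enrichedGenera = 9),
    "1..nGenera", fixed = TRUE
  )
})

test_that("growth curve generator honours replicates, grid and the no-growth baseline", {
  g <- simulateGrowthCurves(carryingCapacity = 0.8, noiseSd = 0,
                            nReplicates = 3)
  expect_equal(nrow(g), 3 * length(seq(0, 48, by = 0.5)))
  expect_equal(max(g$od600), 0.8, tolerance = 1e-3)
  flat <- simulateGrowthCurves(boosted = FALSE, noiseSd = 0)
  expect_lt(max(flat$od600), 0.06)
})

test_that("qPCR series generator is exactly log-linear at zero noise", {
  run <- simulateQpcrSeries(copies = 10^(0:5), slope = -3.5, intercept = 38,
                            noiseSd = 0)
  expect_equal(nrow(run), 3 * 6) # triplicate wells per dilution
  fit <- fitStandardCurve(run)
  expect_equal(fit$slope, -3.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 38, tolerance = 1e-10)
})

test_that("qPCR slope estimate is unbiased under Cq noise", {
  slopes <- vapply(1:100, function(s) {
    fitStandardCurve(simulateQpcrSeries(noiseSd = 0.2, seed = s))$slope
  }, numeric(1))
  # Monte-Carlo error of the mean slope over 100 seeds
  expect_lt(abs(mean(slopes) - (-3.3219)), 4 * sd(slopes) / sqrt(100))
})

test_that("isolate census generator expands compositions record by record", {
  records <- simulateIsolateCensus()
  expect_equal(nrow(records), 98)
  two <- simulateIsolateCensus(
    data.frame(species = c("a", "b"), phylum = c("P1", "P2"),
               count = c(3L, 2L))
  )
  expect_equal(nrow(two), 5)
  expect_equal(unname(speciesFractions(censusSummary(two))[c("a", "b")]),
               c(0.6, 0.4))
  one <- simulateIsolateCensus(
    data.frame(species = "a", phylum = "P1", count = 1L)
  )
  cs <- censusSummary(one)
  expect_equal(nrow(censusRecords(cs)), 1)
  expect_equal(unname(speciesFractions(cs)), 1)
})
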