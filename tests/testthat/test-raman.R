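test_that("band integration removes baselines and recovers known areas", {
  w <- 400:3200
  # constant intensity: endpoint baseline removes it entirely
  flat <- RamanSpectrum(w, rep(7, length(w)))
  expect_equal(integrateBand(flat, c(2040, 2300)), 0)
  # unit-height triangle of base 2 * 50: area = 50
  tri <- triangleSpectrum(center = 2170, halfWidth = 50)
  expect_equal(integrateBand(tri, c(2040, 2300)), 50, tolerance = 1e-9)
  # Gaussian of known area, dense-grid numeric oracle
  area <- 80
  sigma <- 40 / (2 * sqrt(2 * log(2)))
  y <- area * dnorm(w, 2950, sigma)
  gauss <- RamanSpectrum(w, y)
  expect_equal(integrateBand(gauss, c(2800, 3100)), area, tolerance = 0.01 * area)
})

test_that("band integration rejects bad windows", {
  sp <- triangleSpectrum(2170, 50)
  expect_error(integrateBand(sp, c(3300, 3400)), "outside")
  expect_error(integrateBand(sp, c(2170.1, 2170.9)), "fewer than 2")
})

test_that("%CD is invariant to intensity scaling and additive linear baselines", {
  for (s in 1:5) {
    sp <- simulateSpectrum(cdFraction = 25, noiseSd = 0.01, seed = s)
    ref <- computeCdFraction(sp)
    w <- wavenumbers(sp)
    scaled <- RamanSpectrum(w, 3.7 * intensities(sp))
    shifted <- RamanSpectrum(w, intensities(sp) + 2 + 0.004 * w)
    expect_equal(computeCdFraction(scaled), ref, tolerance = 1e-9)
    expect_equal(computeCdFraction(shifted), ref, tolerance = 1e-9)
  }
})

test_that("%CD endpoints: no C-D mass gives 0, symmetric split gives 50", {
  expect_lt(computeCdFraction(simulateSpectrum(0, noiseSd = 0)), 1e-9)
  expect_equal(computeCdFraction(simulateSpectrum(50, noiseSd = 0)), 50,
               tolerance = 1e-4)
  empty <- RamanSpectrum(400:3200, rep(0, 2801))
  expect_error(computeCdFraction(empty), "no cellular signal")
})

test_that("validity requires clear C-H and phenylalanine peaks", {
  expect_false(isValidSpectrum(RamanSpectrum(400:3200, rep(0, 2801))))
  expect_true(isValidSpectrum(simulateSpectrum(20, noiseSd = 0.005, seed = 1)))
  noPhe <- simulateSpectrum(20, pheArea = 0, noiseSd = 0.005, seed = 1)
  expect_false(isValidSpectrum(noPhe))
})

test_that("activity threshold is mean + 3 sample SD with location/scale equivariance", {
  expect_equal(thresholdValue(fitActivityThreshold(c(5, 5, 5))), 5)
  expect_equal(thresholdValue(fitActivityThreshold(c(1, 2, 3))), 5)
  expect_error(fitActivityThreshold(numeric()), "at least 2")
  expect_error(fitActivityThreshold(4), "at least 2")
  base <- c(1, 2, 3, 4)
  t0 <- thresholdValue(fitActivityThreshold(base))
  # shifting all controls shifts the threshold; scaling scales it
  expect_equal(thresholdValue(fitActivityThreshold(base + 2.5)), t0 + 2.5)
  expect_equal(thresholdValue(fitActivityThreshold(base * 3)), t0 * 3)
  # raising the top control value never lowers the threshold
  up <- base
  up[4] <- up[4] + 0.5
  expect_gte(thresholdValue(fitActivityThreshold(up)), t0)
})

test_that("classification is strict at the threshold and skips invalid cells", {
  thr <- fitActivityThreshold(c(1, 2, 3)) # threshold 5
  res <- data.frame(
    cell_id = c("at", "above", "below", "bad"),
    cd_fraction = c(5, 5 + 1e-9, 4.9, 50),
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- classifyActive(res, thr)
  expect_identical(out$active, c(FALSE, TRUE, FALSE, NA))
  expect_true(all(out$threshold_used == 5))
})

test_that("a labelled cohort is almost entirely called active against water controls", {
  spectra <- c(
    lapply(1:50, function(i) simulateSpectrum(
      cdFraction = 20, noiseSd = 0.01, seed = i, cellId = paste0("lab", i),
      condition = "AG"
    )),
    lapply(1:50, function(i) simulateSpectrum(
      cdFraction = abs(rnorm(1, 0, 0.2)), noiseSd = 0.01, seed = 100 + i,
      cellId = paste0("ctl", i), condition = "water"
    ))
  )
  out <- scoreActivity(spectra, controlCondition = "water")
  lab <- out[out$condition == "AG", ]
  expect_gte(mean(lab$active), 0.95)
})

test_that("condition comparison is a one-way ANOVA with the expected behaviour", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- compareActivity(same)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  far <- list(a = rnorm(20, 0, 0.01), b = rnorm(20, 20, 0.01))
  expect_lt(compareActivity(far)$p.value, 1e-6)
  expect_error(compareActivity(list(a = 1, b = c(1, 2))), ">= 2 values")
  expect_error(compareActivity(list(a = c(1, 2))), "two condition groups")
})
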