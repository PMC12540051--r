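# Shared fixtures built in code.

# spectrum with a unit-height triangle peak of given base width on a zero
# background, covering all standard bands
triangleSpectrum <- function(center, halfWidth, wmin = 400, wmax = 3200) {
  w <- wmin:wmax
  y <- pmax(1 - abs(w - center) / halfWidth, 0)
  RamanSpectrum(w, y, cellId = "tri")
}

# piecewise-constant spectrum: `levels` is a named list window -> intensity,
# e.g. list(cd = 12 / 260, plRef = 2 / 50); everything else zero
bandLevelSpectrum <- function(levels, bands = bandDefinitions(),
                              wmin = 400, wmax = 3200) {
  w <- wmin:wmax
  y <- numeric(length(w))
  for (nm in names(levels)) {
    win <- slot(bands, nm)
    y[w >= win[1] & w <= win[2]] <- levels[[nm]]
  }
  RamanSpectrum(w, y, cellId = "levels")
}

# minimal abundance experiment: one treated + one control sample per donor at
# one timepoint, counts supplied as genera x (2 * nDonors) matrix ordered
# (donor1 treated, donor1 control, donor2 treated, ...)
pairedAbundance <- function(counts, nDonors, timepoint = 6,
                            treatment = "AG") {
  meta <- data.frame(
    donor = rep(sprintf("D%d", seq_len(nDonors)), each = 2),
    treatment = rep(c(treatment, "NA"), nDonors),
    timepoint = timepoint
  )
  AbundanceExperiment(counts, meta)
}

# tidy growth-curve set with one linear ramp od(t) = slope_r * t per replicate
rampCurves <- function(slopes, duration = 48, interval = 0.5,
                       condition = "AG") {
  do.call(rbind, lapply(seq_along(slopes), function(r) {
    t <- seq(0, duration, by = interval)
    data.frame(strain = "s", condition = condition, replicate = r,
               time_h = t, od600 = slopes[r] * t / duration)
  }))
}
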