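# Single-cell Raman activity scoring: band integration, spectrum validity,
# %CD computation, water-control thresholding, condition comparison.

.windowIndex <- function(spectrum, window) {
  w <- wavenumbers(spectrum)
  if (window[1] < min(w) || window[2] > max(w))
    stop(sprintf(
      "window [%g, %g] cm^-1 lies outside the spectrum range [%g, %g]",
      window[1], window[2], min(w), max(w)
    ))
  idx <- which(w >= window[1] & w <= window[2])
  if (length(idx) < 2L)
    stop(sprintf(
      "window [%g, %g] cm^-1 contains fewer than 2 spectral points",
      window[1], window[2]
    ))
  idx
}

# linear baseline through the window's endpoint intensities
.endpointBaseline <- function(w, y) {
  n <- length(w)
  y[1] + (y[n] - y[1]) * (w - w[1]) / (w[n] - w[1])
}

#' Integrate a Raman band
#'
#' Trapezoidal integral of intensity over a wavenumber window. With
#' `baseline = "linear"` (default) the straight line through the window's
#' endpoint intensities is subtracted first and negative corrected intensities
#' are clipped to zero, which makes downstream band ratios invariant to
#' intensity scaling and any additive linear baseline. With
#' `baseline = "none"` the raw signal is integrated (used by the sorting
#' indices, which the instrument computes on raw signal in real time).
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param window numeric(2) wavenumber interval (cm^-1); must overlap the
#'   spectrum range with at least two points.
#' @param baseline `"linear"` (endpoint baseline, clipped) or `"none"` (raw).
#'
#' @return numeric(1), integrated intensity-area (a.u. * cm^-1).
#' @examples
#' sp <- RamanSpectrum(1:11, c(0, 0, 0, 1, 2, 3, 2, 1, 0, 0, 0))
#' integrateBand(sp, c(1, 11)) # triangle, area 9
#' @export
integrateBand <- function(spectrum, window, baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  idx <- .windowIndex(spectrum, window)
  w <- wavenumbers(spectrum)[idx]
  y <- intensities(spectrum)[idx]
  if (baseline == "linear") y <- pmax(y - .endpointBaseline(w, y), 0)
  pracma::trapz(w, y)
}

# peak height above the window's endpoint baseline
.bandHeight <- function(spectrum, window) {
  idx <- .windowIndex(spectrum, window)
  w <- wavenumbers(spectrum)[idx]
  y <- intensities(spectrum)[idx]
  max(y - .endpointBaseline(w, y))
}

#' Spectrum validity check
#'
#' A spectrum is considered valid when it shows a clear C-H stretch and a
#' clear phenylalanine peak, confirming the signal originates from cellular
#' material. "Clear" is implemented as the baseline-corrected peak height
#' exceeding `snrMin` times a robust noise estimate, the scaled median
#' absolute deviation of the silent reference window (1850-1900 cm^-1)
#' residuals about its endpoint baseline.
#'
#' @param spectrum a [RamanSpectrum-class] covering the C-H, phenylalanine and
#'   reference windows.
#' @param bands a [BandDefinitions-class].
#' @param snrMin minimum peak signal-to-noise ratio (default 3, the
#'   conventional detection limit).
#'
#' @return logical(1).
#' @export
isValidSpectrum <- function(spectrum, bands = bandDefinitions(), snrMin = 3) {
  idx <- .windowIndex(spectrum, bands@plRef)
  w <- wavenumbers(spectrum)[idx]
  y <- intensities(spectrum)[idx]
  noise <- stats::mad(y - .endpointBaseline(w, y), center = 0)
  hCh <- .bandHeight(spectrum, bands@ch)
  hPhe <- .bandHeight(spectrum, bands@phe)
  hCh > snrMin * noise && hPhe > snrMin * noise
}

#' Percentage of deuterium-labelled bonds (%CD)
#'
#' The per-cell metabolic-activity score: the C-D band integral divided by the
#' summed C-D and C-H integrals, times 100. Band integrals use the
#' endpoint-baseline trapezoid of [integrateBand()], so the score is invariant
#' to intensity scaling and additive linear baselines.
#'
#' @param spectrum a valid [RamanSpectrum-class] covering the C-D and C-H
#'   windows (see [isValidSpectrum()]).
#' @param bands a [BandDefinitions-class].
#'
#' @return numeric(1) in `[0, 100]`.
#' @examples
#' sp <- simulateSpectrum(cdFraction = 30, noiseSd = 0, seed = 1)
#' computeCdFraction(sp)
#' @export
computeCdFraction <- function(spectrum, bands = bandDefinitions()) {
  iCd <- integrateBand(spectrum, bands@cd)
  iCh <- integrateBand(spectrum, bands@ch)
  if (iCd + iCh <= 0)
    stop("no cellular signal: C-D and C-H band integrals are both zero")
  100 * iCd / (iCd + iCh)
}

#' Fit the metabolic-activity threshold from water controls
#'
#' The activity cutoff is the mean plus `multiplier` (default 3) sample
#' standard deviations (n-1 denominator) of %CD values from cells incubated
#' without heavy water.
#'
#' @param controlCds numeric vector of water-control %CD values (>= 2 values).
#' @param multiplier SD multiplier, default 3.
#'
#' @return An [ActivityThreshold-class].
#' @examples
#' fitActivityThreshold(c(1, 2, 3)) # mean 2, SD 1 -> threshold 5
#' @export
fitActivityThreshold <- function(controlCds, multiplier = 3) {
  controlCds <- as.numeric(controlCds)
  if (length(controlCds) < 2L)
    stop("at least 2 water-control %CD values are required")
  m <- mean(controlCds)
  s <- stats::sd(controlCds)
  new("ActivityThreshold",
    meanControl = m, sdControl = s, threshold = m + multiplier * s,
    multiplier = multiplier, nControl = length(controlCds)
  )
}

#' Classify cells as metabolically active
#'
#' Marks each valid cell active when its %CD strictly exceeds the
#' water-control threshold. Invalid spectra are excluded from classification
#' (`active` stays `NA`) but kept in the table, flagged by `valid`.
#'
#' @param results data.frame with at least columns `cd_fraction` (percent) and
#'   `valid` (logical); typically the output of [scoreActivity()].
#' @param threshold an [ActivityThreshold-class].
#'
#' @return The input data.frame with `active` (logical) and `threshold_used`
#'   (percent) columns filled.
#' @export
classifyActive <- function(results, threshold) {
  stopifnot(is(threshold, "ActivityThreshold"),
            all(c("cd_fraction", "valid") %in% names(results)))
  thr <- thresholdValue(threshold)
  results$active <- ifelse(results$valid, results$cd_fraction > thr, NA)
  results$threshold_used <- thr
  results
}

#' Compare %CD across conditions
#'
#' One-way fixed-effects ANOVA of per-cell %CD values across incubation
#' conditions, cells pooled over donors.
#'
#' @param groups named list of numeric %CD vectors, one per condition; at
#'   least two groups with at least two values each.
#'
#' @return An object of class `htest` with the F statistic, degrees of freedom
#'   and p-value.
#' @examples
#' compareActivity(list(AG = c(10, 12, 14), NA_ = c(1, 2, 3)))
#' @export
compareActivity <- function(groups) {
  if (length(groups) < 2L)
    stop("at least two condition groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop(sprintf(
      "every group needs >= 2 values; offending group(s): %s",
      paste(names(groups)[sizes < 2L], collapse = ", ")
    ))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes))
  )
  stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
}

#' Score activity for a set of spectra
#'
#' Computes validity and %CD for each spectrum; optionally fits the
#' water-control threshold from the spectra whose condition equals
#' `controlCondition` and classifies all valid cells.
#'
#' @param spectra list of [RamanSpectrum-class] objects.
#' @param bands a [BandDefinitions-class].
#' @param snrMin validity signal-to-noise cutoff (see [isValidSpectrum()]).
#' @param controlCondition condition label of the water controls, or `NULL`
#'   to skip thresholding.
#' @param multiplier SD multiplier for the threshold.
#'
#' @return data.frame with columns `cell_id`, `donor`, `condition`,
#'   `timepoint`, `valid`, `cd_fraction`, and (when thresholded) `active` and
#'   `threshold_used`.
#' @export
scoreActivity <- function(spectra, bands = bandDefinitions(), snrMin = 3,
                          controlCondition = "water", multiplier = 3) {
  rows <- lapply(spectra, function(sp) {
    valid <- isValidSpectrum(sp, bands, snrMin)
    cd <- if (valid) computeCdFraction(sp, bands) else NA_real_
    data.frame(
      cell_id = sp@cellId, donor = sp@donor, condition = sp@condition,
      timepoint = sp@timepoint, valid = valid, cd_fraction = cd,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(controlCondition)) {
    ctrl <- out$cd_fraction[out$condition == controlCondition & out$valid]
    if (length(ctrl) < 2L)
      stop(sprintf(
        "fewer than 2 valid water-control spectra with condition '%s'",
        controlCondition
      ))
    thr <- fitActivityThreshold(ctrl, multiplier)
    out <- classifyActive(out, thr)
  }
  out
}
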