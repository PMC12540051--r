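# In-silico Raman-activated cell sorting: sorting indices, collect/waste
# decisions, a seeded run simulator with the platform's throughput/accuracy
# model, and post-sort cultivation accounting.

#' Compute the sorting indices Pc and PL
#'
#' The cell index Pc is the integrated 1620-1670 cm^-1 signal of the cell
#' spectrum relative to the same band in the surrounding-medium (background)
#' spectrum; the labelling index PL is the ratio of the C-D stretch integral
#' to a silent reference region (1850-1900 cm^-1) within the cell spectrum.
#' Both use raw (non-baseline-subtracted) trapezoid integrals, as the sorter
#' computes them in real time; PL's denominator is floored at `eps`, and
#' negative indices are clipped to zero.
#'
#' @param cellSpectrum,backgroundSpectrum [RamanSpectrum-class] objects
#'   covering the needed windows.
#' @param bands a [BandDefinitions-class].
#' @param eps denominator floor (intensity-area units), default 1e-12.
#'
#' @return data.frame with columns `cell_id`, `pc`, `pl`.
#' @export
computeSortIndices <- function(cellSpectrum, backgroundSpectrum,
                               bands = bandDefinitions(), eps = 1e-12) {
  bgCell <- integrateBand(backgroundSpectrum, bands@cellBand, baseline = "none")
  if (bgCell <= 0)
    stop("background cell-band integral is <= 0; cannot form the cell index")
  pc <- integrateBand(cellSpectrum, bands@cellBand, baseline = "none") / bgCell
  ref <- max(integrateBand(cellSpectrum, bands@plRef, baseline = "none"), eps)
  pl <- integrateBand(cellSpectrum, bands@cd, baseline = "none") / ref
  data.frame(
    cell_id = cellId(cellSpectrum), pc = max(pc, 0), pl = max(pl, 0),
    stringsAsFactors = FALSE
  )
}

#' Collect/waste decision
#'
#' A cell is routed to the collection outlet when both indices strictly exceed
#' their thresholds (`pc > pcMin` and `pl > plMin`); otherwise it goes to
#' waste. The defaults (1.1 and 6.0) were set on glucose-incubated controls
#' without heavy water.
#'
#' @param pc,pl numeric vectors of sorting indices (recycled to a common
#'   length).
#' @param pcMin,plMin thresholds, defaults 1.1 and 6.0.
#'
#' @return character vector of `"collect"` / `"waste"`.
#' @examples
#' decideSort(c(1.1, 1.2, 5.0), c(6.0, 6.5, 5.9))
#' @export
decideSort <- function(pc, pl, pcMin = 1.1, plMin = 6.0) {
  stopifnot(pcMin > 0, plMin > 0)
  ifelse(pc > pcMin & pl > plMin, "collect", "waste")
}

#' Simulate a sorting run
#'
#' Applies the platform's accuracy model to a sequence of collect/waste
#' decisions: each decided cell is independently misdirected to the other
#' outlet with probability `1 - accuracy`; run duration is
#' `n / throughput`; colonies recovered from the collection outlet are drawn
#' Binomial(n_collected, cultivationP).
#'
#' @param decisions character vector of `"collect"`/`"waste"` decisions
#'   (non-empty), e.g. from [decideSort()].
#' @param accuracy probability a decided cell reaches the intended outlet
#'   (default 0.983, the platform's reported accuracy).
#' @param throughput cells analysed per hour (default 500).
#' @param cultivationP probability a collected cell yields a colony.
#' @param seed integer seed or `NULL`.
#'
#' @return list of class `"SortRunReport"` with fields `n_analyzed`,
#'   `n_collected`, `n_waste`, `n_misdirected`, `n_colonies`, `duration`
#'   (hours) and `success_rate` (percent; `NA` when nothing was collected).
#' @examples
#' simulateSortRun(rep("collect", 100), cultivationP = 0.2, seed = 1)
#' @export
simulateSortRun <- function(decisions, accuracy = 0.983, throughput = 500,
                            cultivationP = 0.1, seed = NULL) {
  if (length(decisions) == 0L)
    stop("decisions must be non-empty")
  stopifnot(all(decisions %in% c("collect", "waste")),
            accuracy >= 0, accuracy <= 1, throughput > 0,
            cultivationP >= 0, cultivationP <= 1)
  .maybeSeed(seed, {
    n <- length(decisions)
    mis <- stats::rbinom(n, 1L, 1 - accuracy) == 1L
    outlet <- ifelse(
      mis,
      ifelse(decisions == "collect", "waste", "collect"),
      decisions
    )
    nCollected <- sum(outlet == "collect")
    nColonies <- stats::rbinom(1L, nCollected, cultivationP)
    report <- list(
      n_analyzed = n,
      n_collected = nCollected,
      n_waste = n - nCollected,
      n_misdirected = sum(mis),
      n_colonies = nColonies,
      duration = n / throughput,
      success_rate = if (nCollected > 0)
        cultivationSuccessRate(nColonies, nCollected) else NA_real_
    )
    class(report) <- "SortRunReport"
    report
  })
}

#' @export
print.SortRunReport <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Sort run: %d cells analysed in %.2f h\n",
      "  collected %d | waste %d | misdirected %d\n",
      "  colonies %d (cultivation success %s%%)\n"
    ),
    x$n_analyzed, x$duration, x$n_collected, x$n_waste, x$n_misdirected,
    x$n_colonies,
    if (is.na(x$success_rate)) "NA" else sprintf("%.2f", x$success_rate)
  ))
  invisible(x)
}

#' Post-sorting cultivation success rate
#'
#' Percentage of colonies recovered relative to the number of labelled cells
#' sorted into the collection outlet.
#'
#' @param nColonies,nSorted counts; `nSorted` must be positive.
#' @return numeric(1), percent.
#' @examples
#' cultivationSuccessRate(10, 100) # 10
#' @export
cultivationSuccessRate <- function(nColonies, nSorted) {
  stopifnot(nSorted > 0, nColonies >= 0)
  100 * nColonies / nSorted
}
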