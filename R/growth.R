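# Growth and coculture quantification: trapezoid AUC, AUC growth boost with
# Student's t-test, qPCR standard curves, absolute quantification and log2
# fold changes.

#' Area under a growth curve
#'
#' Trapezoidal area of OD600 over time after subtracting a blank level;
#' negative blank-corrected values are clipped to zero before integration.
#'
#' @param times numeric vector of times (hours), strictly increasing, >= 2
#'   points.
#' @param values OD600 readings, same length.
#' @param blank blank OD level subtracted before integration (default 0).
#'
#' @return numeric(1), OD * h.
#' @examples
#' aucTrapezoid(c(0, 1, 2), c(0, 1, 0)) # 1
#' @export
aucTrapezoid <- function(times, values, blank = 0) {
  if (length(times) < 2L) stop("at least 2 timepoints are required")
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (no duplicates)")
  pracma::trapz(times, pmax(values - blank, 0))
}

#' AUC growth boost
#'
#' Quantifies substrate-dependent growth as the ratio of mean
#' area-under-the-growth-curve in supplemented medium to the no-amendment
#' control, with a two-sided Student's (equal-variance) t-test on the
#' per-replicate AUCs. With `blankCorrect = TRUE` (default) each replicate's
#' first-timepoint OD is subtracted as its blank.
#'
#' @param treated,control data.frames with columns `time_h`, `od600`,
#'   `replicate` (>= 2 replicates each), e.g. from [simulateGrowthCurves()]
#'   or [readGrowthCurves()].
#' @param blankCorrect subtract each replicate's first OD before integrating.
#' @param varEqual use the classical equal-variance t-test (default `TRUE`);
#'   `FALSE` gives Welch's variant.
#' @param alpha significance level, default 0.05.
#'
#' @return list of class `"GrowthBoostResult"`: `auc_treated`, `auc_control`
#'   (per-replicate AUCs), `boost` (ratio of means; `NA` when the control
#'   mean AUC is zero), `t_stat`, `p`, `significant`.
#' @export
growthBoost <- function(treated, control, blankCorrect = TRUE,
                        varEqual = TRUE, alpha = 0.05) {
  repAuc <- function(df) {
    sp <- split(df, df$replicate)
    if (length(sp) < 2L) stop("at least 2 replicates per condition")
    vapply(sp, function(r) {
      r <- r[order(r$time_h), ]
      aucTrapezoid(r$time_h, r$od600,
                   blank = if (blankCorrect) r$od600[1] else 0)
    }, numeric(1))
  }
  aucT <- repAuc(treated)
  aucC <- repAuc(control)
  boost <- if (mean(aucC) > 0) mean(aucT) / mean(aucC) else NA_real_
  if (stats::sd(c(aucT, aucC)) == 0) {
    tStat <- 0; p <- 1
  } else {
    tt <- stats::t.test(aucT, aucC, var.equal = varEqual)
    tStat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(
      auc_treated = aucT, auc_control = aucC, boost = boost,
      t_stat = tStat, p = p, significant = is.finite(p) && p < alpha
    ),
    class = "GrowthBoostResult"
  )
}

#' @export
print.GrowthBoostResult <- function(x, ...) {
  cat(sprintf(
    "Growth boost: %.3g (mean AUC %.3g vs %.3g OD*h; t = %.3g, p = %.3g%s)\n",
    x$boost, mean(x$auc_treated), mean(x$auc_control), x$t_stat, x$p,
    if (isTRUE(x$significant)) ", significant" else ""
  ))
  invisible(x)
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Cq = slope * log10(copies) + intercept` to a serial
#' dilution series, reporting R^2 and the amplification efficiency
#' `E = 10^(-1/slope) - 1` (1.0 = 100% for slope -3.3219 = -1/log10(2)).
#'
#' @param run data.frame with columns `copies` (> 0) and `cq`; at least 3
#'   distinct dilution levels.
#'
#' @return list of class `"QpcrStandardCurve"`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_levels`.
#' @examples
#' fitStandardCurve(simulateQpcrSeries(slope = -3.3219, noiseSd = 0))
#' @export
fitStandardCurve <- function(run) {
  stopifnot(all(c("copies", "cq") %in% names(run)))
  if (any(run$copies <= 0)) stop("copies must be positive")
  if (length(unique(run$copies)) < 3L)
    stop("at least 3 distinct dilution levels are required")
  fit <- stats::lm(cq ~ log10(copies), data = run)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("fitted slope is non-negative: invalid qPCR assay")
  # R^2 computed directly (summary.lm warns on noise-free series)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((run$cq - mean(run$cq))^2)
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1,
      n_levels = length(unique(run$copies))
    ),
    class = "QpcrStandardCurve"
  )
}

#' @export
print.QpcrStandardCurve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4g * log10(copies) + %.4g (R^2 = %.4f, efficiency = %.1f%%)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency
  ))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept) / slope)`.
#'
#' @param cq numeric vector of quantification cycles.
#' @param curve a `QpcrStandardCurve` from [fitStandardCurve()].
#' @return numeric vector of copy numbers.
#' @export
quantifyCopies <- function(cq, curve) {
  stopifnot(inherits(curve, "QpcrStandardCurve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Log2 fold change
#'
#' `log2((after + pseudocount) / (before + pseudocount))`. A positive
#' pseudocount keeps the result finite when a timepoint has zero copies.
#'
#' @param after,before non-negative copy numbers (vectorised).
#' @param pseudocount non-negative, default 0.
#' @return numeric vector.
#' @examples
#' log2FoldChange(16, 2) # 3
#' @export
log2FoldChange <- function(after, before, pseudocount = 0) {
  if (any(after < 0) || any(before < 0) || pseudocount < 0)
    stop("inputs must be non-negative")
  log2((after + pseudocount) / (before + pseudocount))
}

#' Coculture cross-feeding analysis
#'
#' For one strain quantified by qPCR in monoculture and in coculture with the
#' focal degrader: the within-arm log2 fold change of absolute abundance
#' (24 h vs 0 h, using mean copies per timepoint) and a two-sided Student's
#' t-test comparing coculture vs monoculture 24 h abundances across
#' replicates. Optionally, the focal degrader's own quantifications can be
#' supplied to report its L2FC in coculture vs monoculture and flag growth
#' suppression.
#'
#' @param mono,co data.frames with columns `timepoint_h` (containing 0 and
#'   24) and `copies`, one row per replicate well (>= 2 replicates per
#'   timepoint).
#' @param pseudocount for the L2FC; `NULL` (default) uses the smallest
#'   positive copy number across both arms, or 1 if all are zero.
#' @param varEqual equal-variance t-test (default `TRUE`).
#' @param alpha significance level, default 0.05.
#' @param degraderMono,degraderCo optional data.frames (same layout) with the
#'   focal degrader's quantifications in the two arms.
#'
#' @return list of class `"CocultureResult"`: `l2fc_mono`, `l2fc_co` (within-
#'   arm 24 h vs 0 h L2FC), `t_stat`, `p`, `significant` (co vs mono at 24 h),
#'   `pseudocount`, and when degrader data are given `degrader_l2fc`
#'   (coculture vs monoculture at 24 h) and `degrader_suppressed`.
#' @export
cocultureAnalysis <- function(mono, co, pseudocount = NULL, varEqual = TRUE,
                              alpha = 0.05, degraderMono = NULL,
                              degraderCo = NULL) {
  getTp <- function(df, tp, arm) {
    v <- df$copies[df$timepoint_h == tp]
    if (length(v) < 2L)
      stop(sprintf("missing or underreplicated %g h timepoint in %s arm",
                   tp, arm))
    v
  }
  m0 <- getTp(mono, 0, "monoculture"); m24 <- getTp(mono, 24, "monoculture")
  c0 <- getTp(co, 0, "coculture"); c24 <- getTp(co, 24, "coculture")
  if (is.null(pseudocount)) {
    pos <- c(m0, m24, c0, c24)
    pos <- pos[pos > 0]
    pseudocount <- if (length(pos)) min(pos) else 1
  }
  l2Mono <- log2FoldChange(mean(m24), mean(m0), pseudocount)
  l2Co <- log2FoldChange(mean(c24), mean(c0), pseudocount)
  if (stats::sd(c(c24, m24)) == 0) {
    tStat <- 0; p <- 1
  } else {
    tt <- stats::t.test(c24, m24, var.equal = varEqual)
    tStat <- unname(tt$statistic); p <- tt$p.value
  }
  out <- list(
    l2fc_mono = l2Mono, l2fc_co = l2Co, t_stat = tStat, p = p,
    significant = is.finite(p) && p < alpha, pseudocount = pseudocount
  )
  if (!is.null(degraderMono) && !is.null(degraderCo)) {
    dm24 <- getTp(degraderMono, 24, "degrader monoculture")
    dc24 <- getTp(degraderCo, 24, "degrader coculture")
    out$degrader_l2fc <- log2FoldChange(mean(dc24), mean(dm24), pseudocount)
    out$degrader_suppressed <- out$degrader_l2fc < 0
  }
  class(out) <- "CocultureResult"
  out
}

#' @export
print.CocultureResult <- function(x, ...) {
  cat(sprintf(
    "Coculture: L2FC(24h vs 0h) mono = %.3g, co = %.3g; co vs mono 24h t = %.3g, p = %.3g%s\n",
    x$l2fc_mono, x$l2fc_co, x$t_stat, x$p,
    if (isTRUE(x$significant)) ", significant" else ""
  ))
  if (!is.null(x$degrader_l2fc))
    cat(sprintf(
      "  degrader L2FC (co vs mono, 24h) = %.3g%s\n", x$degrader_l2fc,
      if (isTRUE(x$degrader_suppressed)) " (suppressed)" else ""
    ))
  invisible(x)
}
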