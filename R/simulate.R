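# Seeded synthetic-data generators: Raman spectra with known %CD ground
# truth, donor-structured multinomial count tables with planted enrichments,
# logistic growth curves, log-linear qPCR dilution series, isolate censuses.

.gaussianPeak <- function(w, center, area, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  area * stats::dnorm(w, mean = center, sd = sigma)
}

.maybeSeed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, force(code))
}

#' Simulate a single-cell Raman spectrum with known %CD
#'
#' Builds a noise-free signal of Gaussian peaks at 2170 (C-D), 2950 (C-H),
#' 1003 (phenylalanine) and 1650 (amide) cm^-1, splits the total C-H + C-D
#' area so that the C-D share equals `cdFraction` percent, then adds an
#' additive linear baseline and white Gaussian noise. On the noise-free
#' signal the C-D/(C-D + C-H) trapezoid-integral ratio equals
#' `cdFraction`/100 to within 1e-6 relative error.
#'
#' @param cdFraction true %CD in `[0, 100]`.
#' @param totalArea total C-H + C-D peak area (a.u. * cm^-1, > 0).
#' @param pheArea,amideArea phenylalanine / amide peak areas (>= 0).
#' @param noiseSd white-noise standard deviation (a.u.).
#' @param baselineSlope,baselineIntercept additive linear baseline parameters.
#' @param wavenumberRange numeric(2); must cover 990-3100 cm^-1 so all bands
#'   exist.
#' @param step grid spacing (cm^-1, > 0), default 1.
#' @param fwhmCdCh,fwhmPhe,fwhmAmide peak widths at half maximum (cm^-1).
#' @param seed integer seed, or `NULL`; RNG state is restored afterwards.
#' @param cellId,donor,condition,timepoint metadata passed to the spectrum.
#'
#' @return A [RamanSpectrum-class].
#' @examples
#' sp <- simulateSpectrum(cdFraction = 30, noiseSd = 0)
#' computeCdFraction(sp)
#' @export
simulateSpectrum <- function(cdFraction, totalArea = 100, pheArea = 20,
                             amideArea = 30, noiseSd = 0, baselineSlope = 0,
                             baselineIntercept = 0,
                             wavenumberRange = c(400, 3200), step = 1,
                             fwhmCdCh = 40, fwhmPhe = 12, fwhmAmide = 30,
                             seed = NULL, cellId = "sim", donor = "simD",
                             condition = "sim", timepoint = NA_real_) {
  stopifnot(cdFraction >= 0, cdFraction <= 100, totalArea > 0,
            pheArea >= 0, amideArea >= 0, noiseSd >= 0, step > 0)
  required <- c(phe = 990, ch = 3100)
  if (wavenumberRange[1] > 990)
    stop("wavenumber range misses the phenylalanine band (990-1015 cm^-1)")
  if (wavenumberRange[2] < 3100)
    stop("wavenumber range misses the C-H band (2800-3100 cm^-1)")
  w <- seq(wavenumberRange[1], wavenumberRange[2], by = step)
  cdArea <- totalArea * cdFraction / 100
  chArea <- totalArea - cdArea
  signal <- .gaussianPeak(w, 2170, cdArea, fwhmCdCh) +
    .gaussianPeak(w, 2950, chArea, fwhmCdCh) +
    .gaussianPeak(w, 1003, pheArea, fwhmPhe) +
    .gaussianPeak(w, 1650, amideArea, fwhmAmide)
  y <- signal + baselineIntercept + baselineSlope * w
  if (noiseSd > 0)
    y <- y + .maybeSeed(seed, stats::rnorm(length(w), sd = noiseSd))
  RamanSpectrum(w, y, cellId = cellId, donor = donor, condition = condition,
                timepoint = timepoint)
}

#' Simulate a donor-structured genus count table with planted enrichments
#'
#' For each donor and timepoint one treated and one control ("NA") sample is
#' drawn multinomially at the given sequencing depth from donor-specific
#' baseline proportions (log-normal across genera, reproducing strong
#' inter-donor variation). In treated samples at timepoints > 0 the planted
#' genera have their proportions multiplied by `effectMultiplier` and the
#' vector renormalised.
#'
#' @param nDonors,nGenera counts.
#' @param depth reads per sample (> 0).
#' @param donorLogmeanSd SD of the per-donor, per-genus log baseline.
#' @param enrichedGenera integer indices in `1..nGenera` of planted genera.
#' @param effectMultiplier fold-change applied to planted genera under
#'   treatment (> 0; 1 = null model).
#' @param timepoints numeric vector of timepoint labels (hours).
#' @param treatment treated-condition label, default "AG".
#' @param seed integer seed or `NULL`.
#'
#' @return An [AbundanceExperiment-class]; the planted indices are kept in
#'   `metadata(x)$enriched_genera`.
#' @examples
#' ae <- simulateCommunity(nDonors = 3, nGenera = 5, depth = 1000,
#'                         enrichedGenera = 2, effectMultiplier = 4, seed = 1)
#' ae
#' @export
simulateCommunity <- function(nDonors = 10, nGenera = 20, depth = 50000,
                              donorLogmeanSd = 1, enrichedGenera = integer(),
                              effectMultiplier = 1, timepoints = c(0, 6, 24),
                              treatment = "AG", seed = NULL) {
  stopifnot(depth > 0, effectMultiplier > 0, nDonors >= 1, nGenera >= 1)
  enrichedGenera <- as.integer(enrichedGenera)
  if (length(enrichedGenera) &&
      (min(enrichedGenera) < 1L || max(enrichedGenera) > nGenera))
    stop("enrichedGenera indices must lie in 1..nGenera")
  .maybeSeed(seed, {
    genera <- sprintf("genus%02d", seq_len(nGenera))
    donors <- sprintf("D%02d", seq_len(nDonors))
    counts <- list(); meta <- list(); k <- 0L
    for (d in seq_len(nDonors)) {
      base <- exp(stats::rnorm(nGenera, sd = donorLogmeanSd))
      base <- base / sum(base)
      for (tp in timepoints) {
        pTreat <- base
        if (tp > 0 && length(enrichedGenera)) {
          pTreat[enrichedGenera] <- pTreat[enrichedGenera] * effectMultiplier
          pTreat <- pTreat / sum(pTreat)
        }
        for (cond in c(treatment, "NA")) {
          p <- if (cond == treatment) pTreat else base
          k <- k + 1L
          counts[[k]] <- stats::rmultinom(1, size = depth, prob = p)[, 1]
          meta[[k]] <- data.frame(
            donor = donors[d], treatment = cond, timepoint = tp,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    cnt <- do.call(cbind, counts)
    rownames(cnt) <- genera
    md <- do.call(rbind, meta)
    colnames(cnt) <- sprintf(
      "%s_%s_t%g", md$donor, gsub("NA", "NAc", md$treatment), md$timepoint
    )
    ae <- AbundanceExperiment(cnt, md)
    S4Vectors::metadata(ae)$enriched_genera <- enrichedGenera
    S4Vectors::metadata(ae)$effect_multiplier <- effectMultiplier
    ae
  })
}

#' Simulate replicate growth curves
#'
#' Logistic curves `OD(t) = K / (1 + exp(-r (t - lag)))` plus Gaussian noise,
#' sampled on a regular grid, three technical replicates by default. With
#' `boosted = FALSE` the carrying capacity is replaced by a no-growth baseline
#' level, emulating a strain that cannot use the substrate.
#'
#' @param carryingCapacity K, OD600 units.
#' @param rate logistic rate r, per hour.
#' @param lag inflection time, hours.
#' @param duration,interval assay length and sampling interval, hours
#'   (defaults 48 h every 0.5 h).
#' @param noiseSd OD noise SD.
#' @param nReplicates technical replicates (>= 1, default 3).
#' @param boosted logical; `FALSE` yields the no-growth baseline.
#' @param baselineOd no-growth capacity used when `boosted = FALSE`.
#' @param strain,condition labels stored in the output.
#' @param seed integer seed or `NULL`.
#'
#' @return data.frame with columns `strain`, `condition`, `replicate`,
#'   `time_h`, `od600`.
#' @export
simulateGrowthCurves <- function(carryingCapacity = 1, rate = 0.5, lag = 8,
                                 duration = 48, interval = 0.5, noiseSd = 0,
                                 nReplicates = 3, boosted = TRUE,
                                 baselineOd = 0.05, strain = "strain",
                                 condition = if (boosted) "AG" else "NA",
                                 seed = NULL) {
  stopifnot(duration > 0, interval > 0, nReplicates >= 1)
  times <- seq(0, duration, by = interval)
  K <- if (boosted) carryingCapacity else baselineOd
  mu <- K / (1 + exp(-rate * (times - lag)))
  .maybeSeed(seed, {
    do.call(rbind, lapply(seq_len(nReplicates), function(r) {
      od <- mu
      if (noiseSd > 0) od <- od + stats::rnorm(length(times), sd = noiseSd)
      data.frame(
        strain = strain, condition = condition, replicate = r,
        time_h = times, od600 = od, stringsAsFactors = FALSE
      )
    }))
  })
}

#' Simulate a qPCR dilution series
#'
#' Log-linear quantification cycles, `Cq = slope * log10(copies) + intercept`
#' plus Gaussian noise, with triplicate wells per dilution level — the layout
#' of a 10-fold serial-dilution standard curve.
#'
#' @param copies vector of template copy numbers (> 0), e.g. `10^(0:6)`.
#' @param slope Cq per log10 copies (negative for a valid assay; -3.3219
#'   corresponds to 100% amplification efficiency).
#' @param intercept Cq at 1 copy.
#' @param noiseSd Cq noise SD.
#' @param nWells wells per dilution, default 3.
#' @param seed integer seed or `NULL`.
#'
#' @return data.frame with columns `dilution`, `copies`, `well`, `cq`.
#' @export
simulateQpcrSeries <- function(copies = 10^(0:6), slope = -3.3219,
                               intercept = 40, noiseSd = 0, nWells = 3,
                               seed = NULL) {
  stopifnot(all(copies > 0), nWells >= 1)
  .maybeSeed(seed, {
    df <- expand.grid(well = seq_len(nWells), copies = copies,
                      KEEP.OUT.ATTRS = FALSE)
    df$dilution <- match(df$copies, sort(unique(copies), decreasing = TRUE))
    df$cq <- slope * log10(df$copies) + intercept
    if (noiseSd > 0) df$cq <- df$cq + stats::rnorm(nrow(df), sd = noiseSd)
    df[, c("dilution", "copies", "well", "cq")]
  })
}

#' Reference composition of recovered arabinogalactan-responsive isolates
#'
#' The per-species isolate counts and phylum assignments of the 98 strains
#' recovered by Raman-activated cell sorting in the underlying study: 16
#' species across Actinomycetota (72), Bacteroidota (16) and Bacillota (10),
#' dominated by *Bifidobacterium longum* (n = 45).
#'
#' @return data.frame with columns `species`, `phylum`, `count`.
#' @examples
#' sum(agIsolateComposition()$count) # 98
#' @export
agIsolateComposition <- function() {
  data.frame(
    species = c(
      "Bifidobacterium longum", "Collinsella aerofaciens",
      "Eggerthella lenta",
      "Alistipes shahii", "Alistipes senegalensis", "Alistipes putredinis",
      "Alistipes onderdonkii", "Bacteroides uniformis",
      "Bacteroides stercoris", "Parabacteroides merdae",
      "Phocaeicola coprocola",
      "Catenibacterium mitsuokai", "Dysosmobacter welbionis",
      "Faecalibacterium prausnitzii", "Phascolarctobacterium faecium",
      "Ruminococcus bicirculans"
    ),
    phylum = c(
      rep("Actinomycetota", 3),
      rep("Bacteroidota", 8),
      rep("Bacillota", 5)
    ),
    count = c(45L, 26L, 1L, 5L, 1L, 2L, 3L, 2L, 1L, 1L, 1L, 6L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulate an isolate census
#'
#' Expands a species -> count composition into one record per isolate, donors
#' assigned round-robin. The default composition is the study census returned
#' by [agIsolateComposition()]. The generator is deterministic; `seed` is
#' accepted for interface symmetry with the other simulators.
#'
#' @param composition data.frame with columns `species`, `phylum`, `count`.
#' @param nDonors number of donors for the round-robin assignment.
#' @param seed ignored (kept for generator-interface symmetry).
#'
#' @return data.frame of records with columns `isolate_id`, `species`,
#'   `phylum`, `donor`.
#' @examples
#' nrow(simulateIsolateCensus()) # 98
#' @export
simulateIsolateCensus <- function(composition = agIsolateComposition(),
                                  nDonors = 10, seed = NULL) {
  stopifnot(all(c("species", "phylum", "count") %in% names(composition)),
            all(composition$count >= 1))
  species <- rep(composition$species, composition$count)
  phylum <- rep(composition$phylum, composition$count)
  n <- length(species)
  data.frame(
    isolate_id = sprintf("ISO%03d", seq_len(n)),
    species = species,
    phylum = phylum,
    donor = sprintf("D%02d", ((seq_len(n) - 1L) %% nDonors) + 1L),
    stringsAsFactors = FALSE
  )
}
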