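#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats mad sd oneway.test pnorm p.adjust cmdscale t.test lm
#'   rnorm rbinom rmultinom coef
#' @importFrom utils read.delim write.table read.csv
NULL

#' Single-cell Raman spectrum
#'
#' Container for one cell's Raman trace: a strictly increasing wavenumber axis
#' (cm^-1) with matched intensities (arbitrary units) plus provenance metadata
#' (cell id, donor, incubation condition, timepoint in hours).
#'
#' @slot wavenumbers numeric, strictly increasing, cm^-1.
#' @slot intensities numeric, same length as `wavenumbers`.
#' @slot cellId character(1) cell identifier.
#' @slot donor character(1) donor identifier.
#' @slot condition character(1) incubation condition label (e.g. "AG", "NA",
#'   "water").
#' @slot timepoint numeric(1) incubation time in hours.
#'
#' @export
setClass("RamanSpectrum",
  representation(
    wavenumbers = "numeric",
    intensities = "numeric",
    cellId      = "character",
    donor       = "character",
    condition   = "character",
    timepoint   = "numeric"
  ),
  prototype(
    cellId = NA_character_, donor = NA_character_,
    condition = NA_character_, timepoint = NA_real_
  )
)

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumbers
  y <- object@intensities
  msg <- character()
  if (length(w) != length(y))
    msg <- c(msg, "wavenumbers and intensities must have equal length")
  if (length(w) >= 2 && any(diff(w) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (anyNA(w) || (length(w) && any(!is.finite(w))))
    msg <- c(msg, "wavenumbers must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a RamanSpectrum
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   increasing.
#' @param intensities numeric vector of intensities, same length.
#' @param cellId,donor,condition character(1) metadata labels.
#' @param timepoint numeric(1) hours.
#'
#' @return A [RamanSpectrum-class] object.
#' @examples
#' sp <- RamanSpectrum(400:3200, rep(0, 2801), cellId = "c1")
#' sp
#' @export
RamanSpectrum <- function(wavenumbers, intensities, cellId = NA_character_,
                          donor = NA_character_, condition = NA_character_,
                          timepoint = NA_real_) {
  new("RamanSpectrum",
    wavenumbers = as.numeric(wavenumbers),
    intensities = as.numeric(intensities),
    cellId = as.character(cellId), donor = as.character(donor),
    condition = as.character(condition), timepoint = as.numeric(timepoint)
  )
}

#' @describeIn RamanSpectrum-class wavenumber axis (cm^-1)
#' @param x,object a `RamanSpectrum`
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname RamanSpectrum-class
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(x) x@wavenumbers)

#' @describeIn RamanSpectrum-class intensity values (a.u.)
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname RamanSpectrum-class
#' @export
setMethod("intensities", "RamanSpectrum", function(x) x@intensities)

#' @describeIn RamanSpectrum-class cell identifier
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname RamanSpectrum-class
#' @export
setMethod("cellId", "RamanSpectrum", function(x) x@cellId)

setMethod("show", "RamanSpectrum", function(object) {
  w <- object@wavenumbers
  cat("RamanSpectrum:", object@cellId, "\n")
  cat(sprintf(
    "  %d points, %.0f-%.0f cm^-1 | donor=%s condition=%s t=%sh\n",
    length(w), min(w), max(w), object@donor, object@condition,
    format(object@timepoint)
  ))
})

#' Raman band definitions
#'
#' Wavenumber windows (cm^-1) used throughout the activity and sorting
#' computations: the C-D stretch (deuterium incorporation), the C-H stretch,
#' the phenylalanine marker peak, the cell band used by the sorter's cell
#' index, and a silent reference region.
#'
#' @slot cd numeric(2), C-D stretch window, default 2040-2300.
#' @slot ch numeric(2), C-H stretch window, default 2800-3100.
#' @slot phe numeric(2), phenylalanine window, default 990-1015.
#' @slot cellBand numeric(2), cell (amide-region) window, default 1620-1670.
#' @slot plRef numeric(2), silent reference window, default 1850-1900.
#'
#' @export
setClass("BandDefinitions",
  representation(
    cd = "numeric", ch = "numeric", phe = "numeric",
    cellBand = "numeric", plRef = "numeric"
  )
)

setValidity("BandDefinitions", function(object) {
  ok <- vapply(
    c("cd", "ch", "phe", "cellBand", "plRef"),
    function(s) {
      v <- slot(object, s)
      length(v) == 2 && all(is.finite(v)) && v[1] < v[2]
    },
    logical(1)
  )
  if (all(ok)) TRUE else
    paste("malformed window(s):", paste(names(ok)[!ok], collapse = ", "))
})

#' Construct band definitions
#'
#' Defaults are the windows used for gut-microbiome deuterium labelling work:
#' C-D 2040-2300, C-H 2800-3100, phenylalanine 990-1015 (around the ~1000
#' marker), cell band 1620-1670, silent reference 1850-1900 cm^-1.
#'
#' @param cd,ch,phe,cellBand,plRef numeric(2) windows in cm^-1.
#' @return A [BandDefinitions-class] object.
#' @examples
#' bandDefinitions()
#' @export
bandDefinitions <- function(cd = c(2040, 2300), ch = c(2800, 3100),
                            phe = c(990, 1015), cellBand = c(1620, 1670),
                            plRef = c(1850, 1900)) {
  new("BandDefinitions",
    cd = as.numeric(cd), ch = as.numeric(ch), phe = as.numeric(phe),
    cellBand = as.numeric(cellBand), plRef = as.numeric(plRef)
  )
}

setMethod("show", "BandDefinitions", function(object) {
  cat("BandDefinitions (cm^-1):\n")
  for (s in c("cd", "ch", "phe", "cellBand", "plRef")) {
    v <- slot(object, s)
    cat(sprintf("  %-8s %g-%g\n", s, v[1], v[2]))
  }
})

#' Metabolic-activity threshold from water controls
#'
#' The activity cutoff on %CD derived from cells incubated without heavy
#' water: mean plus three sample standard deviations of the control %CD
#' values.
#'
#' @slot meanControl,sdControl numeric(1), control mean and sample SD (%CD).
#' @slot threshold numeric(1), `meanControl + multiplier * sdControl`.
#' @slot multiplier numeric(1), SD multiplier (default 3).
#' @slot nControl integer(1), number of control cells.
#'
#' @export
setClass("ActivityThreshold",
  representation(
    meanControl = "numeric", sdControl = "numeric",
    threshold = "numeric", multiplier = "numeric", nControl = "integer"
  )
)

setValidity("ActivityThreshold", function(object) {
  msg <- character()
  if (object@nControl < 2L)
    msg <- c(msg, "nControl must be >= 2")
  if (!isTRUE(all.equal(
    object@threshold,
    object@meanControl + object@multiplier * object@sdControl
  )))
    msg <- c(msg, "threshold must equal meanControl + multiplier * sdControl")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ActivityThreshold", function(object) {
  cat(sprintf(
    "ActivityThreshold: %.4g %%CD (mean %.4g + %g x SD %.4g, n = %d controls)\n",
    object@threshold, object@meanControl, object@multiplier,
    object@sdControl, object@nControl
  ))
})

#' @describeIn ActivityThreshold-class the %CD cutoff
#' @param x an `ActivityThreshold`
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname ActivityThreshold-class
#' @export
setMethod("thresholdValue", "ActivityThreshold", function(x) x@threshold)

#' Genus-level abundance experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a genus x sample
#' count matrix in the `"counts"` assay with mandatory per-sample metadata
#' columns `donor`, `treatment` and `timepoint` in `colData`.
#'
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an assay named 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be non-negative integers")
    if (ncol(cnt) && any(colSums(cnt) <= 0))
      msg <- c(msg, "every sample must have a positive total count")
  }
  need <- c("donor", "treatment", "timepoint")
  have <- colnames(SummarizedExperiment::colData(object))
  miss <- setdiff(need, have)
  if (length(miss))
    msg <- c(msg, paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param counts non-negative integer matrix, genera in rows, samples in
#'   columns. Row and column names are kept (defaults are generated when
#'   absent).
#' @param sampleData data.frame with one row per sample and columns `donor`,
#'   `treatment` (e.g. "AG", "arabinose", "galactose", "NA") and `timepoint`
#'   (hours).
#'
#' @return An [AbundanceExperiment-class].
#' @examples
#' cnt <- matrix(c(5L, 5L, 2L, 8L), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))
#' )
#' meta <- data.frame(
#'   donor = c("D1", "D1"), treatment = c("AG", "NA"), timepoint = c(6, 6)
#' )
#' AbundanceExperiment(cnt, meta)
#' @export
AbundanceExperiment <- function(counts, sampleData) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("genus%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%02d", seq_len(ncol(counts)))
  sampleData <- S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = sampleData
  )
  new("AbundanceExperiment", se)
}

#' Isolate census
#'
#' Records of sorted-and-cultivated isolates (id, species, phylum, donor)
#' together with derived species/phylum counts and species fractions.
#'
#' @slot records data.frame with columns `isolate_id`, `species`, `phylum`,
#'   `donor`.
#' @slot speciesCounts named integer vector of isolates per species.
#' @slot phylumCounts named integer vector of isolates per phylum.
#' @slot speciesFractions named numeric vector, fractions of total (sums to 1).
#'
#' @export
setClass("IsolateCensus",
  representation(
    records = "data.frame",
    speciesCounts = "integer",
    phylumCounts = "integer",
    speciesFractions = "numeric"
  )
)

setValidity("IsolateCensus", function(object) {
  msg <- character()
  n <- nrow(object@records)
  if (n == 0L) msg <- c(msg, "records must be non-empty")
  if (sum(object@speciesCounts) != n)
    msg <- c(msg, "species counts must sum to the number of records")
  if (sum(object@phylumCounts) != n)
    msg <- c(msg, "phylum counts must sum to the number of records")
  if (abs(sum(object@speciesFractions) - 1) > 1e-9)
    msg <- c(msg, "species fractions must sum to 1")
  tab <- unique(object@records[, c("species", "phylum")])
  if (anyDuplicated(tab$species))
    msg <- c(msg, "each species must map to exactly one phylum")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IsolateCensus", function(object) {
  cat(sprintf(
    "IsolateCensus: %d isolates, %d species, %d phyla\n",
    nrow(object@records), length(object@speciesCounts),
    length(object@phylumCounts)
  ))
  ph <- sort(object@phylumCounts, decreasing = TRUE)
  cat("  phyla:", paste(sprintf("%s (%d)", names(ph), ph), collapse = ", "), "\n")
})

#' @describeIn IsolateCensus-class isolate records
#' @param x an `IsolateCensus`
#' @export
setGeneric("censusRecords", function(x) standardGeneric("censusRecords"))

#' @rdname IsolateCensus-class
#' @export
setMethod("censusRecords", "IsolateCensus", function(x) x@records)

#' @describeIn IsolateCensus-class named integer vector of isolates per species
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))

#' @rdname IsolateCensus-class
#' @export
setMethod("speciesCounts", "IsolateCensus", function(x) x@speciesCounts)

#' @describeIn IsolateCensus-class named integer vector of isolates per phylum
#' @export
setGeneric("phylumCounts", function(x) standardGeneric("phylumCounts"))

#' @rdname IsolateCensus-class
#' @export
setMethod("phylumCounts", "IsolateCensus", function(x) x@phylumCounts)

#' @describeIn IsolateCensus-class named numeric vector of species fractions
#' @export
setGeneric("speciesFractions", function(x) standardGeneric("speciesFractions"))

#' @rdname IsolateCensus-class
#' @export
setMethod("speciesFractions", "IsolateCensus", function(x) x@speciesFractions)
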