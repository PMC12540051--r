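# Plain-text readers and writers: two-column spectrum files with a TSV
# manifest, genus count tables with sample metadata, growth-curve and qPCR
# CSVs, census TSVs. Writers emit the formats the readers consume.

#' Read / write a single Raman spectrum
#'
#' Two-column delimited text: wavenumber (cm^-1) and intensity, one file per
#' cell. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param cellId,donor,condition,timepoint metadata attached on read
#'   (typically from the manifest).
#' @return [readSpectrum()] returns a [RamanSpectrum-class];
#'   [writeSpectrum()] returns `path` invisibly.
#' @export
readSpectrum <- function(path, cellId = basename(path), donor = NA_character_,
                         condition = NA_character_, timepoint = NA_real_) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("wavenumber", "intensity"))
  RamanSpectrum(df$wavenumber, df$intensity, cellId = cellId, donor = donor,
                condition = condition, timepoint = timepoint)
}

#' @param spectrum a [RamanSpectrum-class].
#' @rdname readSpectrum
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(wavenumbers(spectrum), intensities(spectrum)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read spectra listed in a manifest
#'
#' The manifest is a TSV with columns `file`, `cell_id`, `donor`, `condition`,
#' `timepoint`; `file` paths are resolved relative to the manifest's
#' directory.
#'
#' @param manifestPath path to the manifest TSV.
#' @return named list of [RamanSpectrum-class] objects (names = cell ids).
#' @export
readSpectrumManifest <- function(manifestPath) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE,
                           na.strings = "")
  need <- c("file", "cell_id", "donor", "condition", "timepoint")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dir <- dirname(manifestPath)
  sp <- lapply(seq_len(nrow(man)), function(i) {
    readSpectrum(file.path(dir, man$file[i]), cellId = man$cell_id[i],
                 donor = man$donor[i], condition = man$condition[i],
                 timepoint = man$timepoint[i])
  })
  stats::setNames(sp, man$cell_id)
}

#' Read / write a genus abundance table
#'
#' Counts TSV (rows = samples, columns = genera, first column = sample id)
#' plus a metadata TSV (columns `sample`, `donor`, `treatment`, `timepoint`).
#' The treatment label "NA" (no amendment) is preserved literally.
#'
#' @param countsPath,metaPath input TSV paths.
#' @return [readAbundanceTable()] returns an [AbundanceExperiment-class].
#' @export
readAbundanceTable <- function(countsPath, metaPath) {
  cnt <- utils::read.delim(countsPath, row.names = 1, check.names = FALSE,
                           na.strings = "")
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE,
                            na.strings = "", colClasses = c(
                              sample = "character", donor = "character",
                              treatment = "character", timepoint = "numeric"
                            ))
  if (!all(c("sample", "donor", "treatment", "timepoint") %in% names(meta)))
    stop("metadata must have columns sample, donor, treatment, timepoint")
  meta <- meta[match(rownames(cnt), meta$sample), ]
  if (anyNA(meta$sample))
    stop("metadata is missing rows for some samples in the counts table")
  AbundanceExperiment(
    t(as.matrix(cnt)),
    meta[, c("donor", "treatment", "timepoint")]
  )
}

#' @param x an [AbundanceExperiment-class].
#' @rdname readAbundanceTable
#' @export
writeAbundanceTable <- function(x, countsPath, metaPath) {
  cnt <- t(SummarizedExperiment::assay(x, "counts"))
  df <- data.frame(sample = rownames(cnt), cnt, check.names = FALSE)
  utils::write.table(df, countsPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- data.frame(sample = rownames(meta), meta)
  utils::write.table(meta, metaPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(countsPath)
}

#' Read long-format growth curves
#'
#' CSV with columns `time_h`, `strain`, `condition`, `replicate`, `od600`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readGrowthCurves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("time_h", "strain", "condition", "replicate", "od600")
  if (!all(need %in% names(df)))
    stop("growth CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a qPCR results table
#'
#' CSV with at least columns `copies` and `cq` for standards, or
#' `timepoint_h`, `replicate`, `cq` for samples.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readQpcr <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Read / write an isolate census table
#'
#' TSV with columns `isolate_id`, `species`, `phylum`, `donor`.
#'
#' @param path TSV path.
#' @return [readCensus()] returns a data.frame of records.
#' @export
readCensus <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("isolate_id", "species", "phylum")
  if (!all(need %in% names(df)))
    stop("census TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @param records data.frame of census records.
#' @rdname readCensus
#' @export
writeCensus <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
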