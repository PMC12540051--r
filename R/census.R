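# Isolate census arithmetic: species/phylum summaries of sorted-and-
# cultivated isolates and deterministic representative selection.

#' Summarise an isolate census
#'
#' Tabulates isolate records into per-species and per-phylum counts and
#' species fractions of the total.
#'
#' @param records data.frame with columns `isolate_id`, `species`, `phylum`
#'   (and optionally `donor`), one row per isolate; non-empty, with a phylum
#'   for every species.
#'
#' @return An [IsolateCensus-class].
#' @examples
#' census <- censusSummary(simulateIsolateCensus())
#' census
#' phylumCounts(census)
#' @export
censusSummary <- function(records) {
  stopifnot(all(c("isolate_id", "species", "phylum") %in% names(records)))
  if (nrow(records) == 0L) stop("records must be non-empty")
  missing <- is.na(records$phylum) | records$phylum == ""
  if (any(missing))
    stop(sprintf(
      "species with missing phylum: %s",
      paste(unique(records$species[missing]), collapse = ", ")
    ))
  tab <- unique(records[, c("species", "phylum")])
  if (anyDuplicated(tab$species))
    stop(sprintf(
      "species mapped to multiple phyla: %s",
      paste(tab$species[duplicated(tab$species)], collapse = ", ")
    ))
  if (!"donor" %in% names(records)) records$donor <- NA_character_
  spCounts <- table(records$species)
  phCounts <- table(records$phylum)
  sc <- stats::setNames(as.integer(spCounts), names(spCounts))
  pc <- stats::setNames(as.integer(phCounts), names(phCounts))
  new("IsolateCensus",
    records = records[, c("isolate_id", "species", "phylum", "donor")],
    speciesCounts = sc,
    phylumCounts = pc,
    speciesFractions = sc / sum(sc)
  )
}

#' Select one representative isolate per species
#'
#' Returns exactly one record per distinct species, the one with the
#' lexicographically lowest `isolate_id` — a deterministic tie-break so that
#' representative selection is reproducible across runs.
#'
#' @param records data.frame of isolate records (columns `isolate_id`,
#'   `species`, ...).
#' @return data.frame with one row per species, ordered by species.
#' @examples
#' nrow(selectRepresentatives(simulateIsolateCensus())) # 16
#' @export
selectRepresentatives <- function(records) {
  stopifnot(all(c("isolate_id", "species") %in% names(records)))
  records <- records[order(records$species, records$isolate_id), ]
  out <- records[!duplicated(records$species), ]
  rownames(out) <- NULL
  out
}
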