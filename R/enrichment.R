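# Community-level enrichment analysis: relative abundances, the enrichment
# factor EF = 2A/(A+B) - 1 with donor-matched pairing, z/Benjamini-Hochberg
# enrichment calls, Bray-Curtis dissimilarity, PERMANOVA (sequential
# sums-of-squares partitioning of a Gower-centred dissimilarity matrix) and
# principal-coordinates ordination.

#' Relative abundances
#'
#' Divides each sample's counts by its total. For an
#' [AbundanceExperiment-class] (genera x samples) columns sum to 1; for a
#' plain matrix rows are taken as samples and rows sum to 1.
#'
#' @param x an [AbundanceExperiment-class] or a samples x genera matrix of
#'   non-negative counts.
#' @return numeric matrix of proportions, same orientation as the input.
#' @examples
#' relativeAbundance(matrix(c(1, 2, 7), 1))
#' @export
relativeAbundance <- function(x) {
  if (is(x, "AbundanceExperiment")) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    return(sweep(cnt, 2, colSums(cnt), "/"))
  }
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  tot <- rowSums(x)
  if (any(tot <= 0)) stop("every sample must have a positive total")
  sweep(x, 1, tot, "/")
}

#' Enrichment factor
#'
#' `EF = 2A/(A + B) - 1` for treated (`a`) versus control (`b`) relative
#' abundances; bounded in `[-1, 1]`, 0 when the genus is equally abundant,
#' +1 when absent from the control only, -1 when absent from the treatment
#' only. The indeterminate case `a = b = 0` is defined as 0 (no evidence of
#' change, the only symmetric choice).
#'
#' @param a,b non-negative relative abundances (vectorised, recycled).
#' @return numeric vector of EF values in `[-1, 1]`.
#' @examples
#' enrichmentFactor(0.02, 0.04) # -1/3
#' @export
enrichmentFactor <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("relative abundances must be non-negative")
  s <- a + b
  ifelse(s > 0, 2 * a / ifelse(s > 0, s, 1) - 1, 0)
}

#' Per-genus, per-donor enrichment factors
#'
#' Computes EF for every genus within each donor, comparing the donor's
#' treated sample at `timepoint` against the donor-matched no-amendment
#' control at the same timepoint. When 0 h samples are present, each genus's
#' baseline relative abundance (mean control relative abundance at 0 h) is
#' attached for reporting (bubble sizing).
#'
#' @param x an [AbundanceExperiment-class].
#' @param treatment treated-condition label (e.g. "AG").
#' @param timepoint timepoint (hours) at which to compare.
#' @param control control label, default "NA" (no amendment).
#'
#' @return data.frame with columns `genus`, `donor`, `ef`, `baseline_ra`.
#' @export
efTable <- function(x, treatment, timepoint, control = "NA") {
  stopifnot(is(x, "AbundanceExperiment"))
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  ra <- relativeAbundance(x)
  donors <- unique(meta$donor)
  selT <- meta$treatment == treatment & meta$timepoint == timepoint
  selC <- meta$treatment == control & meta$timepoint == timepoint
  bad <- donors[vapply(donors, function(d) {
    sum(selT & meta$donor == d) != 1L || sum(selC & meta$donor == d) != 1L
  }, logical(1))]
  if (length(bad))
    stop(sprintf(
      "donor(s) without exactly one %s and one %s sample at %g h: %s",
      treatment, control, timepoint, paste(bad, collapse = ", ")
    ))
  base0 <- meta$treatment == control & meta$timepoint == 0
  baseRa <- if (any(base0)) rowMeans(ra[, base0, drop = FALSE]) else
    rep(NA_real_, nrow(ra))
  out <- do.call(rbind, lapply(donors, function(d) {
    aCol <- which(selT & meta$donor == d)
    bCol <- which(selC & meta$donor == d)
    data.frame(
      genus = rownames(ra), donor = d,
      ef = enrichmentFactor(ra[, aCol], ra[, bCol]),
      baseline_ra = baseRa,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, same length, in `[0, 1]`, each >= its raw value.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Call significantly enriched genera
#'
#' For each genus, a one-sample z statistic of its per-donor EF values against
#' zero (`z = mean / (SD / sqrt(n))`, sample SD floored at `sdFloor` so that
#' unanimous effects give a finite, extreme z), a two-sided normal p-value,
#' Benjamini-Hochberg adjustment across the genera of the stratum, and the
#' call `enriched = (mean EF > 0) & (p_adj < alpha)`.
#'
#' @param efs data.frame from [efTable()] (columns `genus`, `donor`, `ef`,
#'   optionally `baseline_ra`).
#' @param alpha FDR level, default 0.05.
#' @param sdFloor lower bound on the EF standard deviation, default 1e-8.
#'
#' @return data.frame with one row per genus: `genus`, `n_donors`, `mean_ef`,
#'   `z`, `p`, `p_adj`, `enriched`, `baseline_ra`.
#' @export
callEnrichment <- function(efs, alpha = 0.05, sdFloor = 1e-8) {
  stopifnot(all(c("genus", "donor", "ef") %in% names(efs)))
  sp <- split(efs, efs$genus)
  nmin <- min(vapply(sp, nrow, integer(1)))
  if (nmin < 2L)
    stop("at least 2 donors per genus are required for the z statistic")
  rows <- lapply(sp, function(g) {
    n <- nrow(g)
    m <- mean(g$ef)
    s <- max(stats::sd(g$ef), sdFloor)
    z <- m / (s / sqrt(n))
    data.frame(
      genus = g$genus[1], n_donors = n, mean_ef = m, z = z,
      p = 2 * stats::pnorm(-abs(z)),
      baseline_ra = if ("baseline_ra" %in% names(g)) mean(g$baseline_ra)
        else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- benjaminiHochberg(out$p)
  out$enriched <- out$mean_ef > 0 & out$p_adj < alpha
  out[, c("genus", "n_donors", "mean_ef", "z", "p", "p_adj", "enriched",
          "baseline_ra")]
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x - y|) / sum(x + y)`; in `[0, 1]` for non-negative inputs, 0 for
#' identical samples, 1 for disjoint supports.
#'
#' @param x,y non-negative numeric vectors of equal length, not both all-zero.
#' @return numeric(1).
#' @examples
#' brayCurtis(c(2, 1), c(1, 1)) # 0.2
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("inputs must be non-negative")
  tot <- sum(x + y)
  if (tot <= 0) stop("inputs must not both be all-zero")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' All pairwise Bray-Curtis dissimilarities (via [vegan::vegdist()]).
#'
#' @param x samples x features non-negative matrix (e.g. the transpose of
#'   [relativeAbundance()] output for an [AbundanceExperiment-class]).
#' @return a `dist` object.
#' @export
brayCurtisMatrix <- function(x) {
  vegan::vegdist(as.matrix(x), method = "bray")
}

.gowerCenter <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a dissimilarity matrix by metadata terms using sequential
#' (Type I) sums of squares on the Gower-centred inner-product matrix, with
#' pseudo-F statistics and p-values from free (unrestricted) permutations of
#' the samples: `p = (1 + #(F_perm >= F_obs)) / (1 + nPerm)`.
#'
#' @param d a `dist` or square symmetric zero-diagonal matrix of
#'   dissimilarities.
#' @param meta data.frame of per-sample metadata, rows matching the order of
#'   `d`.
#' @param terms character vector of metadata columns, entered sequentially
#'   (e.g. `c("donor", "treatment")`).
#' @param nPerm number of permutations (>= 99), default 999.
#' @param seed integer seed or `NULL`.
#'
#' @return data.frame with one row per term plus `Residual` and `Total`:
#'   columns `term`, `df`, `sum_sq`, `r2`, `pseudo_f`, `p`; attribute
#'   `n_perm`.
#' @export
permanova <- function(d, meta, terms, nPerm = 999, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (ncol(m) != n || any(abs(m - t(m)) > 1e-8) || any(abs(diag(m)) > 1e-12))
    stop("d must be a square symmetric zero-diagonal dissimilarity matrix")
  if (nrow(meta) != n) stop("meta must have one row per sample")
  if (!all(terms %in% names(meta)))
    stop("all terms must be metadata columns")
  if (nPerm < 99) stop("nPerm must be >= 99")
  for (tm in terms) {
    if (length(unique(meta[[tm]])) < 2L)
      stop(sprintf("term '%s' has a single level", tm))
    meta[[tm]] <- factor(meta[[tm]])
  }
  G <- .gowerCenter(m)
  ssTotal <- sum(diag(G))
  # cumulative hat matrices: intercept, then + each term in order
  hats <- list(matrix(1 / n, n, n))
  ranks <- 1L
  for (k in seq_along(terms)) {
    X <- stats::model.matrix(
      stats::reformulate(terms[seq_len(k)]), data = meta
    )
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k + 1L]] <- tcrossprod(Q)
    ranks[k + 1L] <- q$rank
  }
  dfTerm <- diff(ranks)
  dfRes <- n - ranks[length(ranks)]
  if (dfRes <= 0) stop("no residual degrees of freedom")
  trHG <- function(G) vapply(hats, function(H) sum(H * G), numeric(1))
  fStats <- function(G) {
    tr <- trHG(G)
    ssSeq <- diff(tr)
    ssRes <- sum(diag(G)) - tr[length(tr)]
    (ssSeq / dfTerm) / (ssRes / dfRes)
  }
  tr <- trHG(G)
  ssSeq <- diff(tr)
  ssRes <- ssTotal - tr[length(tr)]
  fObs <- (ssSeq / dfTerm) / (ssRes / dfRes)
  exceed <- integer(length(terms))
  .maybeSeed(seed, {
    for (i in seq_len(nPerm)) {
      perm <- sample.int(n)
      fp <- fStats(G[perm, perm])
      exceed <- exceed + (fp >= fObs)
    }
  })
  p <- (1 + exceed) / (1 + nPerm)
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfTerm, dfRes, n - 1L),
    sum_sq = c(ssSeq, ssRes, ssTotal),
    r2 = c(ssSeq, ssRes, ssTotal) / ssTotal,
    pseudo_f = c(fObs, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- nPerm
  out
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix (double-centring +
#' eigendecomposition via [stats::cmdscale()]); axes with non-positive
#' eigenvalues are dropped. For Euclidean-embeddable matrices the coordinates
#' reproduce the input distances.
#'
#' @param d a `dist` or square symmetric dissimilarity matrix.
#' @return list with `points` (samples x positive axes), `eig` (all
#'   eigenvalues) and `rel_eig` (eigenvalues over the sum of positive
#'   eigenvalues).
#' @export
pcoaOrdination <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(m, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-8 * max(abs(eig), 1e-12)
  keep <- which(eig > tol)
  nAxes <- min(ncol(fit$points), length(keep))
  pts <- if (nAxes > 0) fit$points[, seq_len(nAxes), drop = FALSE] else
    matrix(0, n, 0)
  rownames(pts) <- rownames(m)
  colnames(pts) <- if (ncol(pts)) paste0("PCo", seq_len(ncol(pts))) else
    character()
  list(
    points = pts, eig = eig,
    rel_eig = if (any(eig > 0)) eig / sum(eig[eig > 0]) else eig
  )
}
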