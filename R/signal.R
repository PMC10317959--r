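# Region-signal quantification: binned occupancy matrices with percentile
# clipping and 0-1 scaling, two-cluster partitioning, fixed-window coverage
# and log-scale rank correlation.

.trackCoverage <- function(track) {
  if (!"score" %in% colnames(S4Vectors::mcols(track)))
    stop("track must carry a 'score' metadata column")
  GenomicRanges::coverage(track, weight = "score")
}

#' Bin signal in a fixed window around summits
#'
#' Divides a window of \code{2 * halfWindow} bp centered on each summit into
#' \code{nBins} equal bins and records the mean per-base signal in each.
#' Regions whose window exceeds the bounds of the track are dropped with a
#' warning.
#'
#' @param track a \link[GenomicRanges]{GRanges} with a \code{score} column
#'   (per-base signal, bedGraph-style intervals).
#' @param summits a \link[GenomicRanges]{GRanges} of summit positions (width
#'   1, or the midpoint is used); names (or a \code{union_id} column) label
#'   the regions.
#' @param halfWindow half-width of the window in bp.
#' @param nBins number of bins; must divide \code{2 * halfWindow}.
#' @return a \linkS4class{BinnedSignal} in the \code{raw} state.
#' @export
binSignal <- function(track, summits, halfWindow = 2000, nBins = 100) {
  width <- 2 * halfWindow
  if (width %% nBins != 0)
    stop("nBins must divide the window width (", width, " bp)")
  binWidth <- width %/% nBins
  cov <- .trackCoverage(track)
  centers <- floor((GenomicRanges::start(summits) + GenomicRanges::end(summits)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(summits))
  ids <- if (!is.null(names(summits))) names(summits)
         else if ("union_id" %in% colnames(S4Vectors::mcols(summits)))
           summits$union_id
         else sprintf("region_%05d", seq_along(summits))
  from <- centers - halfWindow
  to <- centers + halfWindow - 1
  keep <- logical(length(summits))
  for (i in seq_along(summits)) {
    keep[i] <- chrom[i] %in% names(cov) && from[i] >= 1 &&
      to[i] <= length(cov[[chrom[i]]])
  }
  if (!all(keep))
    warning(sum(!keep), " region(s) exceed the track bounds and were dropped")
  if (!any(keep)) stop("no region lies within the track bounds")
  vals <- matrix(NA_real_, sum(keep), nBins)
  ki <- which(keep)
  for (j in seq_along(ki)) {
    i <- ki[j]
    v <- as.numeric(S4Vectors::window(cov[[chrom[i]]], from[i], to[i]))
    vals[j, ] <- colMeans(matrix(v, nrow = binWidth))
  }
  rownames(vals) <- ids[keep]
  new("BinnedSignal", regions = as.character(ids[keep]), values = vals,
      halfWindow = halfWindow, nBins = nBins, state = "raw",
      clip = numeric(0))
}

#' Percentile-clip and 0-1 scale a binned signal matrix
#'
#' Values above the \code{hiPct} percentile (computed over all bins of the
#' matrix pooled, linear-interpolation definition) are set to that
#' percentile, values below the \code{loPct} percentile to that percentile,
#' and the matrix is then min-max scaled to [0, 1].
#'
#' @param x a \linkS4class{BinnedSignal} in the \code{raw} state.
#' @param hiPct,loPct clip percentiles (in percent).
#' @return a \linkS4class{BinnedSignal} in the \code{scaled} state; the clip
#'   levels (raw scale) are kept in the \code{clip} slot. A constant matrix
#'   scales to all zeros with a warning.
#' @export
clipScale <- function(x, hiPct = 98, loPct = 1) {
  stopifnot(is(x, "BinnedSignal"))
  if (x@state != "raw") stop("matrix is already ", x@state)
  v <- x@values
  hi <- unname(quantile(v, hiPct / 100, type = 7))
  lo <- unname(quantile(v, loPct / 100, type = 7))
  v[v > hi] <- hi
  v[v < lo] <- lo
  rng <- max(v) - min(v)
  if (rng == 0) {
    warning("constant matrix: scaled values set to 0")
    v[] <- 0
  } else {
    v <- (v - min(v)) / rng
  }
  new("BinnedSignal", regions = x@regions, values = v,
      halfWindow = x@halfWindow, nBins = x@nBins, state = "scaled",
      clip = c(lo, hi))
}

#' Two-cluster partitioning of regions by multi-track signal
#'
#' Concatenates the scaled per-region bin vectors of the selected tracks and
#' partitions the regions with k-means (fixed seed, Lloyd's algorithm,
#' multiple restarts). Within each cluster, regions are ordered by the total
#' signal of a designated ranking track, descending.
#'
#' @param matrices named list of \linkS4class{BinnedSignal} objects in the
#'   \code{scaled} state, sharing region order.
#' @param k number of clusters.
#' @param seed seed for the k-means restarts.
#' @param nstart number of restarts.
#' @param rankTrack name or index of the track used for within-cluster
#'   ordering.
#' @return a data.frame in display order: \code{region}, \code{cluster},
#'   \code{rank_signal}.
#' @export
clusterRegions <- function(matrices, k = 2, seed = 7, nstart = 10,
                           rankTrack = 1) {
  stopifnot(length(matrices) >= 1)
  regs <- signalRegions(matrices[[1]])
  for (m in matrices) {
    if (signalState(m) != "scaled") stop("all matrices must be scaled")
    if (!identical(signalRegions(m), regs)) stop("tracks must share region order")
  }
  if (length(regs) < k) stop("fewer regions than clusters")
  X <- do.call(cbind, lapply(matrices, signalValues))
  set.seed(seed)
  km <- suppressWarnings(kmeans(X, centers = k, nstart = nstart,
                                iter.max = 200, algorithm = "Lloyd"))
  ranks <- rowSums(signalValues(matrices[[rankTrack]]))
  out <- data.frame(region = regs, cluster = km$cluster,
                    rank_signal = unname(ranks), stringsAsFactors = FALSE)
  out[order(out$cluster, -out$rank_signal), , drop = FALSE]
}

#' Mean signal coverage in a fixed window around region centers
#'
#' For each region and track, the mean per-base signal in
#' \code{[center - halfwidth, center + halfwidth)} (a window of
#' \code{2 * halfwidth} bp).
#'
#' @param regions a \link[GenomicRanges]{GRanges}; the window is centered on
#'   each region's midpoint.
#' @param tracks a named list of score-carrying
#'   \link[GenomicRanges]{GRanges} tracks (a single GRanges is accepted).
#' @param halfwidth window half-width in bp (> 0).
#' @return a numeric matrix, regions x tracks.
#' @export
coverageAt <- function(regions, tracks, halfwidth = 250) {
  if (halfwidth <= 0) stop("halfwidth must be > 0 (empty window)")
  if (is(tracks, "GRanges")) tracks <- list(track = tracks)
  centers <- floor((GenomicRanges::start(regions) + GenomicRanges::end(regions)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  ids <- if (!is.null(names(regions))) names(regions)
         else if ("union_id" %in% colnames(S4Vectors::mcols(regions)))
           regions$union_id
         else sprintf("region_%05d", seq_along(regions))
  out <- matrix(NA_real_, length(regions), length(tracks),
                dimnames = list(ids, names(tracks)))
  for (tn in seq_along(tracks)) {
    cov <- .trackCoverage(tracks[[tn]])
    for (i in seq_along(regions)) {
      if (!chrom[i] %in% names(cov))
        stop("region center outside track bounds: ", ids[i])
      from <- centers[i] - halfwidth
      to <- centers[i] + halfwidth - 1
      cv <- cov[[chrom[i]]]
      if (from < 1 || to > length(cv))
        stop("region center outside track bounds: ", ids[i])
      out[i, tn] <- mean(S4Vectors::window(cv, from, to))
    }
  }
  out
}

#' Pairwise Spearman correlation of log-transformed coverage
#'
#' Computes the Spearman rank correlation of \code{log(coverage + c)}
#' between all pairs of tracks. The pseudocount \code{c} defaults to the
#' smallest nonzero entry of the table. Constant tracks have undefined
#' ranks; their correlations are \code{NA} and a warning is raised.
#'
#' @param coverage region x track matrix from \code{\link{coverageAt}}.
#' @param pseudocount added before the log; default: smallest nonzero entry
#'   (0 if there are no zeros).
#' @return symmetric track x track correlation matrix with unit diagonal.
#' @export
logRankCorrelation <- function(coverage, pseudocount = NULL) {
  if (ncol(coverage) < 2) stop("need at least 2 tracks")
  if (is.null(pseudocount))
    pseudocount <- if (any(coverage == 0)) min(coverage[coverage > 0]) else 0
  lx <- log(coverage + pseudocount)
  const <- apply(lx, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant track(s): ", paste(colnames(coverage)[const], collapse = ", "))
  cc <- suppressWarnings(cor(lx, method = "spearman"))
  diag(cc) <- 1
  cc
}
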