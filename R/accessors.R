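# Accessors, constructors and show methods for the core classes.

#' Create a simulation configuration
#'
#' Constructor for \linkS4class{ScreenSimConfig}. Defaults describe the study
#' conditions the rest of the package assumes: four cell models (two per
#' lineage), two replicates, harvests at days 0/8/15/22, an expected depth of
#' 1000 reads per guide, NB dispersion 0.05, control-pool sizes matching a
#' full-scale tiling library, and planted fitness effects drawn
#' Uniform(-0.20, -0.05) for experimental hits and Uniform(-0.25, -0.10) for
#' pan-lethal controls.
#'
#' @param nRegions,guidesPerRegion,cellLines,lineages,replicates,timepoints
#'   see \linkS4class{ScreenSimConfig}.
#' @param depth,dispersion,depthSd,shareDay0 count-model parameters.
#' @param fracCommon,fracLineage planted hit fractions.
#' @param alphaHit,alphaPanLethal,alphaControl true fitness-score ranges.
#' @param nNT,nPL,nHS,nYT control-pool sizes.
#' @param kneeNeglogFdr,sigFraction,bgMean,bgSd,sigSd peak significance
#'   mixture parameters.
#' @param sharedFraction fraction of regions shared by all cell lines.
#' @param seed integer seed.
#' @return a validated \linkS4class{ScreenSimConfig}.
#' @examples
#' cfg <- screenSimConfig(nRegions = 50, seed = 1)
#' cfg
#' @export
screenSimConfig <- function(nRegions = 500, guidesPerRegion = 10,
    cellLines = c("meso1", "meso2", "uveal1", "uveal2"),
    lineages = c("meso", "meso", "uveal", "uveal"),
    replicates = 2, timepoints = c(0, 8, 15, 22),
    depth = 1000, dispersion = 0.05, depthSd = 0.1, shareDay0 = TRUE,
    fracCommon = 0.2, fracLineage = 0.15,
    alphaHit = c(-0.20, -0.05), alphaPanLethal = c(-0.25, -0.10),
    alphaControl = c(-0.15, -0.05),
    nNT = 496, nPL = 1030, nHS = 419, nYT = 605,
    kneeNeglogFdr = 50, sigFraction = 0.25,
    bgMean = 10, bgSd = 3, sigSd = 4,
    sharedFraction = 0.6, seed = 1) {
  new("ScreenSimConfig", nRegions = nRegions, guidesPerRegion = guidesPerRegion,
      cellLines = cellLines, lineages = lineages, replicates = replicates,
      timepoints = timepoints, depth = depth, dispersion = dispersion,
      depthSd = depthSd, shareDay0 = shareDay0,
      fracCommon = fracCommon, fracLineage = fracLineage,
      alphaHit = alphaHit, alphaPanLethal = alphaPanLethal,
      alphaControl = alphaControl,
      nNT = nNT, nPL = nPL, nHS = nHS, nYT = nYT,
      kneeNeglogFdr = kneeNeglogFdr, sigFraction = sigFraction,
      bgMean = bgMean, bgSd = bgSd, sigSd = sigSd,
      sharedFraction = sharedFraction, seed = seed)
}

setMethod("show", "ScreenSimConfig", function(object) {
  cat("ScreenSimConfig\n")
  cat("  regions:", object@nRegions, " guides/region:", object@guidesPerRegion, "\n")
  cat("  cell lines:", paste(object@cellLines, collapse = ", "),
      " (lineages:", paste(unique(object@lineages), collapse = "/"), ")\n")
  cat("  replicates:", object@replicates,
      " timepoints:", paste(object@timepoints, collapse = ","), "\n")
  cat("  depth:", object@depth, " dispersion:", object@dispersion,
      " seed:", object@seed, "\n")
})

#' Construct a GuideLibrary
#'
#' @param entries a data.frame or DataFrame with the library columns (see
#'   \linkS4class{GuideLibrary}).
#' @return a validated \linkS4class{GuideLibrary}.
#' @export
GuideLibrary <- function(entries) {
  e <- as(entries, "DataFrame")
  for (col in setdiff(.libraryColumns, colnames(e))) e[[col]] <- NA
  new("GuideLibrary", entries = e[, .libraryColumns])
}

#' @rdname GuideLibrary-class
#' @export
setMethod("guideInfo", "GuideLibrary", function(x) x@entries)

#' @rdname GuideLibrary-class
#' @export
setMethod("poolSizes", "GuideLibrary", function(x) table(x@entries$pool))

#' @rdname GuideLibrary-class
#' @export
setMethod("nGuides", "GuideLibrary", function(x) nrow(x@entries))

setMethod("show", "GuideLibrary", function(object) {
  e <- object@entries
  cat("GuideLibrary with", nrow(e), "guides\n")
  if (nrow(e)) {
    ps <- poolSizes(object)
    cat("  pools:", paste(names(ps), ps, sep = "=", collapse = ", "), "\n")
    nexp <- sum(is.na(e$control_class))
    cat("  experimental:", nexp, "guides over",
        length(unique(e$union_id[is.na(e$control_class)])), "regions\n")
  }
})

#' Construct a ScreenExperiment
#'
#' @param counts guide x sample matrix (integer counts, or real values after
#'   normalization); rownames are guide ids.
#' @param cellLine,replicate,day per-sample metadata vectors.
#' @param lineage optional per-sample lineage labels.
#' @return a \linkS4class{ScreenExperiment}.
#' @export
ScreenExperiment <- function(counts, cellLine, replicate, day, lineage = NULL) {
  cd <- S4Vectors::DataFrame(cell_line = cellLine, replicate = replicate, day = day)
  if (!is.null(lineage)) cd$lineage <- lineage
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("ScreenExperiment", se)
}

setMethod("show", "ScreenExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ScreenExperiment:", nrow(object), "guides x", ncol(object), "samples\n")
  cat("  cell lines:", paste(unique(cd$cell_line), collapse = ", "), "\n")
  cat("  days:", paste(sort(unique(cd$day)), collapse = ","),
      " replicates:", length(unique(cd$replicate)), "\n")
})

#' @rdname BinnedSignal-class
#' @export
setMethod("signalValues", "BinnedSignal", function(x) x@values)

#' @rdname BinnedSignal-class
#' @export
setMethod("signalState", "BinnedSignal", function(x) x@state)

#' @rdname BinnedSignal-class
#' @export
setMethod("signalRegions", "BinnedSignal", function(x) x@regions)

setMethod("show", "BinnedSignal", function(object) {
  cat("BinnedSignal:", nrow(object@values), "regions x", object@nBins,
      "bins (", 2 * object@halfWindow / object@nBins, "bp each )\n")
  cat("  window: +/-", object@halfWindow, "bp; state:", object@state, "\n")
})
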