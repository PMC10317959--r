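#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Simulation configuration for synthetic tiling screens
#'
#' Holds every tunable of the synthetic-data generator: the layout of the
#' simulated peak sets, the negative-binomial noise model of the guide count
#' matrices, the planted fitness-effect distributions, and the seed that
#' fully determines all outputs.
#'
#' @slot nRegions number of regulatory regions to simulate.
#' @slot guidesPerRegion target number of sgRNAs per region.
#' @slot cellLines names of the simulated cell models.
#' @slot lineages lineage label per cell model (parallel to \code{cellLines});
#'   the default is two models per lineage.
#' @slot replicates number of infection replicates.
#' @slot timepoints harvest days; must be sorted and include day 0.
#' @slot depth expected reads per guide at day 0.
#' @slot dispersion negative-binomial overdispersion; the count variance is
#'   \code{mu + mu^2 * dispersion}.
#' @slot depthSd log-normal sd of the per-sample depth factor (0 = equal depth).
#' @slot shareDay0 logical; if TRUE the day-0 draw of each replicate (the
#'   library representation of one infected pool) is shared across cell lines.
#' @slot fracCommon,fracLineage fraction of library regions planted as common
#'   hits and as hits of each single lineage.
#' @slot alphaHit,alphaPanLethal,alphaControl ranges (min, max) of the true
#'   per-day fitness score for experimental hits, pan-lethal controls, and
#'   pathway/target-gene controls.
#' @slot nNT,nPL,nHS,nYT sizes of the non-targeting, pan-lethal,
#'   pathway and target-gene control pools.
#' @slot kneeNeglogFdr planted location (on the -log10 FDR scale) of the knee
#'   of the peak significance ECDF.
#' @slot sigFraction fraction of peaks in the high-significance mixture
#'   component.
#' @slot bgMean,bgSd,sigSd parameters of the two -log10 FDR mixture components.
#' @slot sharedFraction fraction of regions whose peaks are present, with
#'   identical intervals, in every cell line.
#' @slot seed integer seed; identical configurations give identical output.
#' @export
setClass("ScreenSimConfig",
  representation(
    nRegions = "numeric", guidesPerRegion = "numeric",
    cellLines = "character", lineages = "character",
    replicates = "numeric", timepoints = "numeric",
    depth = "numeric", dispersion = "numeric", depthSd = "numeric",
    shareDay0 = "logical",
    fracCommon = "numeric", fracLineage = "numeric",
    alphaHit = "numeric", alphaPanLethal = "numeric", alphaControl = "numeric",
    nNT = "numeric", nPL = "numeric", nHS = "numeric", nYT = "numeric",
    kneeNeglogFdr = "numeric", sigFraction = "numeric",
    bgMean = "numeric", bgSd = "numeric", sigSd = "numeric",
    sharedFraction = "numeric", seed = "numeric"
  )
)

setValidity("ScreenSimConfig", function(object) {
  msg <- character()
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  tp <- object@timepoints
  if (is.unsorted(tp, strictly = TRUE)) msg <- c(msg, "timepoints must be sorted ascending")
  if (tp[1] != 0) msg <- c(msg, "timepoints must include day 0 first")
  if (length(object@cellLines) != length(object@lineages))
    msg <- c(msg, "cellLines and lineages must have the same length")
  if (anyDuplicated(object@cellLines)) msg <- c(msg, "cellLines must be unique")
  if (object@fracCommon + 2 * object@fracLineage > 1)
    msg <- c(msg, "fracCommon + 2*fracLineage must be <= 1")
  for (nm in c("alphaHit", "alphaPanLethal", "alphaControl")) {
    r <- slot(object, nm)
    if (length(r) != 2 || r[1] > r[2]) msg <- c(msg, paste(nm, "must be a (min, max) range"))
  }
  if (object@sharedFraction < 0 || object@sharedFraction > 1)
    msg <- c(msg, "sharedFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Designed sgRNA library
#'
#' Container for a designed tiling library: one row per guide, with the
#' 20-nt protospacer, strand, target position (PAM-proximal cut site),
#' consensus region assignment (\code{union_id}) and pool / control-class
#' labels. Experimental guides map to exactly one consensus region; control
#' guides carry a control class (NT, PL, HS, YT) instead.
#'
#' @slot entries a \linkS4class{DataFrame} with columns \code{guide_id},
#'   \code{protospacer}, \code{strand}, \code{chrom}, \code{target_pos},
#'   \code{union_id}, \code{distance_to_summit}, \code{pool},
#'   \code{control_class}.
#' @export
setClass("GuideLibrary", representation(entries = "DataFrame"))

.libraryColumns <- c("guide_id", "protospacer", "strand", "chrom", "target_pos",
                     "union_id", "distance_to_summit", "pool", "control_class")

setValidity("GuideLibrary", function(object) {
  e <- object@entries
  msg <- character()
  miss <- setdiff(.libraryColumns, colnames(e))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  ps <- e$protospacer
  bad <- !is.na(ps) & nchar(ps) != 20L
  if (any(bad)) msg <- c(msg, "all protospacers must be exactly 20 nt")
  if (nrow(e)) {
    dup <- unsplit(lapply(split(as.character(ps), e$pool), duplicated), e$pool)
    if (any(dup & !is.na(ps))) msg <- c(msg, "duplicate protospacer within a pool")
  }
  exper <- is.na(e$control_class)
  if (any(exper & is.na(e$union_id)))
    msg <- c(msg, "every experimental guide must map to a union_id")
  if (anyDuplicated(e$guide_id)) msg <- c(msg, "guide_id must be unique")
  if (length(msg)) msg else TRUE
})

#' Screen count matrix
#'
#' A \linkS4class{SummarizedExperiment} of guide-level screen counts with
#' sample metadata columns \code{cell_line}, \code{replicate}, \code{day}
#' (and optionally \code{lineage}). Day-0 samples must be present for every
#' cell line. The first assay is named \code{counts}; after normalization it
#' holds real values.
#'
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  need <- c("cell_line", "replicate", "day")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) return(paste("colData must contain:", paste(miss, collapse = ", ")))
  a <- SummarizedExperiment::assay(object)
  if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  for (cl in unique(cd$cell_line))
    if (!any(cd$day[cd$cell_line == cl] == 0))
      msg <- c(msg, paste0("cell line '", cl, "' has no day-0 sample"))
  if (length(msg)) msg else TRUE
})

#' Binned occupancy matrix around region summits
#'
#' Region-by-bin matrix of mean per-base signal in equal bins of a fixed
#' window centered on region summits, together with its normalization state
#' (\code{raw}, or \code{scaled} after percentile clipping and 0-1 scaling).
#'
#' @slot regions region identifiers (row order of \code{values}).
#' @slot values numeric matrix, regions x bins.
#' @slot halfWindow half-width of the window in bp.
#' @slot nBins number of bins.
#' @slot state one of \code{"raw"}, \code{"scaled"}.
#' @slot clip clip levels used (length 0 before scaling, length 2 after:
#'   low and high percentile values on the raw scale).
#' @export
setClass("BinnedSignal",
  representation(regions = "character", values = "matrix",
                 halfWindow = "numeric", nBins = "numeric",
                 state = "character", clip = "numeric"))

setValidity("BinnedSignal", function(object) {
  msg <- character()
  if (!object@state %in% c("raw", "scaled")) msg <- c(msg, "state must be raw or scaled")
  if (ncol(object@values) != object@nBins) msg <- c(msg, "values must have nBins columns")
  if (nrow(object@values) != length(object@regions))
    msg <- c(msg, "regions must match rows of values")
  if ((2 * object@halfWindow) %% object@nBins != 0)
    msg <- c(msg, "nBins must divide the window width")
  if (object@state == "scaled") {
    v <- object@values
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "scaled values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
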