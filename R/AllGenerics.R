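#' @rdname GuideLibrary-class
#' @param x a \linkS4class{GuideLibrary}.
#' @export
setGeneric("guideInfo", function(x) standardGeneric("guideInfo"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("poolSizes", function(x) standardGeneric("poolSizes"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("nGuides", function(x) standardGeneric("nGuides"))

#' @rdname BinnedSignal-class
#' @param x a \linkS4class{BinnedSignal}.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname BinnedSignal-class
#' @export
setGeneric("signalState", function(x) standardGeneric("signalState"))

#' @rdname BinnedSignal-class
#' @export
setGeneric("signalRegions", function(x) standardGeneric("signalRegions"))
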