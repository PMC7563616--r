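#' @include AllClasses.R
NULL

#' @export
setGeneric("leftAnchors", function(x) standardGeneric("leftAnchors"))
#' @export
setGeneric("rightAnchors", function(x) standardGeneric("rightAnchors"))
#' @export
setGeneric("loopIds", function(x) standardGeneric("loopIds"))
#' @export
setGeneric("loopLength", function(x) standardGeneric("loopLength"))
#' @export
setGeneric("anchorDistance", function(x) standardGeneric("anchorDistance"))
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @export
setGeneric("loopLabels", function(x) standardGeneric("loopLabels"))
#' @export
setGeneric("trackName", function(x) standardGeneric("trackName"))
#' @export
setGeneric("trackReads", function(x) standardGeneric("trackReads"))
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))
#' @export
setGeneric("featureImportance", function(model, ...)
    standardGeneric("featureImportance"))
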