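#' @import methods
NULL

#' @rdname CallSet-class
#' @export
setGeneric("variants", function(x, ...) standardGeneric("variants"))

#' @rdname CallSet-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname CallSet-class
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))

#' @rdname CallSet-class
#' @export
setGeneric("callerClass", function(x) standardGeneric("callerClass"))

#' @rdname CallSet-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname PairedComparison-class
#' @export
setGeneric("sharedVariants", function(x) standardGeneric("sharedVariants"))

#' @rdname PairedComparison-class
#' @export
setGeneric("smearUnique", function(x) standardGeneric("smearUnique"))

#' @rdname PairedComparison-class
#' @export
setGeneric("bmcUnique", function(x) standardGeneric("bmcUnique"))

#' @rdname PanelOfNormals-class
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))

#' @rdname FilterReport-class
#' @export
setGeneric("filterStages", function(x) standardGeneric("filterStages"))

#' @rdname BoundaryEstimate-class
#' @export
setGeneric("noiseBoundary", function(x) standardGeneric("noiseBoundary"))

#' @rdname BoundaryEstimate-class
#' @export
setGeneric("enrichmentRatios", function(x) standardGeneric("enrichmentRatios"))
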