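#' @import methods
NULL

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(x, ...) standardGeneric("logTransform"))

#' @rdname stratifiedSplit
#' @export
setGeneric("stratifiedSplit", function(x, trainFraction = 0.7, seed = 1L, ...)
    standardGeneric("stratifiedSplit"))

#' @rdname scaleState
#' @export
setGeneric("scaleState", function(x) standardGeneric("scaleState"))

#' @rdname abundanceValues
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname groupLabels
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname extractBackbone
#' @export
setGeneric("extractBackbone", function(network, alphaCutoff = 0.3, ...)
    standardGeneric("extractBackbone"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname exportGraphML
#' @export
setGeneric("exportGraphML", function(x, path, ...) standardGeneric("exportGraphML"))

#' @rdname edges
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname nodes
#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @rdname centralities
#' @export
setGeneric("centralities", function(backbone, ...) standardGeneric("centralities"))
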