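#' @rdname networkAccessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkAccessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkAccessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname networkAccessors
#' @export
setGeneric("controlNodes", function(x) standardGeneric("controlNodes"))

#' @rdname networkAccessors
#' @export
setGeneric("endpointNodes", function(x) standardGeneric("endpointNodes"))

#' @rdname networkAccessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname scanAccessors
#' @export
setGeneric("ssMatrix", function(x) standardGeneric("ssMatrix"))

#' @rdname scanAccessors
#' @export
setGeneric("stateLevels", function(x) standardGeneric("stateLevels"))
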