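#' Steady-state record accessors
#'
#' @param x a [SteadyStateRecord].
#' @return `ssValues`: named numeric vector of steady-state activities;
#'   `isConverged`: logical; `ssResidual`: `max |dx/dt|` at termination;
#'   `ssAssignment`: the basal-activity assignment that produced it.
#' @name recordAccessors
NULL

#' @rdname recordAccessors
#' @export
ssValues <- function(x) x@ss

#' @rdname recordAccessors
#' @export
isConverged <- function(x) x@converged

#' @rdname recordAccessors
#' @export
ssResidual <- function(x) x@residual

#' @rdname recordAccessors
#' @export
ssAssignment <- function(x) x@assignment

setMethod("show", "SteadyStateRecord", function(object) {
  cat("SteadyStateRecord:", length(object@ss), "nodes;",
      if (object@converged) "converged" else "NOT converged",
      sprintf("(residual %.3g)\n", object@residual))
  print(round(object@ss, 6))
})
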