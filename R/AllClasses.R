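#' @import methods
#' @importFrom stats quantile setNames
#' @importFrom utils head tail write.table read.delim packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Signed signalling network
#'
#' An S4 container for a directed signed network: a node table carrying each
#' node's basal ("independent") activity levels and endpoint flag, and an
#' edge table of activating/inhibiting interactions.
#'
#' @slot nodes `data.frame` with columns `name` (character, unique),
#'   `beta_low` and `beta_high` (positive basal activities, arbitrary
#'   relative units, `beta_high > beta_low`), `is_endpoint` (logical;
#'   endpoints are readout nodes, never control nodes).
#' @slot edges `data.frame` with columns `source`, `target` (node names),
#'   `sign` (`"activating"` or `"inhibiting"`) and `weight` (positive
#'   dimensionless gain, default 1).
#' @slot metadata free-form provenance `list`.
#'
#' @seealso [signedNetwork()], [npmAlkNetwork()], [validateNetwork()]
#' @export
setClass("SignedNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 metadata = "list"),
  prototype(nodes = data.frame(), edges = data.frame(), metadata = list()))

setValidity("SignedNetwork", function(object) {
  msg <- character()
  need_n <- c("name", "beta_low", "beta_high", "is_endpoint")
  need_e <- c("source", "target", "sign", "weight")
  if (!all(need_n %in% names(object@nodes)))
    msg <- c(msg, paste("node table must have columns",
                        paste(need_n, collapse = ", ")))
  if (nrow(object@edges) > 0 && !all(need_e %in% names(object@edges)))
    msg <- c(msg, paste("edge table must have columns",
                        paste(need_e, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Kinetic parameters of the Hill-type transfer functions
#'
#' Parameters shared by every interaction link. Each activating edge
#' contributes a Hill term `w * x^h / (K^h + x^h)` of its source activity
#' `x`; multiple activators are aggregated by mean (default) or sum.
#' Each inhibiting edge contributes a complementary factor
#' `1 - w * x^h / (K^h + x^h)`; inhibitors combine multiplicatively
#' (AND-NOT logic).
#'
#' @slot hillCoef Hill coefficient `h` (dimensionless, `>= 1`).
#' @slot halfSat half-saturation constant `K` (activity units, `> 0`).
#' @slot degradation first-order decay rate `gamma` (1/time, `> 0`).
#' @slot aggregation `"mean"` or `"sum"` for multiple activators.
#' @slot endpointBeta fixed production scale of endpoint nodes (default 1);
#'   endpoints are readouts, so their steady state purely reflects
#'   upstream input.
#' @seealso [kineticParams()]
#' @export
setClass("KineticParams",
  representation(hillCoef = "numeric", halfSat = "numeric",
                 degradation = "numeric", aggregation = "character",
                 endpointBeta = "numeric"))

setValidity("KineticParams", function(object) {
  msg <- character()
  if (object@hillCoef < 1) msg <- c(msg, "hillCoef must be >= 1")
  if (object@halfSat <= 0) msg <- c(msg, "halfSat must be > 0")
  if (object@degradation <= 0) msg <- c(msg, "degradation must be > 0")
  if (!object@aggregation %in% c("mean", "sum"))
    msg <- c(msg, "aggregation must be 'mean' or 'sum'")
  if (object@endpointBeta <= 0) msg <- c(msg, "endpointBeta must be > 0")
  if (length(msg)) msg else TRUE
})

#' Steady-state solver configuration
#'
#' @slot rateTol convergence threshold on `max |dx/dt|` (`> 0`).
#' @slot tMax integration-time cap (`> 0`); non-convergence by `tMax` is
#'   reported honestly via the `converged` flag.
#' @slot init initial condition: `"beta"` (each node starts at its basal
#'   activity) or `"zeros"`.
#' @slot backend `"lsoda"` (adaptive integration via deSolve) or
#'   `"fixedpoint"` (damped fixed-point iteration, the vectorised engine
#'   used by the scanning functions).
#' @seealso [solverConfig()], [steadyState()]
#' @export
setClass("SolverConfig",
  representation(rateTol = "numeric", tMax = "numeric", init = "character",
                 backend = "character"))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (object@rateTol <= 0) msg <- c(msg, "rateTol must be > 0")
  if (object@tMax <= 0) msg <- c(msg, "tMax must be > 0")
  if (!object@init %in% c("beta", "zeros"))
    msg <- c(msg, "init must be 'beta' or 'zeros'")
  if (!object@backend %in% c("lsoda", "fixedpoint"))
    msg <- c(msg, "backend must be 'lsoda' or 'fixedpoint'")
  if (length(msg)) msg else TRUE
})

#' One converged steady state
#'
#' @slot assignment named numeric vector of basal activities (beta) for
#'   every non-endpoint node.
#' @slot ss named numeric vector of steady-state activities for all nodes.
#' @slot converged logical flag; `TRUE` iff `residual <= rateTol`.
#' @slot residual `max |dx/dt|` at termination.
#' @seealso [steadyState()]
#' @export
setClass("SteadyStateRecord",
  representation(assignment = "numeric", ss = "numeric",
                 converged = "logical", residual = "numeric"))

#' A collection of steady states over enumerated or gridded activity states
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: rows are network
#' nodes, columns are activity states. The `"ss"` assay holds steady-state
#' activities; `colData` carries per-state bookkeeping (`state_id`,
#' `converged`, `residual`, plus the binary `level` matrix for coarse
#' scans or the `beta` coordinate matrix for grid scans). `metadata()`
#' records the network, enumerated control nodes, kinetic and solver
#' settings.
#'
#' @seealso [scanStates()], [gridScan()], [ssMatrix()], [stateLevels()]
#' @export
setClass("SteadyStateScan", contains = "SummarizedExperiment")
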