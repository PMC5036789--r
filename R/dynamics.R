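#' Kinetic parameter constructor
#'
#' @param hillCoef Hill coefficient `h` (default 2).
#' @param halfSat half-saturation `K` (default 0.5; sits between the
#'   coarse-grained basal levels 0.001 and 0.1 and typical cascade gains).
#' @param degradation decay rate `gamma` (default 1, which makes a source
#'   node's steady state equal its basal activity `beta`).
#' @param aggregation `"mean"` (default; activators combine redundantly)
#'   or `"sum"`.
#' @param endpointBeta production scale of endpoint nodes (default 1).
#' @return a [KineticParams].
#' @export
kineticParams <- function(hillCoef = 2, halfSat = 0.5, degradation = 1,
                          aggregation = c("mean", "sum"), endpointBeta = 1) {
  new("KineticParams", hillCoef = hillCoef, halfSat = halfSat,
      degradation = degradation, aggregation = match.arg(aggregation),
      endpointBeta = endpointBeta)
}

#' Solver configuration constructor
#'
#' @param rateTol convergence threshold on `max |dx/dt|` (default 1e-9).
#' @param tMax integration-time cap (default 1e4).
#' @param init `"beta"` (default) or `"zeros"`.
#' @param backend `"lsoda"` (default for [steadyState()]) or
#'   `"fixedpoint"`.
#' @return a [SolverConfig].
#' @export
solverConfig <- function(rateTol = 1e-9, tMax = 1e4,
                         init = c("beta", "zeros"),
                         backend = c("lsoda", "fixedpoint")) {
  new("SolverConfig", rateTol = rateTol, tMax = tMax,
      init = match.arg(init), backend = match.arg(backend))
}

#' Hill activation function
#'
#' The saturating transfer kernel `x^h / (K^h + x^h)` used on every
#' activating link; inhibiting links use its complement.
#'
#' @param x activity (vector or matrix), must be non-negative.
#' @param K half-saturation constant (`hillActivation(K, K, h)` is 0.5
#'   for any `h`).
#' @param h Hill coefficient (`>= 1`).
#' @return values in `[0, 1]`, monotone nondecreasing in `x`.
#' @examples
#' hillActivation(0.5, 0.5, 2)  # 0.5
#' hillActivation(0.1, 0.5, 2)  # 0.01 / 0.26
#' @export
hillActivation <- function(x, K, h) {
  if (any(x < 0)) stop("hillActivation: x must be >= 0")
  if (K <= 0) stop("hillActivation: K must be > 0")
  if (h < 1) stop("hillActivation: h must be >= 1")
  xh <- x^h
  xh / (K^h + xh)
}

# Precompute the structural pieces of the ODE right-hand side.
# Wact[target, source] holds activating-edge weights; inhibiting edges are
# kept as index triplets (few in typical networks).
.buildModel <- function(net, params) {
  nd <- net@nodes
  ed <- net@edges
  n <- nrow(nd)
  nm <- nd$name
  src <- match(ed$source, nm)
  tgt <- match(ed$target, nm)
  if (any(is.na(src)) || any(is.na(tgt)))
    stop("edge references unknown node")
  act <- ed$sign == "activating"
  Wact <- matrix(0, n, n, dimnames = list(nm, nm))
  if (any(act)) Wact[cbind(tgt[act], src[act])] <- ed$weight[act]
  nAct <- tabulate(tgt[act], nbins = n)
  inh <- list(src = src[!act], tgt = tgt[!act], w = ed$weight[!act])
  list(n = n, names = nm, Wact = Wact, nAct = nAct, hasAct = nAct > 0,
       inh = inh, is_endpoint = nd$is_endpoint,
       beta_low = setNames(nd$beta_low, nm),
       beta_high = setNames(nd$beta_high, nm))
}

# Production factor A(x) * I(x) for an activity matrix X (nodes x states).
.production <- function(model, params, X) {
  H <- hillActivation(X, params@halfSat, params@hillCoef)
  A <- model$Wact %*% H
  if (params@aggregation == "mean" && any(model$hasAct))
    A[model$hasAct, ] <- A[model$hasAct, , drop = FALSE] /
      model$nAct[model$hasAct]
  A[!model$hasAct, ] <- 1
  if (length(model$inh$src)) {
    for (k in seq_along(model$inh$src)) {
      s <- model$inh$src[k]; t <- model$inh$tgt[k]; w <- model$inh$w[k]
      A[t, ] <- A[t, ] * pmax(0, 1 - w * H[s, , drop = TRUE])
    }
  }
  A
}

# Full beta vector over all nodes: assignment for non-endpoints,
# endpointBeta for endpoints.
.betaVector <- function(net, params, assignment) {
  nd <- net@nodes
  beta <- setNames(rep(params@endpointBeta, nrow(nd)), nd$name)
  ctrl <- nd$name[!nd$is_endpoint]
  missing <- setdiff(ctrl, names(assignment))
  if (length(missing))
    stop("assignment missing node(s): ", paste(missing, collapse = ", "))
  if (any(assignment[ctrl] <= 0))
    stop("assignment values must be > 0")
  beta[ctrl] <- assignment[ctrl]
  beta
}

#' Evaluate the ODE right-hand side
#'
#' The network dynamics are
#' `dx_i/dt = beta_i * A_i(x) * I_i(x) - gamma * x_i`, where `A_i` is the
#' aggregated Hill activation over the node's activators (1 if it has
#' none) and `I_i` the product of complementary Hill terms over its
#' inhibitors (1 if none). Endpoint nodes use the fixed `endpointBeta`.
#'
#' @param net a [SignedNetwork].
#' @param params a [KineticParams].
#' @param assignment named numeric vector of basal activities covering
#'   every non-endpoint node.
#' @param x named numeric vector of current activities (all nodes,
#'   non-negative).
#' @return named numeric vector of rates `dx/dt`.
#' @export
evaluateRates <- function(net, params = kineticParams(), assignment, x) {
  model <- .buildModel(net, params)
  if (length(x) != model$n) stop("x must have one entry per node")
  if (!is.null(names(x))) x <- x[model$names]
  if (any(is.na(x))) stop("x names must match network nodes")
  beta <- .betaVector(net, params, assignment)
  P <- .production(model, params, matrix(x, ncol = 1))
  setNames(beta * P[, 1] - params@degradation * x, model$names)
}

# Upper bound on the Jacobian scale of the production term, used to pick
# a stable damping step for the fixed-point iteration.
.hillSlopeMax <- function(K, h) {
  if (h == 1) return(1 / K)
  x0 <- K * ((h - 1) / (h + 1))^(1 / h)
  h * x0^(h - 1) * K^h / (K^h + x0^h)^2
}

# Damped fixed-point iteration on a whole batch of states at once.
# X <- X + dt * (Beta * P(X) - gamma * X), dt from a Lipschitz bound, so
# the iteration is a stable explicit relaxation towards the ODE's fixed
# point (which it shares exactly with the integrated system).
.batchSolve <- function(model, params, Beta, solver, init = NULL) {
  gamma <- params@degradation
  m <- ncol(Beta)
  X <- if (is.null(init)) {
    if (solver@init == "zeros") matrix(0, model$n, m) else Beta / gamma
  } else init
  wmax <- if (nrow(model$Wact) && any(model$Wact > 0)) max(model$Wact) else 0
  wmax <- max(wmax, if (length(model$inh$w)) max(model$inh$w) else 0)
  L <- gamma + max(Beta) * wmax *
    .hillSlopeMax(params@halfSat, params@hillCoef)
  dt <- 1 / L
  maxIter <- min(ceiling(solver@tMax / dt), 200000L)
  resid <- rep(Inf, m)
  active <- rep(TRUE, m)
  for (iter in seq_len(maxIter)) {
    R <- Beta * .production(model, params, X) - gamma * X
    X <- X + dt * R
    if (iter %% 10 == 0 || iter == maxIter) {
      resid <- apply(abs(R), 2, max)
      if (all(resid <= solver@rateTol)) break
    }
  }
  R <- Beta * .production(model, params, X) - gamma * X
  resid <- apply(abs(R), 2, max)
  list(ss = X, converged = resid <= solver@rateTol, residual = resid)
}

#' Compute the steady state for one activity assignment
#'
#' Integrates the Hill-type ODE system from the configured initial
#' condition until `max |dx/dt|` falls below `rateTol` or time exceeds
#' `tMax`. The default backend is adaptive integration (deSolve's lsoda);
#' `"fixedpoint"` uses the damped fixed-point engine shared with the
#' scanning functions (both converge to the same fixed point; their
#' agreement is part of the test suite).
#'
#' @inheritParams evaluateRates
#' @param solver a [SolverConfig].
#' @return a [SteadyStateRecord]; `converged` is reported honestly and
#'   downstream analyses exclude (and count) non-converged states.
#' @examples
#' net <- npmAlkNetwork()
#' beta <- setNames(rep(0.001, 19), controlNodes(net))
#' rec <- steadyState(net, assignment = beta)
#' @export
steadyState <- function(net, params = kineticParams(), assignment,
                        solver = solverConfig()) {
  model <- .buildModel(net, params)
  beta <- .betaVector(net, params, assignment)
  gamma <- params@degradation
  if (solver@backend == "fixedpoint") {
    res <- .batchSolve(model, params, matrix(beta, ncol = 1), solver)
    return(new("SteadyStateRecord",
               assignment = beta[!model$is_endpoint],
               ss = setNames(res$ss[, 1], model$names),
               converged = res$converged[1], residual = res$residual[1]))
  }
  rhs <- function(t, y, parms) {
    if (any(y < -1e-8))
      stop("negative activity excursion during integration")
    y <- pmax(y, 0)
    P <- .production(model, params, matrix(y, ncol = 1))
    list(beta * P[, 1] - gamma * y)
  }
  y <- if (solver@init == "zeros") rep(0, model$n) else as.numeric(beta)
  t <- 0
  chunk <- min(20, solver@tMax)
  resid <- Inf
  repeat {
    out <- deSolve::lsoda(y, times = c(t, t + chunk), func = rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    y <- out[nrow(out), -1]
    t <- t + chunk
    resid <- max(abs(rhs(t, y, NULL)[[1]]))
    if (resid <= solver@rateTol || t >= solver@tMax) break
  }
  new("SteadyStateRecord", assignment = beta[!model$is_endpoint],
      ss = setNames(pmax(as.numeric(y), 0), model$names),
      converged = resid <= solver@rateTol, residual = resid)
}

#' Batch steady states for a matrix of basal-activity assignments
#'
#' Vectorised damped fixed-point solution of the same ODE fixed point as
#' [steadyState()], for many states at once (columns).
#'
#' @inheritParams steadyState
#' @param betaMatrix numeric matrix, one row per network node (in network
#'   order or named) and one column per state; endpoint rows are ignored
#'   and replaced by `endpointBeta`.
#' @return list with `ss` (nodes x states matrix), `converged` (logical
#'   per state) and `residual` (numeric per state).
#' @export
steadyStateBatch <- function(net, params = kineticParams(), betaMatrix,
                             solver = solverConfig()) {
  model <- .buildModel(net, params)
  if (nrow(betaMatrix) != model$n)
    stop("betaMatrix must have one row per node")
  if (!is.null(rownames(betaMatrix)))
    betaMatrix <- betaMatrix[model$names, , drop = FALSE]
  betaMatrix[model$is_endpoint, ] <- params@endpointBeta
  res <- .batchSolve(model, params, betaMatrix, solver)
  rownames(res$ss) <- model$names
  res
}
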