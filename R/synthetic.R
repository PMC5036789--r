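#' Generate a random signed network
#'
#' Draws a sparse Erdos-Renyi-style directed network emulating the
#' statistical shape of the curated NPM-ALK model: mostly activating
#' edges, a handful of inhibiting ones, optional feedback cycles, and a
#' few sink endpoints. All randomness is governed by one seed; the same
#' configuration and seed reproduce the network exactly.
#'
#' Nodes are laid out in a topological order; forward edges are drawn
#' with `edgeProbability`, and (when `allowCycles`) back edges among
#' non-endpoints with a quarter of that probability. The last
#' `nEndpoints` nodes are endpoints: they are sinks, and each is
#' guaranteed an incoming edge. Draws that fail validation (e.g.
#' disconnected skeletons) are redrawn up to `maxTries` times.
#'
#' @param nNodes number of nodes (`>= 3`).
#' @param edgeProbability forward-edge probability (0, 1].
#' @param inhibitionFraction probability that an edge is inhibiting.
#' @param allowCycles allow feedback (back) edges; if `FALSE` the result
#'   is a DAG with endpoints as sinks.
#' @param nEndpoints number of endpoint (readout) nodes.
#' @param seed integer seed; fixes all randomness.
#' @param betaLow,betaHigh basal activity levels given to every node
#'   (defaults 0.001 / 0.1).
#' @param maxTries redraw budget before giving up.
#' @return a validated [SignedNetwork].
#' @examples
#' net <- randomNetwork(8, seed = 7)
#' @export
randomNetwork <- function(nNodes, edgeProbability = 0.15,
                          inhibitionFraction = 0.1, allowCycles = TRUE,
                          nEndpoints = 2, seed,
                          betaLow = 0.001, betaHigh = 0.1,
                          maxTries = 100) {
  stopifnot(nNodes >= 3, edgeProbability > 0, edgeProbability <= 1,
            inhibitionFraction >= 0, inhibitionFraction <= 1,
            nEndpoints >= 1, nEndpoints < nNodes)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nm <- sprintf("N%02d", seq_len(nNodes))
  ep <- nm[seq(nNodes - nEndpoints + 1, nNodes)]
  for (attempt in seq_len(maxTries)) {
    src <- character(); tgt <- character()
    for (i in seq_len(nNodes - 1)) {
      for (j in seq(i + 1, nNodes)) {
        if (nm[i] %in% ep) next  # endpoints are sinks
        if (stats::runif(1) < edgeProbability) {
          src <- c(src, nm[i]); tgt <- c(tgt, nm[j])
        }
      }
    }
    if (allowCycles) {
      nonep <- setdiff(nm, ep)
      for (i in seq_along(nonep)) {
        for (j in seq_len(i - 1)) {
          if (stats::runif(1) < edgeProbability / 4) {
            src <- c(src, nonep[i]); tgt <- c(tgt, nonep[j])
          }
        }
      }
    }
    # every endpoint needs at least one incoming edge
    for (e in ep) {
      if (!e %in% tgt) {
        cand <- setdiff(nm, ep)
        pick <- cand[sample.int(length(cand), 1)]
        src <- c(src, pick); tgt <- c(tgt, e)
      }
    }
    if (length(src) == 0) next
    key <- !duplicated(paste(src, tgt, sep = "\r"))
    src <- src[key]; tgt <- tgt[key]
    sign <- ifelse(stats::runif(length(src)) < inhibitionFraction,
                   "inhibiting", "activating")
    nodes <- data.frame(name = nm, beta_low = betaLow,
                        beta_high = betaHigh, is_endpoint = nm %in% ep,
                        stringsAsFactors = FALSE)
    edges <- data.frame(source = src, target = tgt, sign = sign,
                        weight = 1, stringsAsFactors = FALSE)
    net <- signedNetwork(nodes, edges,
                         metadata = list(name = sprintf("synthetic-%d", seed),
                                         synthetic = TRUE, seed = seed),
                         validate = FALSE)
    if (length(validateNetwork(net)) == 0) return(net)
  }
  stop("randomNetwork: could not draw a valid network within ", maxTries,
       " attempts")
}

#' Analytically solvable network motifs
#'
#' Small motifs with closed-form steady states, used as independent
#' oracles for the numerical solvers:
#' \describe{
#'   \item{`cascade`}{a chain `N1 -> N2 -> ... -> Nk` (terminal node is
#'     the endpoint); steady states compose the Hill transfer explicitly.}
#'   \item{`fan_in`}{two activators `A`, `B` converging on endpoint `T`.}
#'   \item{`inhibitor_pair`}{an inhibitor `I -| T`; the endpoint's
#'     production is the complementary Hill factor.}
#'   \item{`feedback_loop`}{`D -> A <-> B -> E`, a two-node positive
#'     feedback with an external driver; the scalar fixed point for `A`
#'     is solved by bisection to 1e-12.}
#' }
#'
#' @param name motif name; `"cascade_3"`-style suffixes set the chain
#'   length.
#' @param k chain length for `cascade` (default 2).
#' @return list with elements `network` (a [SignedNetwork]) and
#'   `closedForm`, a `function(assignment, params)` returning the exact
#'   named steady-state vector for any basal-activity assignment of the
#'   motif's non-endpoint nodes.
#' @examples
#' mo <- motifNetwork("cascade", k = 2)
#' mo$closedForm(c(N1 = 0.1))["N2"]  # 1 * hill(0.1, 0.5, 2)
#' @export
motifNetwork <- function(name = c("cascade", "fan_in", "inhibitor_pair",
                                  "feedback_loop"), k = 2) {
  nm <- as.character(name)[1]
  if (grepl("^cascade_[0-9]+$", nm)) {
    k <- as.integer(sub("^cascade_", "", nm))
    nm <- "cascade"
  }
  nm <- match.arg(nm, c("cascade", "fan_in", "inhibitor_pair",
                        "feedback_loop"))
  hill <- function(x, p) hillActivation(x, p@halfSat, p@hillCoef)
  agg <- function(terms, p)
    if (p@aggregation == "mean") mean(terms) else sum(terms)

  if (nm == "cascade") {
    stopifnot(k >= 2)
    nodes <- sprintf("N%d", seq_len(k))
    net <- signedNetwork(
      data.frame(name = nodes,
                 is_endpoint = seq_len(k) == k),
      data.frame(source = nodes[-k], target = nodes[-1],
                 sign = "activating"))
    closed <- function(assignment, params = kineticParams()) {
      g <- params@degradation
      x <- numeric(k); names(x) <- nodes
      x[1] <- assignment[[nodes[1]]] / g
      for (i in seq(2, k)) {
        b <- if (i == k) params@endpointBeta else assignment[[nodes[i]]]
        x[i] <- b * hill(x[i - 1], params) / g
      }
      x
    }
    return(list(network = net, closedForm = closed))
  }
  if (nm == "fan_in") {
    net <- signedNetwork(
      data.frame(name = c("A", "B", "T"),
                 is_endpoint = c(FALSE, FALSE, TRUE)),
      data.frame(source = c("A", "B"), target = "T", sign = "activating"))
    closed <- function(assignment, params = kineticParams()) {
      g <- params@degradation
      xa <- assignment[["A"]] / g
      xb <- assignment[["B"]] / g
      xt <- params@endpointBeta *
        agg(c(hill(xa, params), hill(xb, params)), params) / g
      c(A = xa, B = xb, T = xt)
    }
    return(list(network = net, closedForm = closed))
  }
  if (nm == "inhibitor_pair") {
    net <- signedNetwork(
      data.frame(name = c("I", "T"), is_endpoint = c(FALSE, TRUE)),
      data.frame(source = "I", target = "T", sign = "inhibiting"))
    closed <- function(assignment, params = kineticParams()) {
      g <- params@degradation
      xi <- assignment[["I"]] / g
      xt <- params@endpointBeta * (1 - hill(xi, params)) / g
      c(I = xi, T = xt)
    }
    return(list(network = net, closedForm = closed))
  }
  # feedback_loop: D -> A, A -> B, B -> A, B -> E
  net <- signedNetwork(
    data.frame(name = c("D", "A", "B", "E"),
               is_endpoint = c(FALSE, FALSE, FALSE, TRUE)),
    data.frame(source = c("D", "A", "B", "B"),
               target = c("A", "B", "A", "E"),
               sign = "activating"))
  closed <- function(assignment, params = kineticParams()) {
    g <- params@degradation
    xd <- assignment[["D"]] / g
    ba <- assignment[["A"]]; bb <- assignment[["B"]]
    fa <- function(x) {
      xb <- bb * hill(x, params) / g
      ba * agg(c(hill(xd, params), hill(xb, params)), params) / g - x
    }
    upper <- ba * (if (params@aggregation == "mean") 1 else 2) / g
    lo <- 0; hi <- upper
    if (fa(hi) > 0) hi <- upper  # production bounded, root is in [0, upper]
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (fa(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-12 * max(1, upper)) break
    }
    xa <- (lo + hi) / 2
    xb <- bb * hill(xa, params) / g
    xe <- params@endpointBeta * hill(xb, params) / g
    c(D = xd, A = xa, B = xb, E = xe)
  }
  list(network = net, closedForm = closed)
}
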