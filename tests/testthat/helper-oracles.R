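# Independent oracles used across the suite. These deliberately avoid the
# package's solver internals: the Euler oracle integrates with its own
# fixed-step arithmetic, the topological oracle composes transfer
# functions explicitly, and the pair counter enumerates hypercube edges.

oracle_hill <- function(x, K, h) x^h / (K^h + x^h)

# fixed-step Euler integration of the network ODE, written from the model
# definition (mean-aggregated activators, AND-NOT inhibitors, unit weights)
euler_ss <- function(net, assignment, dt = 0.01, t_end = 150,
                     K = 0.5, h = 2, gamma = 1, endpoint_beta = 1) {
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  nm <- nd$name
  n <- length(nm)
  src <- match(ed$source, nm)
  tgt <- match(ed$target, nm)
  act <- ed$sign == "activating"
  W <- matrix(0, n, n)
  W[cbind(tgt[act], src[act])] <- ed$weight[act]
  nact <- tabulate(tgt[act], n)
  hasact <- nact > 0
  inh <- cbind(tgt[!act], src[!act])
  beta <- ifelse(nd$is_endpoint, endpoint_beta, assignment[nm])
  x <- beta
  for (s in seq_len(ceiling(t_end / dt))) {
    hx <- oracle_hill(x, K, h)
    A <- drop(W %*% hx)
    A[hasact] <- A[hasact] / nact[hasact]
    A[!hasact] <- 1
    if (nrow(inh) > 0) {
      for (k in seq_len(nrow(inh)))
        A[inh[k, 1]] <- A[inh[k, 1]] * (1 - hx[inh[k, 2]])
    }
    x <- x + dt * (beta * A - gamma * x)
  }
  setNames(x, nm)
}

# explicit steady state of an acyclic network by topological composition
topo_ss <- function(net, assignment, K = 0.5, h = 2, gamma = 1,
                    endpoint_beta = 1) {
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  ord <- names(igraph::topo_sort(asIgraph(net)))
  x <- setNames(rep(NA_real_, nrow(nd)), nd$name)
  for (node in ord) {
    beta <- if (nd$is_endpoint[nd$name == node]) endpoint_beta
            else assignment[[node]]
    acts <- ed$source[ed$target == node & ed$sign == "activating"]
    inhs <- ed$source[ed$target == node & ed$sign == "inhibiting"]
    A <- if (length(acts)) mean(oracle_hill(x[acts], K, h)) else 1
    I <- if (length(inhs)) prod(1 - oracle_hill(x[inhs], K, h)) else 1
    x[node] <- beta * A * I / gamma
  }
  x
}

# brute-force count of unordered state pairs differing in exactly one node
brute_pair_count <- function(n, s) {
  states <- as.matrix(expand.grid(rep(list(seq_len(s) - 1), n)))
  cnt <- 0
  for (i in seq_len(nrow(states) - 1)) {
    for (j in seq(i + 1, nrow(states))) {
      if (sum(states[i, ] != states[j, ]) == 1) cnt <- cnt + 1
    }
  }
  cnt
}

# relative error with an absolute floor (both solvers work to absolute
# rate tolerances, so relative agreement is only meaningful above it)
rel_err <- function(a, b, floor = 1e-9) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# a chain N1 -> N2 -> ... -> Nk -> E with chosen signs on each edge
chain_net <- function(signs, beta_low = 0.001, beta_high = 0.1) {
  k <- length(signs)
  nodes <- c(sprintf("N%d", seq_len(k)), "E")
  signedNetwork(
    data.frame(name = nodes, is_endpoint = nodes == "E",
               beta_low = beta_low, beta_high = beta_high),
    data.frame(source = nodes[-(k + 1)], target = nodes[-1], sign = signs))
}

# A -> E and a dangling branch A -> B (B has no path to the endpoint)
branch_net <- function() {
  signedNetwork(
    data.frame(name = c("A", "B", "E"),
               is_endpoint = c(FALSE, FALSE, TRUE)),
    data.frame(source = c("A", "A"), target = c("E", "B"),
               sign = "activating"))
}

# two symmetric activators of one endpoint
parallel_net <- function() {
  signedNetwork(
    data.frame(name = c("A", "B", "E"),
               is_endpoint = c(FALSE, FALSE, TRUE)),
    data.frame(source = c("A", "B"), target = "E", sign = "activating"))
}

npm_alk_sub12 <- function() {
  subNetwork(npmAlkNetwork(),
             c("NPM-ALK", "HSP90", "SHP1", "Interleukins", "JAK3/STAT3",
               "p85/PI3K/p110", "PIP3", "pAKT", "Phosphatases",
               "GRB/SHC/IRS1", "VAV1", "CDC42"))
}
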