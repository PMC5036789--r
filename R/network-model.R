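#' Construct a signed network
#'
#' Builds and (by default) validates a [SignedNetwork] from node and edge
#' tables.
#'
#' @param nodes `data.frame` with columns `name`, and optionally
#'   `beta_low` (default 0.001), `beta_high` (default 0.1) and
#'   `is_endpoint` (default `FALSE`).
#' @param edges `data.frame` with columns `source`, `target`, `sign`
#'   (`"activating"`/`"inhibiting"`) and optionally `weight` (default 1).
#' @param metadata free-form provenance list.
#' @param validate if `TRUE` (default), [validateNetwork()] is run and any
#'   diagnostic raises an error.
#' @return a [SignedNetwork].
#' @examples
#' net <- signedNetwork(
#'   nodes = data.frame(name = c("A", "B"),
#'                      is_endpoint = c(FALSE, TRUE)),
#'   edges = data.frame(source = "A", target = "B", sign = "activating"))
#' @export
signedNetwork <- function(nodes, edges, metadata = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$beta_low)) nodes$beta_low <- 0.001
  if (is.null(nodes$beta_high)) nodes$beta_high <- 0.1
  if (is.null(nodes$is_endpoint)) nodes$is_endpoint <- FALSE
  nodes$name <- as.character(nodes$name)
  nodes$is_endpoint <- as.logical(nodes$is_endpoint)
  nodes <- nodes[c("name", "beta_low", "beta_high", "is_endpoint")]
  if (nrow(edges) > 0) {
    if (is.null(edges$weight)) edges$weight <- 1
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.character(edges$sign)
    edges <- edges[c("source", "target", "sign", "weight")]
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), weight = numeric())
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  net <- new("SignedNetwork", nodes = nodes, edges = edges,
             metadata = metadata)
  if (validate) {
    diag <- validateNetwork(net)
    if (length(diag))
      stop("invalid network:\n  ", paste(diag, collapse = "\n  "))
  }
  net
}

#' Network accessors
#'
#' @param x a [SignedNetwork].
#' @return `networkNodes`/`networkEdges` return the node/edge
#'   `data.frame`; `nodeNames`, `controlNodes` (non-endpoints) and
#'   `endpointNodes` return character vectors; `asIgraph` returns an
#'   [igraph::igraph] with `sign` and `weight` edge attributes.
#' @name networkAccessors
NULL

#' @rdname networkAccessors
#' @export
setMethod("networkNodes", "SignedNetwork", function(x) x@nodes)

#' @rdname networkAccessors
#' @export
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)

#' @rdname networkAccessors
#' @export
setMethod("nodeNames", "SignedNetwork", function(x) x@nodes$name)

#' @rdname networkAccessors
#' @export
setMethod("controlNodes", "SignedNetwork",
          function(x) x@nodes$name[!x@nodes$is_endpoint])

#' @rdname networkAccessors
#' @export
setMethod("endpointNodes", "SignedNetwork",
          function(x) x@nodes$name[x@nodes$is_endpoint])

#' @rdname networkAccessors
#' @export
setMethod("asIgraph", "SignedNetwork", function(x) {
  g <- igraph::graph_from_data_frame(
    x@edges[c("source", "target", "sign", "weight")],
    directed = TRUE,
    vertices = x@nodes[c("name", "is_endpoint")])
  g
})

setMethod("show", "SignedNetwork", function(object) {
  n <- nrow(object@nodes)
  e <- nrow(object@edges)
  inh <- sum(object@edges$sign == "inhibiting")
  cat("SignedNetwork with", n, "nodes (",
      sum(object@nodes$is_endpoint), "endpoints ) and", e, "edges (",
      inh, "inhibiting )\n")
  cat("  nodes:", paste(head(object@nodes$name, 6), collapse = ", "),
      if (n > 6) "..." else "", "\n")
})

#' Validate a signed network
#'
#' Checks all structural invariants and returns diagnostics rather than
#' raising: unique node names, positive basal activities with
#' `beta_high > beta_low`, edges referencing existing nodes, no duplicated
#' source/target pairs, positive weights, weak connectivity, no isolated
#' node, at least one endpoint, every endpoint with at least one incoming
#' edge, no endpoint with outgoing edges, and every endpoint reachable
#' from some non-endpoint node.
#'
#' @param net a [SignedNetwork].
#' @return character vector of diagnostics, each naming the offending
#'   element; empty iff the network is valid.
#' @export
validateNetwork <- function(net) {
  nd <- net@nodes
  ed <- net@edges
  msg <- character()
  dup <- unique(nd$name[duplicated(nd$name)])
  if (length(dup))
    msg <- c(msg, paste0("duplicate node name: ", dup))
  bad <- nd$name[!is.finite(nd$beta_low) | nd$beta_low <= 0]
  if (length(bad)) msg <- c(msg, paste0("beta_low must be > 0 for node: ", bad))
  bad <- nd$name[!is.finite(nd$beta_high) | nd$beta_high <= nd$beta_low]
  if (length(bad))
    msg <- c(msg, paste0("beta_high must exceed beta_low for node: ", bad))
  if (nrow(ed) > 0) {
    miss <- unique(c(ed$source[!ed$source %in% nd$name],
                     ed$target[!ed$target %in% nd$name]))
    if (length(miss))
      msg <- c(msg, paste0("edge references unknown node: ", miss))
    key <- paste(ed$source, ed$target, sep = "\r")
    dup <- unique(key[duplicated(key)])
    if (length(dup))
      msg <- c(msg, paste0("duplicate edge: ", gsub("\r", " -> ", dup)))
    bad <- which(!ed$sign %in% c("activating", "inhibiting"))
    if (length(bad))
      msg <- c(msg, paste0("invalid edge sign: ", ed$sign[bad]))
    bad <- which(!is.finite(ed$weight) | ed$weight <= 0)
    if (length(bad))
      msg <- c(msg, paste0("edge weight must be > 0: ", ed$source[bad],
                           " -> ", ed$target[bad]))
  }
  # graph-level checks only make sense if the element-level ones pass
  if (length(msg)) return(msg)

  deg_out <- table(factor(ed$source, levels = nd$name))
  deg_in <- table(factor(ed$target, levels = nd$name))
  iso <- nd$name[deg_out == 0 & deg_in == 0]
  if (length(iso)) msg <- c(msg, paste0("isolated node: ", iso))

  if (nrow(nd) > 1 && nrow(ed) > 0) {
    g <- asIgraph(net)
    if (!igraph::is_connected(g, mode = "weak"))
      msg <- c(msg, "network is not connected as an undirected skeleton")
  }
  ep <- nd$name[nd$is_endpoint]
  if (length(ep) == 0) {
    msg <- c(msg, "network has no endpoint node")
  } else {
    noin <- ep[!(ep %in% ed$target)]
    if (length(noin))
      msg <- c(msg, paste0("endpoint has no incoming edge: ", noin))
    outep <- unique(ed$source[ed$source %in% ep])
    if (length(outep))
      msg <- c(msg, paste0("endpoint has outgoing edges: ", outep))
    if (nrow(ed) > 0 && length(ep) < nrow(nd)) {
      g <- asIgraph(net)
      d <- igraph::distances(g, v = nd$name[!nd$is_endpoint], to = ep,
                             mode = "out")
      unreachable <- ep[apply(d, 2, function(col) all(!is.finite(col)))]
      if (length(unreachable))
        msg <- c(msg, paste0("endpoint unreachable from any control node: ",
                             unreachable))
    }
  }
  msg
}

#' Extract an induced subnetwork
#'
#' Keeps the named nodes (endpoints of the parent are kept automatically)
#' and all edges among them.
#'
#' @param net a [SignedNetwork].
#' @param keep character vector of node names to retain.
#' @param validate validate the result (default `TRUE`).
#' @return a [SignedNetwork].
#' @export
subNetwork <- function(net, keep, validate = TRUE) {
  keep <- union(keep, endpointNodes(net))
  missing <- setdiff(keep, nodeNames(net))
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  nd <- net@nodes[net@nodes$name %in% keep, , drop = FALSE]
  ed <- net@edges[net@edges$source %in% keep & net@edges$target %in% keep, ,
                  drop = FALSE]
  md <- net@metadata
  md$subnetwork_of <- if (!is.null(md$name)) md$name else "parent"
  signedNetwork(nd, ed, metadata = md, validate = validate)
}
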