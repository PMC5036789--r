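#' Read a signed network from disk
#'
#' Two dialects are supported. JSON is canonical and lossless:
#' `{"nodes": [{"name", "beta_low", "beta_high", "is_endpoint"}, ...],
#' "edges": [{"source", "target", "sign", "weight"}, ...],
#' "metadata": {...}}`. SIF carries topology only
#' (`source<TAB>activates|inhibits<TAB>target`, one edge per line): basal
#' activities take the package defaults (0.001 / 0.1) and sink nodes are
#' flagged as endpoints.
#'
#' @param path file path.
#' @param format `"json"` or `"sif"`; guessed from the file extension
#'   when omitted.
#' @return a validated [SignedNetwork]; validation failures raise an
#'   error naming the offending element.
#' @seealso [writeNetwork()]
#' @export
loadNetwork <- function(path, format = c("auto", "json", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$nodes) || is.null(obj$edges))
      stop("malformed network JSON (need 'nodes' and 'edges'): ", path)
    md <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
    signedNetwork(as.data.frame(obj$nodes), as.data.frame(obj$edges),
                  metadata = md)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3))
      stop("malformed SIF line(s): ",
           paste(lines[lengths(parts) != 3], collapse = "; "))
    rel <- vapply(parts, `[`, "", 2)
    if (any(!rel %in% c("activates", "inhibits")))
      stop("unknown SIF relation(s): ",
           paste(unique(rel[!rel %in% c("activates", "inhibits")]),
                 collapse = ", "))
    edges <- data.frame(
      source = vapply(parts, `[`, "", 1),
      target = vapply(parts, `[`, "", 3),
      sign = ifelse(rel == "activates", "activating", "inhibiting"),
      weight = 1, stringsAsFactors = FALSE)
    nm <- unique(c(edges$source, edges$target))
    nodes <- data.frame(name = nm, beta_low = 0.001, beta_high = 0.1,
                        is_endpoint = !nm %in% edges$source,
                        stringsAsFactors = FALSE)
    signedNetwork(nodes, edges, metadata = list(source_file = basename(path)))
  }
}

#' Write a signed network to disk
#'
#' @param net a [SignedNetwork].
#' @param path output file path.
#' @param format `"json"` (lossless) or `"sif"` (topology and edge signs
#'   only; basal activities and endpoint flags are dropped by design).
#' @return `path`, invisibly.
#' @seealso [loadNetwork()], [exportGraphML()]
#' @export
writeNetwork <- function(net, path, format = c("auto", "json", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "json"
  if (format == "json") {
    obj <- list(nodes = net@nodes, edges = net@edges,
                metadata = net@metadata)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    rel <- ifelse(net@edges$sign == "activating", "activates", "inhibits")
    writeLines(paste(net@edges$source, rel, net@edges$target, sep = "\t"),
               path)
  }
  invisible(path)
}

#' Export a network as GraphML
#'
#' Writes topology with a `sign` edge attribute and an `is_endpoint` node
#' attribute, plus any extra per-node attributes supplied (e.g. the
#' width/grey columns produced by [flowAttributes()]), for use in network
#' viewers such as Cytoscape.
#'
#' @param net a [SignedNetwork].
#' @param path output `.graphml` path.
#' @param nodeAttrs optional `data.frame` with a `node` column and one
#'   column per extra attribute.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(net, path, nodeAttrs = NULL) {
  g <- asIgraph(net)
  if (!is.null(nodeAttrs)) {
    idx <- match(igraph::V(g)$name, nodeAttrs$node)
    for (col in setdiff(names(nodeAttrs), "node")) {
      igraph::vertex_attr(g, col) <- nodeAttrs[[col]][idx]
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
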