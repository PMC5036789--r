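test_that("the NPM-ALK fixture has the curated structure", {
  net <- npmAlkNetwork()
  nd <- networkNodes(net)
  ed <- networkEdges(net)

  expect_equal(nrow(nd), 21)
  expect_equal(length(endpointNodes(net)), 2)
  expect_setequal(endpointNodes(net), c("Proliferation", "Cell Survival"))
  expect_equal(length(controlNodes(net)), 19)
  expect_equal(nrow(ed), 28)

  # the only inhibiting edges come from the two phosphatase-type nodes
  inh <- ed[ed$sign == "inhibiting", ]
  expect_setequal(unique(inh$source), c("SHP1", "Phosphatases"))
  expect_equal(nrow(inh), 3)

  # SHP1 is a pure source (nothing in the curated model regulates it)
  expect_false("SHP1" %in% ed$target)

  # coarse-grained basal activity levels: high = 0.1, low = 0.001
  expect_true(all(nd$beta_low == 0.001))
  expect_true(all(nd$beta_high == 0.1))

  expect_length(validateNetwork(net), 0)
})

test_that("the fixture's only cycle is the interleukin-JAK3/STAT3 feedback", {
  net <- npmAlkNetwork()
  g <- asIgraph(net)
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1)
  expect_length(big, 1)
  expect_setequal(names(comp$membership)[comp$membership == big],
                  c("Interleukins", "JAK3/STAT3"))
  # removing one arc of that feedback leaves a DAG: no other cycle exists
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
    g, c("JAK3/STAT3", "Interleukins")))
  expect_true(igraph::is_dag(g2))
})

test_that("every control node has a directed path to an endpoint", {
  net <- npmAlkNetwork()
  d <- igraph::distances(asIgraph(net), v = controlNodes(net),
                         to = endpointNodes(net), mode = "out")
  expect_true(all(apply(d, 1, function(r) any(is.finite(r)))))
})

test_that("JSON round trip is the identity; SIF preserves topology", {
  net <- npmAlkNetwork()
  json <- withr::local_tempfile(fileext = ".json")
  writeNetwork(net, json)
  back <- loadNetwork(json)
  expect_equal(networkNodes(back), networkNodes(net))
  expect_equal(networkEdges(back), networkEdges(net))

  sif <- withr::local_tempfile(fileext = ".sif")
  writeNetwork(net, sif)
  back <- loadNetwork(sif)
  expect_setequal(nodeNames(back), nodeNames(net))
  eo <- function(e) e[order(e$source, e$target), c("source", "target", "sign")]
  expect_equal(eo(networkEdges(back)), eo(networkEdges(net)),
               ignore_attr = TRUE)
  # the fixture's sinks are exactly its endpoints, so the flag survives SIF
  expect_setequal(endpointNodes(back), endpointNodes(net))

  # round trip holds for generated networks too, in both dialects
  for (seed in 1:3) {
    rn <- randomNetwork(9, seed = seed)
    writeNetwork(rn, json)
    expect_equal(networkEdges(loadNetwork(json)), networkEdges(rn))
    expect_equal(networkNodes(loadNetwork(json)), networkNodes(rn))
  }
})

test_that("a minimal two-node JSON network loads", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    nodes = list(list(name = "A", beta_low = 0.001, beta_high = 0.1,
                      is_endpoint = FALSE),
                 list(name = "B", beta_low = 0.001, beta_high = 0.1,
                      is_endpoint = TRUE)),
    edges = list(list(source = "A", target = "B", sign = "activating",
                      weight = 1))), auto_unbox = TRUE), path)
  net <- loadNetwork(path)
  expect_equal(nrow(networkNodes(net)), 2)
  expect_equal(networkEdges(net)$sign, "activating")
})

test_that("validation failures are raised on load and name the offender", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    nodes = list(list(name = "Y", beta_low = 0.001, beta_high = 0.1,
                      is_endpoint = TRUE)),
    edges = list(list(source = "X", target = "Y", sign = "activating",
                      weight = 1))), auto_unbox = TRUE), path)
  expect_error(loadNetwork(path), "X")
  expect_error(loadNetwork(withr::local_tempfile(fileext = ".json")),
               "no such file")
})

test_that("validateNetwork reports diagnostics instead of raising", {
  nodes <- data.frame(name = c("A", "B", "E"),
                      beta_low = 0.001, beta_high = 0.1,
                      is_endpoint = c(FALSE, FALSE, TRUE))
  edges <- data.frame(source = "A", target = "E", sign = "activating",
                      weight = 1)
  net <- signedNetwork(nodes, edges, validate = FALSE)
  diag <- validateNetwork(net)
  expect_length(grep("isolated node: B", diag), 1)

  # an endpoint feeding back into a control node is flagged
  edges2 <- rbind(edges,
                  data.frame(source = "E", target = "B",
                             sign = "activating", weight = 1))
  diag2 <- validateNetwork(signedNetwork(nodes, edges2, validate = FALSE))
  expect_length(grep("endpoint has outgoing edges: E", diag2), 1)

  # basal-activity violations name the node
  nodes3 <- nodes
  nodes3$beta_high[1] <- 0.0001
  diag3 <- validateNetwork(signedNetwork(nodes3, edges, validate = FALSE))
  expect_length(grep("beta_high.*: A", diag3), 1)

  expect_error(signedNetwork(nodes, edges), "isolated node")
})

test_that("GraphML export is readable and carries the sign attribute", {
  net <- npmAlkNetwork()
  path <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 21)
  expect_setequal(unique(igraph::E(g)$sign), c("activating", "inhibiting"))
})

test_that("subNetwork induces edges and keeps endpoints", {
  net12 <- npm_alk_sub12()
  expect_equal(length(controlNodes(net12)), 12)
  expect_setequal(endpointNodes(net12), c("Proliferation", "Cell Survival"))
  expect_length(validateNetwork(net12), 0)
  ed <- networkEdges(net12)
  expect_false(any(!ed$source %in% nodeNames(net12)))
  # the dropped PLC-gamma arm takes its edges with it
  expect_false(any(ed$source == "PLC-gamma" | ed$target == "PLC-gamma"))
})
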