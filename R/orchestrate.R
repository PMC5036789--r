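#' Default run configuration
#'
#' A nested list with a documented default for every pipeline setting;
#' supplied values are merged over the defaults recursively.
#'
#' \describe{
#'   \item{network}{`"builtin:npm-alk"`, or a path to a JSON/SIF file.}
#'   \item{seed}{integer governing every randomised step.}
#'   \item{workers}{parallel workers for batch scanning (results are
#'     assembled in deterministic order regardless).}
#'   \item{out}{output directory.}
#'   \item{kinetics, solver}{fields of [kineticParams()] /
#'     [solverConfig()].}
#'   \item{coarse}{`sample` (states/pairs drawn; `NULL` = full
#'     enumeration), `q`, `plateau`, `resume`.}
#'   \item{flow}{`control`, `quantile`, `sample` (states drawn for the
#'     flow averages).}
#'   \item{fine}{`axes` (two varied nodes), `zNode`, `zLevels`, `points`,
#'     `from`, `to`.}
#'   \item{synth}{arguments of [randomNetwork()].}
#' }
#'
#' @param ... named overrides, e.g. `runConfig(coarse = list(sample = 500))`.
#' @return configuration list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    network = "builtin:npm-alk",
    seed = 1L,
    workers = 1L,
    out = "netsens-out",
    kinetics = list(hillCoef = 2, halfSat = 0.5, degradation = 1,
                    aggregation = "mean", endpointBeta = 1),
    solver = list(rateTol = 1e-9, tMax = 1e4, init = "beta",
                  backend = "fixedpoint"),
    coarse = list(sample = NULL, q = 0.02, plateau = 0.005,
                  resume = FALSE),
    flow = list(control = "NPM-ALK", quantile = 0.75, sample = 4096),
    fine = list(axes = c("JAK3/STAT3", "SHP1"), zNode = "NPM-ALK",
                zLevels = c(0.001, 0.1, 10, 100), points = 25,
                from = 1e-3, to = 1e2),
    synth = list(nNodes = 21, edgeProbability = 0.15,
                 inhibitionFraction = 0.1, allowCycles = TRUE,
                 nEndpoints = 2))
  .mergeConfig(cfg, list(...))
}

.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a run configuration file
#'
#' @param path YAML or JSON file; fields missing from the file keep
#'   their [runConfig()] defaults.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  over <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(runConfig, as.list(over))
}

.resolveNetwork <- function(x) {
  if (is(x, "SignedNetwork")) return(x)
  if (identical(x, "builtin:npm-alk")) return(npmAlkNetwork())
  loadNetwork(x)
}

.kineticsFrom <- function(cfg) do.call(kineticParams, cfg$kinetics)
.solverFrom <- function(cfg) do.call(solverConfig, cfg$solver)

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.safeName <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

.writeMeta <- function(out, name, cfg, extra = list()) {
  meta <- c(list(tool = "netsens",
                 version = as.character(packageVersion("netsens")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = cfg$seed,
                 config = cfg[setdiff(names(cfg), "network")]),
            extra)
  jsonlite::write_json(meta, file.path(out, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the coarse-grained scan pipeline
#'
#' Enumerates (or samples) the binary basal-activity states of the
#' configured network, writes the long-format steady-state table, the
#' endpoint sensitivity table and the per-node ranking summary, plus a
#' sidecar JSON with run metadata (the only file carrying a timestamp;
#' all result tables are byte-reproducible under an identical
#' configuration). With `coarse$sample` set, that many states are drawn
#' (seeded) for the steady-state table and that many single-node
#' difference pairs for the sensitivity table; otherwise the full `2^n`
#' enumeration is used. A completed full scan is checkpointed and reused
#' when `coarse$resume` is `TRUE`.
#'
#' @param config list from [runConfig()] / [readRunConfig()].
#' @return (invisibly) list with the scan, the sensitivity table and the
#'   per-endpoint ranking profiles.
#' @export
runCoarse <- function(config = runConfig()) {
  net <- .resolveNetwork(config$network)
  params <- .kineticsFrom(config)
  solver <- .solverFrom(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sample <- config$coarse$sample
  # runtime checkpoint (lossless; lives in the output dir, not the repo)
  ckpt <- file.path(out, "coarse_scan_checkpoint.rds")

  if (is.null(sample) && isTRUE(config$coarse$resume) &&
      file.exists(ckpt)) {
    scan <- readRDS(ckpt)
  } else {
    scan <- scanStates(net, params = params, solver = solver,
                       sample = sample, seed = config$seed,
                       workers = config$workers)
    if (is.null(sample)) saveRDS(scan, ckpt)
  }
  .writeTSV(ssTable(scan), file.path(out, "steady_states.tsv"))

  sens <- if (is.null(sample)) {
    sensitivityTable(scan, observed = "endpoints")
  } else {
    sampledSensitivity(net, nPairs = sample, seed = config$seed,
                       params = params, solver = solver,
                       observed = "endpoints")
  }
  .writeTSV(sens, file.path(out, "sensitivities.tsv"))

  profiles <- lapply(endpointNodes(net), function(ep)
    rankProfile(sens, q = config$coarse$q,
                plateauBand = config$coarse$plateau, endpoint = ep))
  names(profiles) <- endpointNodes(net)
  summ <- do.call(rbind, lapply(names(profiles), function(ep) {
    s <- profiles[[ep]]$summary
    cbind(endpoint = ep, s)
  }))
  .writeTSV(summ, file.path(out, "ranking_summary.tsv"))

  .writeMeta(out, "coarse", config,
             list(n_states = ncol(scan),
                  n_nonconverged =
                    sum(!SummarizedExperiment::colData(scan)$converged),
                  n_invalid_sensitivities = attr(sens, "n_invalid"),
                  extreme_size = profiles[[1]]$extreme_size))
  invisible(list(scan = scan, sensitivities = sens, profiles = profiles))
}

#' Run the signal-flow pipeline
#'
#' Computes involvement and amplification-ratio metrics for the
#' configured control node against each endpoint over a seeded state
#' sample (or the full enumeration when small enough), and writes the
#' node-attribute TSV and GraphML per endpoint.
#'
#' @param config list from [runConfig()].
#' @param control control node; default from `config$flow$control`.
#' @return (invisibly) named list of flow metrics per endpoint.
#' @export
runFlow <- function(config = runConfig(), control = config$flow$control) {
  net <- .resolveNetwork(config$network)
  params <- .kineticsFrom(config)
  solver <- .solverFrom(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  total <- countStates(length(controlNodes(net)), 2)
  sample <- if (total <= config$flow$sample) NULL else config$flow$sample
  scan <- scanStates(net, params = params, solver = solver,
                     sample = sample, seed = config$seed,
                     workers = config$workers)
  res <- list()
  for (ep in endpointNodes(net)) {
    metrics <- flowMetrics(scan, control, ep,
                           selectionQuantile = config$flow$quantile)
    attrs <- flowAttributes(metrics)
    stem <- file.path(out, paste0("flow_", .safeName(control), "_",
                                  .safeName(ep)))
    .writeTSV(attrs, paste0(stem, ".tsv"))
    exportGraphML(net, paste0(stem, ".graphml"), nodeAttrs = attrs)
    res[[ep]] <- metrics
  }
  .writeMeta(out, "flow", config,
             list(control = control, n_states = ncol(scan)))
  invisible(res)
}

#' Run the fine-grained grid pipeline
#'
#' For each configured level of the z-axis node, scans the 2-D lattice of
#' the two varied axes (all other control nodes at their low basal
#' activity), computes the local log-log sensitivity of every endpoint
#' with respect to each varied axis, and writes one long-format table.
#'
#' @param config list from [runConfig()].
#' @return (invisibly) the combined surface `data.frame`.
#' @export
runFine <- function(config = runConfig()) {
  net <- .resolveNetwork(config$network)
  params <- .kineticsFrom(config)
  solver <- .solverFrom(config)
  fc <- config$fine
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grid <- logGrid(fc$from, fc$to, fc$points)
  varied <- setNames(list(grid, grid), fc$axes)
  surfaces <- list()
  for (z in fc$zLevels) {
    fixed <- setNames(z, fc$zNode)
    scan <- gridScan(net, varied = varied, fixed = fixed,
                     params = params, solver = solver)
    for (ep in endpointNodes(net)) {
      for (ax in fc$axes) {
        s <- localSensitivity(scan, ep, ax)
        s[[fc$zNode]] <- z
        surfaces[[length(surfaces) + 1]] <- s
      }
    }
  }
  res <- do.call(rbind, surfaces)
  .writeTSV(res, file.path(out, "fine_sensitivities.tsv"))
  .writeMeta(out, "fine", config,
             list(points = fc$points, zLevels = fc$zLevels))
  invisible(res)
}

#' Generate and write a synthetic network
#'
#' @param config list from [runConfig()]; `config$synth` supplies the
#'   [randomNetwork()] arguments and `config$seed` the seed.
#' @return (invisibly) the generated [SignedNetwork]; written as
#'   canonical JSON and topology-only SIF under `config$out`.
#' @export
runSynth <- function(config = runConfig()) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  net <- do.call(randomNetwork, c(config$synth, list(seed = config$seed)))
  writeNetwork(net, file.path(out, "synthetic_network.json"))
  writeNetwork(net, file.path(out, "synthetic_network.sif"))
  .writeMeta(out, "synth", config, list(n_nodes = nrow(networkNodes(net)),
                                        n_edges = nrow(networkEdges(net))))
  invisible(net)
}
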