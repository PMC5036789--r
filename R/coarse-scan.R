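#' Size of the coarse-grained state space
#'
#' Number of conditions when each of `n` control nodes independently
#' assumes one of `s` activity levels: `s^n`, computed exactly.
#'
#' @param n number of control nodes (`>= 1`).
#' @param s number of levels per node (`>= 2`).
#' @return `s^n` as a numeric; an error is raised if the result would
#'   exceed the exactly representable integer range (2^53).
#' @examples
#' countStates(20, 2)  # 1048576
#' @export
countStates <- function(n, s) {
  stopifnot(n >= 1, s >= 2, n == floor(n), s == floor(s))
  if (n * log2(s) > 53)
    stop("countStates: result exceeds exact integer range")
  out <- 1
  for (i in seq_len(n)) out <- out * s
  out
}

#' Number of single-node-difference state pairs
#'
#' Counts the unordered pairs of coarse-grained states that differ in
#' exactly one node's level -- the number of pairwise sensitivity values
#' a full scan yields: `s^n * n * (s - 1) / 2` (each of the `s^n` states
#' has `n * (s - 1)` single-node neighbours, and each pair is counted
#' once).
#'
#' @inheritParams countStates
#' @return the exact pair count as a numeric.
#' @examples
#' countSensitivityPairs(20, 2)  # 10485760
#' @export
countSensitivityPairs <- function(n, s) {
  stopifnot(n >= 1, s >= 2)
  countStates(n, s) * n * (s - 1) / 2
}

# Levels matrix (states x controls, entries 0/1) for the given 0-based
# state ids under the deterministic lexicographic order: control-node
# tuple in declared node order, first node most significant, low (0)
# before high (1).
.levelsForIds <- function(ids, n) {
  L <- matrix(0L, length(ids), n)
  for (k in seq_len(n)) {
    L[, k] <- as.integer((ids %/% 2^(n - k)) %% 2)
  }
  L
}

.betaFromLevels <- function(net, params, levels, controls, fixed = NULL) {
  nd <- net@nodes
  nm <- nd$name
  m <- nrow(levels)
  base <- setNames(nd$beta_low, nm)
  base[nd$is_endpoint] <- params@endpointBeta
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  Beta <- matrix(base, length(nm), m, dimnames = list(nm, NULL))
  bl <- setNames(nd$beta_low, nm)[controls]
  bh <- setNames(nd$beta_high, nm)[controls]
  Beta[controls, ] <- ifelse(t(levels) == 1L, bh, bl)
  Beta
}

#' Enumerate coarse-grained states and solve their steady states
#'
#' Enumerates all `2^n` high/low basal-activity assignments of the
#' control nodes (or a seeded uniform subsample of them) in deterministic
#' lexicographic order, and solves every state with the vectorised
#' batch engine.
#'
#' @param net a [SignedNetwork].
#' @param controls character vector of control nodes to enumerate
#'   (default: all non-endpoint nodes). Non-enumerated control nodes are
#'   held at `beta_low` (or at values given in `fixed`).
#' @param params a [KineticParams].
#' @param solver a [SolverConfig].
#' @param sample optional number of states to draw (uniform, without
#'   replacement); requires `seed`.
#' @param seed integer seed fixing the subsample.
#' @param fixed optional named vector of basal activities overriding the
#'   default `beta_low` for non-enumerated control nodes.
#' @param chunkSize states solved per batch (memory control).
#' @param workers parallel workers for the chunk loop (forked; results
#'   are reassembled in deterministic state order regardless of
#'   completion order).
#' @return a [SteadyStateScan]; columns follow the lexicographic state
#'   order (subsampled scans keep the same relative order). Non-converged
#'   states are flagged in `colData(x)$converged`, never dropped here.
#' @examples
#' net <- npmAlkNetwork()
#' scan <- scanStates(net, sample = 64, seed = 1)
#' @export
scanStates <- function(net, controls = controlNodes(net),
                       params = kineticParams(),
                       solver = solverConfig(backend = "fixedpoint"),
                       sample = NULL, seed = NULL, fixed = NULL,
                       chunkSize = 16384L, workers = 1L) {
  stopifnot(all(controls %in% controlNodes(net)))
  n <- length(controls)
  total <- countStates(n, 2)
  if (is.null(sample)) {
    ids <- seq_len(total) - 1
  } else {
    if (is.null(seed)) stop("sampled scans need a seed")
    if (sample > total) stop("sample exceeds number of states")
    ids <- sort(.seededSample(total, sample, seed)) - 1
  }
  m <- length(ids)
  levels <- .levelsForIds(ids, n)
  model <- .buildModel(net, params)
  starts <- seq(1, m, by = chunkSize)
  solveChunk <- function(from) {
    to <- min(from + chunkSize - 1, m)
    Beta <- .betaFromLevels(net, params, levels[from:to, , drop = FALSE],
                            controls, fixed)
    .batchSolve(model, params, Beta, solver)
  }
  chunks <- if (workers > 1) {
    parallel::mclapply(starts, solveChunk, mc.cores = workers)
  } else {
    lapply(starts, solveChunk)
  }
  SS <- do.call(cbind, lapply(chunks, `[[`, "ss"))
  conv <- unlist(lapply(chunks, `[[`, "converged"), use.names = FALSE)
  resid <- unlist(lapply(chunks, `[[`, "residual"), use.names = FALSE)
  rownames(SS) <- model$names
  colnames(SS) <- paste0("s", ids)
  cd <- S4Vectors::DataFrame(state_id = ids, converged = conv,
                             residual = resid,
                             row.names = colnames(SS))
  colnames(levels) <- controls
  cd$level <- levels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ss = SS), colData = cd,
    metadata = list(network = net, controls = controls, params = params,
                    solver = solver, full = is.null(sample),
                    fixed = fixed, type = "coarse"))
  new("SteadyStateScan", se)
}

# sample.int under a local seed, leaving the caller's RNG state alone
.seededSample <- function(total, size, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(total, size)
}

#' Scan accessors
#'
#' @param x a [SteadyStateScan].
#' @return `ssMatrix` returns the nodes-by-states steady-state matrix;
#'   `stateLevels` the states-by-controls 0/1 level matrix of a coarse
#'   scan (0 = low, 1 = high).
#' @name scanAccessors
NULL

#' @rdname scanAccessors
#' @export
setMethod("ssMatrix", "SteadyStateScan",
          function(x) SummarizedExperiment::assay(x, "ss"))

#' @rdname scanAccessors
#' @export
setMethod("stateLevels", "SteadyStateScan", function(x) {
  lv <- SummarizedExperiment::colData(x)$level
  if (is.null(lv)) stop("scan has no level matrix (grid scan?)")
  lv
})

setMethod("show", "SteadyStateScan", function(object) {
  md <- S4Vectors::metadata(object)
  cat("SteadyStateScan (", md$type, ") with", nrow(object), "nodes x",
      ncol(object), "states;",
      sum(!SummarizedExperiment::colData(object)$converged),
      "non-converged\n")
})

#' As a long-format table
#'
#' @param x a [SteadyStateScan].
#' @return `data.frame` with columns `state_id`, `node`, `ss`,
#'   `converged`, `residual` -- the on-disk steady-state table layout.
#' @export
ssTable <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  SS <- ssMatrix(x)
  data.frame(
    state_id = rep(cd$state_id, each = nrow(SS)),
    node = rep(rownames(SS), ncol(SS)),
    ss = as.numeric(SS),
    converged = rep(cd$converged, each = nrow(SS)),
    residual = rep(cd$residual, each = nrow(SS)),
    stringsAsFactors = FALSE)
}

#' Log-log sensitivity between two steady states
#'
#' The sensitivity of an observed node `N_i` to a perturbed node `N_j`'s
#' basal activity, between two states that are identical except for
#' `N_j`: `S(N_i, beta(N_j)) = ln(SS_i(b) / SS_i(a)) / ln(beta_j(b) /
#' beta_j(a))`. The value is invariant to which state is labelled low or
#' high (swapping both numerators and denominators leaves it unchanged).
#'
#' @param ssA,ssB two [SteadyStateRecord]s whose assignments differ only
#'   in `perturbed`.
#' @param perturbed name of the perturbed node.
#' @param includePerturbed also report the perturbed node observed with
#'   respect to itself (a unit-gain check for source nodes); default
#'   `FALSE`.
#' @return `data.frame` with columns `observed`, `perturbed`, `value`,
#'   `valid`. Records with non-positive steady states or non-converged
#'   inputs are flagged `valid = FALSE`, not dropped. Endpoint records
#'   are always included.
#' @export
pairwiseSensitivity <- function(ssA, ssB, perturbed,
                                includePerturbed = FALSE) {
  a <- ssA@assignment
  b <- ssB@assignment
  if (!perturbed %in% names(a))
    stop("unknown perturbed node: ", perturbed)
  others <- setdiff(names(a), perturbed)
  if (!isTRUE(all.equal(a[others], b[others])))
    stop("assignments must differ only in the perturbed node")
  if (a[perturbed] == b[perturbed])
    stop("perturbed node has the same basal activity in both states")
  denom <- log(b[[perturbed]] / a[[perturbed]])
  observed <- names(ssA@ss)
  if (!includePerturbed) observed <- setdiff(observed, perturbed)
  sa <- ssA@ss[observed]
  sb <- ssB@ss[observed]
  ok <- ssA@converged && ssB@converged
  valid <- ok & sa > 0 & sb > 0
  value <- ifelse(valid, log(sb / sa) / denom, NA_real_)
  data.frame(observed = observed, perturbed = perturbed,
             value = as.numeric(value), valid = valid,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' All pairwise sensitivities of a fully enumerated scan
#'
#' For every unordered pair of enumerated states differing in exactly one
#' control node, computes the log-log sensitivity of each observed node.
#' Requires a full (non-subsampled) [scanStates()] result, where the
#' partner of a state under a single-node flip is located by index
#' arithmetic.
#'
#' @param scan a full-enumeration [SteadyStateScan].
#' @param observed `"endpoints"` (default), `"all"`, or a character
#'   vector of node names.
#' @return `data.frame` with columns `observed`, `perturbed`, `state_id`
#'   (the id of the low-level member of the pair), `value`, `valid`.
#'   Rows are ordered by perturbed node, then state id. Invalid records
#'   (non-converged or non-positive steady states) are flagged, and the
#'   number excluded is available as `attr(x, "n_invalid")`.
#' @export
sensitivityTable <- function(scan, observed = "endpoints") {
  md <- S4Vectors::metadata(scan)
  if (!isTRUE(md$full))
    stop("sensitivityTable needs a full enumeration; use sampledSensitivity")
  net <- md$network
  controls <- md$controls
  n <- length(controls)
  obs <- .resolveObserved(net, observed)
  SS <- ssMatrix(scan)
  conv <- SummarizedExperiment::colData(scan)$converged
  ids <- SummarizedExperiment::colData(scan)$state_id
  nd <- net@nodes
  bl <- setNames(nd$beta_low, nd$name)
  bh <- setNames(nd$beta_high, nd$name)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    j <- controls[k]
    obsK <- setdiff(obs, j)  # a node is never observed against itself
    stride <- 2^(n - k)
    lowpos <- which((ids %/% stride) %% 2 == 0)
    hipos <- lowpos + stride
    denom <- log(bh[[j]] / bl[[j]])
    slo <- SS[obsK, lowpos, drop = FALSE]
    shi <- SS[obsK, hipos, drop = FALSE]
    valid <- rep(conv[lowpos] & conv[hipos], each = length(obsK)) &
      slo > 0 & shi > 0
    val <- matrix(NA_real_, length(obsK), length(lowpos))
    val[valid] <- (log(shi[valid]) - log(slo[valid])) / denom
    out[[k]] <- data.frame(
      observed = rep(obsK, length(lowpos)),
      perturbed = j,
      state_id = rep(ids[lowpos], each = length(obsK)),
      value = as.numeric(val),
      valid = as.logical(valid),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_invalid") <- sum(!res$valid)
  res
}

.resolveObserved <- function(net, observed) {
  if (identical(observed, "endpoints")) return(endpointNodes(net))
  if (identical(observed, "all")) return(nodeNames(net))
  stopifnot(all(observed %in% nodeNames(net)))
  observed
}

#' Seeded sample of single-node-difference sensitivity pairs
#'
#' Draws a uniform sample (without replacement) from the
#' `2^(n-1) * n` unordered state pairs differing in exactly one control
#' node, solves both members of each pair with the batch engine, and
#' returns their sensitivities.
#'
#' @inheritParams scanStates
#' @param nPairs number of pairs to draw.
#' @param observed as in [sensitivityTable()].
#' @return `data.frame` with columns `observed`, `perturbed`, `pair_id`,
#'   `value`, `valid`, ordered by pair id; deterministic under `seed`.
#' @export
sampledSensitivity <- function(net, nPairs, seed,
                               controls = controlNodes(net),
                               params = kineticParams(),
                               solver = solverConfig(backend = "fixedpoint"),
                               observed = "endpoints",
                               chunkSize = 16384L) {
  n <- length(controls)
  half <- countStates(n, 2) / 2
  total <- half * n
  if (total > .Machine$integer.max)
    stop("pair space too large to sample by index")
  if (nPairs > total) stop("nPairs exceeds the number of pairs")
  pid <- sort(.seededSample(total, nPairs, seed)) - 1
  jidx <- pid %/% half + 1
  rest <- pid %% half
  # context bits for the n-1 non-perturbed controls, perturbed bit at 0/1
  Llow <- matrix(0L, nPairs, n)
  ctx <- .levelsForIds(rest, n - 1)
  for (p in seq_len(nPairs)) {
    Llow[p, -jidx[p]] <- ctx[p, ]
  }
  Lhigh <- Llow
  Lhigh[cbind(seq_len(nPairs), jidx)] <- 1L
  colnames(Llow) <- colnames(Lhigh) <- controls
  model <- .buildModel(net, params)
  obs <- .resolveObserved(net, observed)
  nd <- net@nodes
  bl <- setNames(nd$beta_low, nd$name)
  bh <- setNames(nd$beta_high, nd$name)
  solveL <- function(levels) {
    m <- nrow(levels)
    SS <- matrix(NA_real_, model$n, m, dimnames = list(model$names, NULL))
    conv <- logical(m)
    for (from in seq(1, m, by = chunkSize)) {
      to <- min(from + chunkSize - 1, m)
      Beta <- .betaFromLevels(net, params, levels[from:to, , drop = FALSE],
                              controls, NULL)
      res <- .batchSolve(model, params, Beta, solver)
      SS[, from:to] <- res$ss
      conv[from:to] <- res$converged
    }
    list(ss = SS, conv = conv)
  }
  lo <- solveL(Llow)
  hi <- solveL(Lhigh)
  denom <- log(bh[controls] / bl[controls])[jidx]
  slo <- lo$ss[obs, , drop = FALSE]
  shi <- hi$ss[obs, , drop = FALSE]
  valid <- rep(lo$conv & hi$conv, each = length(obs)) & slo > 0 & shi > 0
  denomM <- matrix(rep(denom, each = length(obs)), length(obs), nPairs)
  val <- matrix(NA_real_, length(obs), nPairs)
  val[valid] <- (log(shi[valid]) - log(slo[valid])) / denomM[valid]
  res <- data.frame(
    observed = rep(obs, nPairs),
    perturbed = rep(controls[jidx], each = length(obs)),
    pair_id = rep(pid, each = length(obs)),
    value = as.numeric(val),
    valid = as.logical(valid),
    stringsAsFactors = FALSE)
  res <- res[res$observed != res$perturbed, ]  # never observed vs itself
  rownames(res) <- NULL
  attr(res, "n_invalid") <- sum(!res$valid)
  res
}

#' Profile the extremes of a ranked sensitivity distribution
#'
#' Sorts one endpoint's sensitivity values ascending (stable, ties broken
#' by perturbed node name then state index), takes the bottom and top
#' `floor(q * N)` records, and summarises per perturbed node: frequency
#' in each extreme set, overall extreme values (`eps_max`, `eps_min`),
#' and the fraction of its records inside the negligible-sensitivity
#' plateau band.
#'
#' @param records `data.frame` as returned by [sensitivityTable()] or
#'   [sampledSensitivity()], restricted to (or filtered by) a single
#'   observed node. Invalid records are excluded with a message.
#' @param q extreme fraction (default 0.02, the top/bottom-2% regions).
#' @param plateauBand half-width of the negligible band (default 0.005).
#' @param endpoint optional observed-node filter when `records` holds
#'   several.
#' @return list with `summary` (`data.frame`: `node`, `top_count`,
#'   `bottom_count`, `eps_max`, `eps_min`, `plateau_fraction`), `values`
#'   (the sorted vector), and `extreme_size` (`floor(q * N)`).
#' @export
rankProfile <- function(records, q = 0.02, plateauBand = 0.005,
                        endpoint = NULL) {
  stopifnot(q > 0, q < 0.5)
  if (!is.null(endpoint)) records <- records[records$observed == endpoint, ]
  if ("observed" %in% names(records) &&
      length(unique(records$observed)) > 1)
    stop("records mix several observed nodes; use the 'endpoint' argument")
  nbad <- sum(!records$valid)
  if (nbad > 0) {
    message("rankProfile: excluding ", nbad, " invalid record(s)")
    records <- records[records$valid, ]
  }
  N <- nrow(records)
  if (N == 0) stop("no valid records")
  k <- floor(q * N)
  if (k < 1) stop("extreme set empty (q * N < 1)")
  idcol <- if ("state_id" %in% names(records)) records$state_id
           else records$pair_id
  ord <- order(records$value, records$perturbed, idcol, method = "radix")
  sorted <- records[ord, ]
  bottom <- sorted[seq_len(k), ]
  top <- sorted[seq(N - k + 1, N), ]
  nodes <- sort(unique(records$perturbed))
  cnt <- function(set) {
    tb <- table(factor(set$perturbed, levels = nodes))
    as.integer(tb)
  }
  eps_max <- vapply(nodes, function(nd)
    max(records$value[records$perturbed == nd]), 0)
  eps_min <- vapply(nodes, function(nd)
    min(records$value[records$perturbed == nd]), 0)
  plateau <- vapply(nodes, function(nd)
    mean(abs(records$value[records$perturbed == nd]) <= plateauBand), 0)
  list(summary = data.frame(node = nodes,
                            top_count = cnt(top),
                            bottom_count = cnt(bottom),
                            eps_max = eps_max, eps_min = eps_min,
                            plateau_fraction = plateau,
                            row.names = NULL, stringsAsFactors = FALSE),
       values = sorted$value,
       extreme_size = k)
}
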