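#' Default logarithmic activity grid
#'
#' @param from,to grid range (default `1e-3` to `1e2`, spanning the
#'   coarse levels up to strong overexpression).
#' @param points number of log-spaced points (default 25).
#' @return strictly increasing numeric vector.
#' @export
logGrid <- function(from = 1e-3, to = 1e2, points = 25) {
  stopifnot(from > 0, to > from, points >= 2)
  exp(seq(log(from), log(to), length.out = points))
}

#' Steady states over a continuous basal-activity lattice
#'
#' Varies the basal activity of 1-3 control nodes over given grids while
#' holding every other control node fixed (default: at `beta_low`, the
#' regime where most of the network sits at low basal activity), and
#' solves the full lattice of states with the batch engine. The lattice
#' is traversed in deterministic order (first varied axis fastest).
#'
#' @param net a [SignedNetwork].
#' @param varied named list mapping control-node names to strictly
#'   increasing positive grids (at least 2 points each).
#' @param fixed optional named vector of basal activities for
#'   non-varied control nodes (default all `beta_low`).
#' @param params a [KineticParams].
#' @param solver a [SolverConfig].
#' @return a [SteadyStateScan] whose `colData` holds the `beta`
#'   coordinate matrix; `metadata(x)$grids` records the axes.
#' @examples
#' net <- npmAlkNetwork()
#' sc <- gridScan(net, varied = list("JAK3/STAT3" = logGrid(points = 5),
#'                                   "SHP1" = logGrid(points = 5)))
#' @export
gridScan <- function(net, varied, fixed = NULL, params = kineticParams(),
                     solver = solverConfig(backend = "fixedpoint")) {
  stopifnot(is.list(varied), length(varied) >= 1,
            all(names(varied) %in% controlNodes(net)))
  for (g in varied) {
    stopifnot(all(g > 0), length(g) >= 2, all(diff(g) > 0))
  }
  coords <- as.matrix(expand.grid(varied, KEEP.OUT.ATTRS = FALSE))
  m <- nrow(coords)
  nd <- net@nodes
  nm <- nd$name
  base <- setNames(nd$beta_low, nm)
  base[nd$is_endpoint] <- params@endpointBeta
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  Beta <- matrix(base, length(nm), m, dimnames = list(nm, NULL))
  Beta[colnames(coords), ] <- t(coords)
  model <- .buildModel(net, params)
  res <- .batchSolve(model, params, Beta, solver)
  SS <- res$ss
  rownames(SS) <- nm
  colnames(SS) <- paste0("g", seq_len(m) - 1)
  cd <- S4Vectors::DataFrame(state_id = seq_len(m) - 1,
                             converged = res$converged,
                             residual = res$residual,
                             row.names = colnames(SS))
  cd$beta <- coords
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ss = SS), colData = cd,
    metadata = list(network = net, grids = varied, fixed = fixed,
                    params = params, solver = solver, type = "grid"))
  new("SteadyStateScan", se)
}

#' Local log-log sensitivity surface over a lattice
#'
#' Applies the two-level log-gain statistic between adjacent grid points
#' along one varied axis: for neighbouring basal activities `a < b`,
#' `value = ln(SS(b) / SS(a)) / ln(b / a)`, assigned to the geometric
#' midpoint `sqrt(a b)`. The surface has one fewer cell than the grid
#' along the differenced axis (`"forward"` scheme, default); the
#' `"central"` scheme differences across two grid steps and keeps the
#' interior points.
#'
#' @param scan a grid [SteadyStateScan] from [gridScan()].
#' @param observed node whose response is measured (typically an
#'   endpoint).
#' @param wrt varied node with respect to which the sensitivity is
#'   taken.
#' @param scheme `"forward"` (default) or `"central"`.
#' @return long-format `data.frame`: one coordinate column per varied
#'   node (the `wrt` column holds cell midpoints), plus `observed`,
#'   `wrt`, `value`, `valid` (`FALSE` where a member steady state was
#'   non-converged or non-positive).
#' @export
localSensitivity <- function(scan, observed, wrt,
                             scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  md <- S4Vectors::metadata(scan)
  grids <- md$grids
  stopifnot(!is.null(grids), wrt %in% names(grids),
            observed %in% rownames(scan))
  dims <- lengths(grids)
  a <- match(wrt, names(grids))
  ssv <- array(ssMatrix(scan)[observed, ], dim = dims)
  okv <- array(SummarizedExperiment::colData(scan)$converged &
                 ssMatrix(scan)[observed, ] > 0, dim = dims)
  g <- grids[[wrt]]
  step <- if (scheme == "forward") 1L else 2L
  nA <- dims[a] - step
  if (nA < 1) stop("grid too short along ", wrt, " for scheme ", scheme)
  idx <- lapply(dims, seq_len)
  idx[[a]] <- seq_len(nA)
  loIdx <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  hiIdx <- loIdx
  hiIdx[, a] <- hiIdx[, a] + step
  lo <- ssv[loIdx]
  hi <- ssv[hiIdx]
  valid <- okv[loIdx] & okv[hiIdx]
  val <- rep(NA_real_, length(lo))
  ratio <- log(g[hiIdx[, a]] / g[loIdx[, a]])
  val[valid] <- (log(hi[valid]) - log(lo[valid])) / ratio[valid]
  coords <- matrix(NA_real_, nrow(loIdx), length(grids),
                   dimnames = list(NULL, names(grids)))
  for (d in seq_along(grids)) coords[, d] <- grids[[d]][loIdx[, d]]
  coords[, a] <- sqrt(g[loIdx[, a]] * g[hiIdx[, a]])
  out <- data.frame(coords, check.names = FALSE)
  out$observed <- observed
  out$wrt <- wrt
  out$value <- val
  out$valid <- valid
  out
}
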