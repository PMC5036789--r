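#' Node involvement in high-endpoint states
#'
#' Among the enumerated states in which an endpoint is highly active
#' (steady state at or above a quantile of its values across the scan;
#' the inclusive comparison keeps the selection nonempty under the exact
#' ties a binary enumeration produces), counts
#' how often each control node sat at its high basal level. A node
#' uncorrelated with the endpoint shows a fraction of ~50%; the deviation
#' from 0.5 is its involvement score.
#'
#' @param scan a coarse [SteadyStateScan] (full or sampled).
#' @param endpoint endpoint node name.
#' @param selectionQuantile quantile of the endpoint's steady-state
#'   distribution above which a state counts as "highly active"
#'   (default 0.75).
#' @return `data.frame` with columns `node`, `fraction_high`,
#'   `deviation`; the number of selected states is in
#'   `attr(x, "n_selected")`.
#' @export
involvement <- function(scan, endpoint, selectionQuantile = 0.75) {
  stopifnot(endpoint %in% rownames(scan))
  cd <- SummarizedExperiment::colData(scan)
  keep <- cd$converged
  if (sum(!keep) > 0)
    message("involvement: excluding ", sum(!keep), " non-converged state(s)")
  ssE <- ssMatrix(scan)[endpoint, keep]
  lv <- stateLevels(scan)[keep, , drop = FALSE]
  thr <- quantile(ssE, selectionQuantile, names = FALSE)
  sel <- ssE >= thr
  if (!any(sel)) stop("involvement: empty selection at quantile ",
                      selectionQuantile)
  frac <- colMeans(lv[sel, , drop = FALSE] == 1L)
  out <- data.frame(node = colnames(lv), fraction_high = as.numeric(frac),
                    deviation = abs(as.numeric(frac) - 0.5),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_selected") <- sum(sel)
  out
}

#' Signal-amplification ratios for a control node
#'
#' For a control node `j`, averages each node's steady state over all
#' scanned states on the `beta_j = high` face and on the `beta_j = low`
#' face of the state hypercube. The ratio of the two means measures how
#' strongly the control node's basal-activity change (low to high, a
#' 100-fold increase at the default levels) is transduced through each
#' node.
#'
#' @param scan a coarse [SteadyStateScan].
#' @param control control node name.
#' @param includeControl report the control node's own row as well
#'   (default `FALSE`; by definition its ratio is the basal-activity
#'   ratio itself when it has no regulators).
#' @return `data.frame` with columns `node`, `upsilon_high`,
#'   `upsilon_low`, `ratio`, `defined` (`FALSE` where the low-face mean
#'   is zero). Pure aggregation: invariant to state order.
#' @export
upsilon <- function(scan, control, includeControl = FALSE) {
  lv <- stateLevels(scan)
  stopifnot(control %in% colnames(lv))
  cd <- SummarizedExperiment::colData(scan)
  keep <- cd$converged
  if (sum(!keep) > 0)
    message("upsilon: excluding ", sum(!keep), " non-converged state(s)")
  SS <- ssMatrix(scan)[, keep, drop = FALSE]
  ctl <- lv[keep, control] == 1L
  if (!any(ctl) || all(ctl))
    stop("scan does not span both levels of ", control)
  hi <- rowMeans(SS[, ctl, drop = FALSE])
  lo <- rowMeans(SS[, !ctl, drop = FALSE])
  out <- data.frame(node = rownames(SS), upsilon_high = hi,
                    upsilon_low = lo,
                    ratio = ifelse(lo > 0, hi / lo, NA_real_),
                    defined = lo > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!includeControl) out <- out[out$node != control, ]
  rownames(out) <- NULL
  out
}

#' Combined signal-flow metrics for one control node and one endpoint
#'
#' @inheritParams involvement
#' @param control control node whose basal-activity increase is being
#'   traced.
#' @return `data.frame` merging [involvement()] (per control node) and
#'   [upsilon()] (per node) columns, with attributes `control` and
#'   `endpoint`. The control node carries no metrics of its own.
#' @export
flowMetrics <- function(scan, control, endpoint,
                        selectionQuantile = 0.75) {
  inv <- involvement(scan, endpoint, selectionQuantile)
  ups <- upsilon(scan, control)
  out <- merge(ups, inv, by = "node", all.x = TRUE, sort = FALSE)
  out <- out[match(setdiff(rownames(scan), control), out$node), ]
  rownames(out) <- NULL
  attr(out, "control") <- control
  attr(out, "endpoint") <- endpoint
  out
}

.linmap <- function(x, from, to) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    return(rep((from + to) / 2, length(x)))
  from + (x - rng[1]) / (rng[2] - rng[1]) * (to - from)
}

#' Viewer-ready node attributes from flow metrics
#'
#' Maps involvement deviations linearly to node widths in `[30, 120]`
#' (minimum to maximum effect) and amplification ratios linearly to grey
#' levels in `[255, 50]` (darker = larger ratio = stronger transduced
#' signal). The control node itself is drawn black (grey 0) at maximal
#' width. Nodes without a metric (endpoints have no basal level to count;
#' undefined ratios) receive the midpoint of the respective range.
#' When all metric values coincide, every node maps to the midpoint.
#'
#' @param metrics output of [flowMetrics()].
#' @return `data.frame` with columns `node`, `width` (numeric in
#'   `[30, 120]`) and `grey` (integer in `{0} + [50, 255]`).
#' @seealso [exportGraphML()] to attach these to a GraphML file.
#' @export
flowAttributes <- function(metrics) {
  control <- attr(metrics, "control")
  width <- .linmap(metrics$deviation, 30, 120)
  width[is.na(metrics$deviation)] <- 75
  grey <- .linmap(metrics$ratio, 255, 50)
  grey[is.na(metrics$ratio)] <- (255 + 50) / 2
  out <- data.frame(node = metrics$node, width = width,
                    grey = round(grey),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(control))
    out <- rbind(out, data.frame(node = control, width = 120, grey = 0))
  out
}
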