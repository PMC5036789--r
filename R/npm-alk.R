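#' The curated NPM-ALK signalling network
#'
#' Returns the signed network model of NPM-ALK-driven signalling in
#' anaplastic large cell lymphoma used throughout this package: 19
#' control nodes plus the two readout endpoints, Proliferation and
#' Cell Survival.
#'
#' The wiring follows the literature-curated core model: HSP90 stabilises
#' NPM-ALK; the phosphatase SHP1 inhibits both NPM-ALK and JAK3/STAT3;
#' NPM-ALK activates JAK3/STAT3, p85/PI3K/p110, GRB/SHC/IRS1 and
#' PLC-gamma; autocrine interleukin signalling forms a positive feedback
#' loop with JAK3/STAT3 (the only directed cycle in the model);
#' p85/PI3K/p110 produces PIP3 which activates pAKT, while lipid
#' phosphatases (e.g. PTEN) remove PIP3; GRB/SHC/IRS1 activates Ras and
#' VAV1, VAV1 activates CDC42; PLC-gamma signals through
#' IP3/DAG/Ca2+/PKC to Ras; the Ras -> MEK -> ERK -> AP-1 -> CD30 cascade
#' feeds cell survival. Proliferation is driven by JAK3/STAT3, pAKT and
#' CDC42; cell survival by JAK3/STAT3, pAKT, ERK and CD30.
#'
#' Every node's basal (independent) activity beta can be "high" (0.1) or
#' "low" (0.001) in coarse-grained scans; all edge weights are 1.
#'
#' @return a [SignedNetwork] with 21 nodes (2 endpoints) and 28 edges,
#'   3 of them inhibiting (from SHP1 and Phosphatases).
#' @examples
#' net <- npmAlkNetwork()
#' length(controlNodes(net))  # 19
#' @export
npmAlkNetwork <- function() {
  controls <- c("NPM-ALK", "HSP90", "SHP1", "Interleukins", "JAK3/STAT3",
                "p85/PI3K/p110", "PIP3", "pAKT", "Phosphatases",
                "PLC-gamma", "IP3/DAG/Ca2+/PKC", "GRB/SHC/IRS1", "VAV1",
                "CDC42", "Ras", "MEK", "ERK", "AP-1", "CD30")
  endpoints <- c("Proliferation", "Cell Survival")
  nodes <- data.frame(
    name = c(controls, endpoints),
    beta_low = 0.001,
    beta_high = 0.1,
    is_endpoint = rep(c(FALSE, TRUE), c(length(controls), length(endpoints))),
    stringsAsFactors = FALSE)

  e <- function(source, target, sign = "activating")
    data.frame(source = source, target = target, sign = sign, weight = 1,
               stringsAsFactors = FALSE)
  edges <- rbind(
    e("HSP90", "NPM-ALK"),
    e("SHP1", "NPM-ALK", "inhibiting"),
    e("SHP1", "JAK3/STAT3", "inhibiting"),
    e("NPM-ALK", "JAK3/STAT3"),
    e("NPM-ALK", "p85/PI3K/p110"),
    e("NPM-ALK", "GRB/SHC/IRS1"),
    e("NPM-ALK", "PLC-gamma"),
    e("Interleukins", "JAK3/STAT3"),
    e("JAK3/STAT3", "Interleukins"),
    e("p85/PI3K/p110", "PIP3"),
    e("Phosphatases", "PIP3", "inhibiting"),
    e("PIP3", "pAKT"),
    e("GRB/SHC/IRS1", "Ras"),
    e("GRB/SHC/IRS1", "VAV1"),
    e("VAV1", "CDC42"),
    e("PLC-gamma", "IP3/DAG/Ca2+/PKC"),
    e("IP3/DAG/Ca2+/PKC", "Ras"),
    e("Ras", "MEK"),
    e("MEK", "ERK"),
    e("ERK", "AP-1"),
    e("AP-1", "CD30"),
    e("JAK3/STAT3", "Proliferation"),
    e("pAKT", "Proliferation"),
    e("CDC42", "Proliferation"),
    e("JAK3/STAT3", "Cell Survival"),
    e("pAKT", "Cell Survival"),
    e("ERK", "Cell Survival"),
    e("CD30", "Cell Survival"))

  signedNetwork(nodes, edges,
                metadata = list(name = "npm-alk",
                                description = "curated NPM-ALK core signalling network"))
}
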