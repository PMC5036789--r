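test_that("the Hill kernel obeys its defining identities", {
  for (h in c(1, 2, 4)) expect_equal(hillActivation(0.5, 0.5, h), 0.5)
  expect_equal(hillActivation(0, 0.5, 2), 0)
  expect_equal(hillActivation(0.1, 0.5, 2), 0.01 / 0.26)
  expect_error(hillActivation(-0.1, 0.5, 2), "must be >= 0")
  # monotone nondecreasing, bounded in [0, 1]
  x <- sort(exp(seq(log(1e-4), log(1e3), length.out = 50)))
  y <- hillActivation(x, 0.5, 2)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))
})

test_that("rate evaluation matches the model algebra", {
  net <- parallel_net()
  b <- c(A = 0.2, B = 0.4)
  # a source node sitting at beta/gamma is at rest
  x <- c(A = 0.2, B = 0.4, E = 0.3)
  r <- evaluateRates(net, assignment = b, x = x)
  expect_equal(r[["A"]], 0)
  expect_equal(r[["B"]], 0)
  # endpoint rate: endpointBeta * mean(hill) - x
  expect_equal(r[["E"]],
               mean(hillActivation(c(0.2, 0.4), 0.5, 2)) - 0.3)

  # with everything at zero, only sources produce
  r0 <- evaluateRates(net, assignment = b, x = c(A = 0, B = 0, E = 0))
  expect_equal(unname(r0), c(0.2, 0.4, 0))

  # an inhibitor at K halves production relative to the inhibitor-free case
  mi <- motifNetwork("inhibitor_pair")
  rI <- evaluateRates(mi$network, assignment = c(I = 0.5),
                      x = c(I = 0.5, T = 0))
  expect_equal(rI[["T"]], 0.5)  # endpointBeta * (1 - hill(K)) = 0.5
})

test_that("steady states reproduce closed forms", {
  # isolated source: SS = beta / gamma
  mo <- motifNetwork("cascade", k = 2)
  rec <- steadyState(mo$network, assignment = c(N1 = 0.1),
                     solver = solverConfig(rateTol = 1e-12))
  expect_true(isConverged(rec))
  expect_equal(ssValues(rec)[["N1"]], 0.1, tolerance = 1e-9)
  # terminal node of the two-step cascade: 1 * hill(0.1) = 0.01/0.26
  expect_equal(ssValues(rec)[["N2"]], 0.01 / 0.26, tolerance = 1e-7)

  # gamma rescales a source's steady state
  p <- kineticParams(degradation = 2)
  rec2 <- steadyState(mo$network, params = p, assignment = c(N1 = 0.1),
                      solver = solverConfig(rateTol = 1e-12))
  expect_equal(ssValues(rec2)[["N1"]], 0.05, tolerance = 1e-8)
})

test_that("adaptive integration and damped fixed point agree", {
  for (seed in 1:10) {
    net <- randomNetwork(8, seed = seed, betaLow = 0.01, betaHigh = 0.5)
    set.seed(100 + seed)
    b <- setNames(exp(stats::runif(length(controlNodes(net)),
                                   log(0.05), log(1))),
                  controlNodes(net))
    r1 <- steadyState(net, assignment = b,
                      solver = solverConfig(rateTol = 1e-12))
    r2 <- steadyState(net, assignment = b,
                      solver = solverConfig(rateTol = 1e-12,
                                            backend = "fixedpoint"))
    expect_true(isConverged(r1))
    expect_true(isConverged(r2))
    expect_lt(rel_err(ssValues(r1), ssValues(r2)), 1e-6)
  }
})

test_that("steady states stay within the production bound beta/gamma", {
  for (seed in 1:5) {
    net <- randomNetwork(10, seed = seed)
    scan <- scanStates(net, sample = 32, seed = seed)
    SS <- ssMatrix(scan)
    lv <- stateLevels(scan)
    nd <- networkNodes(net)
    bound <- matrix(ifelse(nd$is_endpoint, 1, NA), nrow(SS), ncol(SS),
                    dimnames = dimnames(SS))
    ctl <- controlNodes(net)
    bound[ctl, ] <- t(ifelse(lv == 1L, 0.1, 0.001))
    expect_true(all(SS <= bound + 1e-9))
    expect_true(all(SS >= 0))
  }
})

test_that("acyclic networks equal the topological composition oracle", {
  for (seed in 1:8) {
    net <- randomNetwork(8, seed = seed, allowCycles = FALSE)
    set.seed(200 + seed)
    b <- setNames(exp(stats::runif(length(controlNodes(net)),
                                   log(0.05), log(1))),
                  controlNodes(net))
    exact <- topo_ss(net, b)
    rec <- steadyState(net, assignment = b,
                       solver = solverConfig(rateTol = 1e-13,
                                             backend = "fixedpoint"))
    expect_lt(rel_err(ssValues(rec)[names(exact)], exact, floor = 1e-8),
              1e-8)
  }
})

test_that("raising basal activity never lowers activity downstream of pure activation", {
  for (seed in 1:5) {
    net <- randomNetwork(8, seed = seed, allowCycles = FALSE,
                         inhibitionFraction = 0)
    ctl <- controlNodes(net)
    b <- setNames(rep(0.05, length(ctl)), ctl)
    base <- ssValues(steadyState(net, assignment = b,
                                 solver = solverConfig(backend = "fixedpoint")))
    for (j in ctl) {
      b2 <- b
      b2[j] <- 0.5
      up <- ssValues(steadyState(net, assignment = b2,
                                 solver = solverConfig(backend = "fixedpoint")))
      expect_true(all(up >= base - 1e-10))
    }
  }
})

test_that("turning an input inhibitory can only lower the target", {
  # a target with a retained activator: under sum aggregation the flipped
  # edge trades a non-negative Hill term for a factor <= 1
  nodes <- data.frame(name = c("S", "C", "T"),
                      is_endpoint = c(FALSE, FALSE, TRUE))
  mk <- function(sign) signedNetwork(nodes, data.frame(
    source = c("C", "S"), target = "T", sign = c("activating", sign)))
  p <- kineticParams(aggregation = "sum")
  sv <- solverConfig(rateTol = 1e-12)
  for (bS in c(0.05, 0.3, 0.9)) {
    b <- c(S = bS, C = 0.4)
    sa <- ssValues(steadyState(mk("activating"), p, b, sv))
    si <- ssValues(steadyState(mk("inhibiting"), p, b, sv))
    expect_lte(si[["T"]], sa[["T"]] + 1e-12)
  }
  # and on either side, the target responds monotonically to the source:
  # up through an activating link, down through an inhibiting one
  hiS <- c(S = 0.9, C = 0.4)
  loS <- c(S = 0.05, C = 0.4)
  expect_gte(ssValues(steadyState(mk("activating"), p, hiS, sv))[["T"]],
             ssValues(steadyState(mk("activating"), p, loS, sv))[["T"]])
  expect_lte(ssValues(steadyState(mk("inhibiting"), p, hiS, sv))[["T"]],
             ssValues(steadyState(mk("inhibiting"), p, loS, sv))[["T"]])
})

test_that("the solver matches a fine fixed-step Euler oracle on the fixture", {
  net <- npmAlkNetwork()
  b <- setNames(rep(0.001, 19), controlNodes(net))
  rec <- steadyState(net, assignment = b,
                     solver = solverConfig(rateTol = 1e-12))
  x <- euler_ss(net, b, dt = 1e-3, t_end = 1e3)
  expect_lt(rel_err(ssValues(rec)[names(x)], x), 1e-6)
})
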