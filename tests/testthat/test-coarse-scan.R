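test_that("state-space combinatorics match brute-force enumeration", {
  expect_equal(countStates(1, 2), 2)
  expect_equal(countStates(3, 3), 27)
  expect_equal(countSensitivityPairs(1, 2), 1)
  expect_equal(countSensitivityPairs(2, 2), 4)
  for (n in 1:4) {
    for (s in 2:3) {
      expect_equal(countStates(n, s), s^n)
      expect_equal(countSensitivityPairs(n, s), brute_pair_count(n, s))
    }
  }
  expect_error(countStates(60, 2), "exact integer range")
})

test_that("scanStates enumerates lexicographically and samples deterministically", {
  net <- chain_net(c("activating", "activating", "activating"))  # N1..N3 -> E
  scan <- scanStates(net)
  expect_equal(ncol(scan), 8)
  cd <- SummarizedExperiment::colData(scan)
  expect_equal(cd$state_id, 0:7)
  lv <- stateLevels(scan)
  # first declared control node is the most significant bit
  expect_equal(unname(lv[, "N1"]), rep(0:1, each = 4))
  expect_equal(unname(lv[, "N3"]), rep(0:1, 4))
  expect_true(all(cd$converged))

  net2 <- npmAlkNetwork()
  s1 <- scanStates(net2, sample = 100, seed = 1)
  s2 <- scanStates(net2, sample = 100, seed = 1)
  expect_identical(ssMatrix(s1), ssMatrix(s2))
  expect_identical(SummarizedExperiment::colData(s1)$state_id,
                   SummarizedExperiment::colData(s2)$state_id)
  s3 <- scanStates(net2, sample = 100, seed = 2)
  expect_false(identical(SummarizedExperiment::colData(s3)$state_id,
                         SummarizedExperiment::colData(s1)$state_id))

  # all-low fixture state: every activity is bounded by the high level
  rec <- steadyState(net2,
                     assignment = setNames(rep(0.001, 19),
                                           controlNodes(net2)),
                     solver = solverConfig(backend = "fixedpoint"))
  expect_true(all(ssValues(rec) <= 0.1))
})

test_that("the pairwise log-gain statistic obeys its identities", {
  net <- branch_net()  # A -> E, A -> B
  sv <- solverConfig(rateTol = 1e-12)
  lo <- steadyState(net, assignment = c(A = 0.001, B = 0.001), solver = sv)
  hi <- steadyState(net, assignment = c(A = 0.001, B = 0.1), solver = sv)

  # B is unreachable from itself-as-perturbed for observers A and E
  s <- pairwiseSensitivity(lo, hi, perturbed = "B")
  expect_true(all(abs(s$value) <= 10 * 1e-12))

  # label-swap symmetry: the statistic does not care which state is "low"
  hiA <- steadyState(net, assignment = c(A = 0.1, B = 0.001), solver = sv)
  s1 <- pairwiseSensitivity(lo, hiA, perturbed = "A")
  s2 <- pairwiseSensitivity(hiA, lo, perturbed = "A")
  expect_equal(s1$value, s2$value)
  expect_true(all(s1$valid))

  # a source observed with respect to itself has unit log-log gain
  su <- pairwiseSensitivity(lo, hiA, perturbed = "A",
                            includePerturbed = TRUE)
  expect_equal(su$value[su$observed == "A"], 1, tolerance = 1e-9)

  # states differing in two nodes are rejected
  hiAB <- steadyState(net, assignment = c(A = 0.1, B = 0.1), solver = sv)
  expect_error(pairwiseSensitivity(lo, hiAB, perturbed = "A"),
               "differ only in")
})

test_that("path sign law: k inhibiting links give sensitivity sign (-1)^k", {
  sv <- solverConfig(rateTol = 1e-12)
  cases <- list(list(signs = c("activating", "activating"), sgn = +1),
                list(signs = c("activating", "inhibiting"), sgn = -1),
                list(signs = c("inhibiting", "inhibiting"), sgn = +1))
  for (cs in cases) {
    net <- chain_net(cs$signs)
    lo <- steadyState(net, assignment = c(N1 = 0.001, N2 = 0.1), solver = sv)
    hi <- steadyState(net, assignment = c(N1 = 0.1, N2 = 0.1), solver = sv)
    s <- pairwiseSensitivity(lo, hi, perturbed = "N1")
    v <- s$value[s$observed == "E"]
    expect_gt(cs$sgn * v, 0)
  }
})

test_that("full-scan sensitivities agree with explicit two-state recomputation", {
  # basal levels high enough that absolute solver error is negligible
  net <- chain_net(c("activating", "inhibiting"), 0.05, 0.5)
  sv <- solverConfig(rateTol = 1e-12, backend = "fixedpoint")
  scan <- scanStates(net, solver = sv)
  tab <- sensitivityTable(scan, observed = "all")
  expect_equal(nrow(tab), 4 * 2)  # 4 pairs x (3 nodes minus the perturbed one)
  expect_true(all(tab$valid))
  # recompute one specific pair independently through steadyState
  lo <- steadyState(net, assignment = c(N1 = 0.05, N2 = 0.05), solver = sv)
  hi <- steadyState(net, assignment = c(N1 = 0.5, N2 = 0.05), solver = sv)
  ref <- pairwiseSensitivity(lo, hi, perturbed = "N1")
  got <- tab[tab$perturbed == "N1" & tab$state_id == 0, ]
  expect_equal(setNames(got$value, got$observed)[ref$observed],
               setNames(ref$value, ref$observed), tolerance = 1e-9)
})

test_that("sampled pairs cover the requested count and are seeded", {
  net <- npmAlkNetwork()
  s1 <- sampledSensitivity(net, nPairs = 50, seed = 7)
  s2 <- sampledSensitivity(net, nPairs = 50, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50 * 2)  # both endpoints observed
  expect_setequal(unique(s1$observed), endpointNodes(net))
})

test_that("rankProfile takes floor(q N) extremes with stable ties", {
  rec <- data.frame(observed = "E",
                    perturbed = rep(c("A", "B"), each = 50),
                    state_id = rep(1:50, 2),
                    value = c(seq(-1, 1, length.out = 50), rep(0, 50)),
                    valid = TRUE)
  pr <- rankProfile(rec, q = 0.02)
  expect_equal(pr$extreme_size, 2)
  expect_equal(pr$summary$node, c("A", "B"))
  expect_equal(pr$summary$bottom_count, c(2L, 0L))
  expect_equal(pr$summary$top_count, c(2L, 0L))
  expect_equal(pr$summary$eps_max, c(1, 0))
  expect_equal(pr$summary$eps_min, c(-1, 0))

  # all-zero records: extremes are disjoint index ranges, plateau is full
  rec0 <- data.frame(observed = "E", perturbed = rep(c("A", "B"), 50),
                     state_id = rep(1:50, each = 2), value = 0,
                     valid = TRUE)
  pr0 <- rankProfile(rec0, q = 0.1)
  expect_equal(pr0$extreme_size, 10)
  expect_equal(sum(pr0$summary$top_count), 10)
  expect_equal(sum(pr0$summary$bottom_count), 10)
  expect_equal(pr0$summary$plateau_fraction, c(1, 1))

  expect_error(rankProfile(rec[1:10, ], q = 0.02), "extreme set empty")
  expect_error(rankProfile(rec, q = 0.6), "q")
})

test_that("invalid records are excluded from ranking with a message", {
  rec <- data.frame(observed = "E", perturbed = "A", state_id = 1:100,
                    value = c(NA, seq_len(99)),
                    valid = c(FALSE, rep(TRUE, 99)))
  expect_message(pr <- rankProfile(rec, q = 0.05), "excluding 1")
  expect_equal(length(pr$values), 99)
})
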