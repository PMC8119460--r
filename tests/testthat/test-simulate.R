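test_that("a fixed seed reproduces the alignment bit for bit", {
  tr <- eightTaxonTree()
  m <- branchSiteModel(2, 0.2, 5, 0.5, 0.3)
  a <- simulateAlignment(m, tr, 40, seed = 77)
  b <- simulateAlignment(m, tr, 40, seed = 77)
  expect_identical(a$alignment@states, b$alignment@states)
  expect_identical(a$truth, b$truth)
  c <- simulateAlignment(m, tr, 40, seed = 78)
  expect_false(identical(a$alignment@states, c$alignment@states))
})

test_that("simulated codon usage matches the stationary distribution", {
  tr <- labeledTree("(A:0.05,B:0.05,C:0.05);")
  sim <- simulateAlignment(oneRatioModel(2, 1), tr, 1e4, seed = 79)
  obs <- tabulate(sim$alignment@states, 61) / length(sim$alignment@states)
  expect_lt(max(abs(obs - 1 / 61)), 0.005)
})

test_that("a counting estimator recovers the simulated omega from two sequences", {
  tr <- labeledTree("(A:0.15,B:0.15);")
  sim <- simulateAlignment(oneRatioModel(2, 0.3), tr, 4000, seed = 80)
  est <- countingOmega(sim$alignment)
  expect_gt(est, 0.2)
  expect_lt(est, 0.4)
})

test_that("site classes are assigned with the model's proportions", {
  tr <- eightTaxonTree()
  m <- branchSiteModel(2, 0.2, 5, 0.5, 0.3)
  sim <- simulateAlignment(m, tr, 5000, seed = 81)
  frac <- tabulate(sim$truth$class, 4) / 5000
  expect_lt(max(abs(frac - unname(m@proportions))), 0.03)
})

test_that("estimates tighten around the simulated omega as codons grow", {
  tr <- eightTaxonTree()
  short <- simulateAlignment(oneRatioModel(2, 0.3), tr, 300, seed = 82)
  long <- simulateAlignment(oneRatioModel(2, 0.3), tr, 3000, seed = 83)
  wShort <- fitOneRatio(short$alignment, tr)@params$omega
  wLong <- fitOneRatio(long$alignment, tr)@params$omega
  expect_gt(wShort, 0.2); expect_lt(wShort, 0.4)
  expect_gt(wLong, 0.27); expect_lt(wLong, 0.33)
})

test_that("simulation trees carry the requested structure", {
  tr <- simulationTree(8, 0.2, kind = "selection")
  expect_equal(length(tr@tree$tip.label), 8L)
  expect_true(all(tr@tree$edge.length == 0.2))
  expect_equal(sum(edgeLabels(tr) == "foreground"), 1L)
  trI <- simulationTree(8, 0.2, kind = "intensity")
  expect_equal(trI@kind, "intensity")
  pec <- simulationTree(6, 0.1, shape = "pectinate", kind = "none")
  expect_equal(length(pec@tree$tip.label), 6L)
  expect_error(simulationTree(3), "at least 4")
})
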