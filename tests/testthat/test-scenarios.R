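test_that("scenario panels are deterministic with structured truth tables", {
  spec <- scenarioSpec("herbivore-ancestor", nGenes = 6, nCodons = 30)
  a <- simulatePanel(spec, seed = 9)
  b <- simulatePanel(spec, seed = 9)
  expect_identical(lapply(a$alignments, function(x) x@states),
                   lapply(b$alignments, function(x) x@states))
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 6L)
  expect_true(all(a$truth$pathway %in% c("CDA", "PDA", "FDA")))
  expect_true(all(a$truth$omega2[a$truth$selected] == spec$omega2))
  expect_s4_class(a$catalog, "PathwayCatalog")
  expect_error(scenarioSpec("null", nGenes = 0), "positive")
})

test_that("scenario tags set the pathway bias of selected genes", {
  herb <- scenarioSpec("herbivore-ancestor")
  expect_lt(herb$selectedFraction[["PDA"]], herb$selectedFraction[["CDA"]])
  carn <- scenarioSpec("carnivore-ancestor")
  expect_lt(carn$selectedFraction[["CDA"]], carn$selectedFraction[["PDA"]])
  expect_true(all(scenarioSpec("null")$selectedFraction == 0))
})

test_that("a null scenario produces PSG calls near the nominal rate", {
  # small panel: checks end-to-end wiring, not the calibration itself
  r <- suppressWarnings(
    runScenario(scenarioSpec("null", nGenes = 8, nCodons = 150), seed = 19))
  expect_lte(sum(psgTable(r$records)$is_psg), 2L)
  expect_true(dietCategory(r$diet) %in% c("indeterminate",
                                          "omnivore-ambiguous",
                                          "carnivore", "herbivore"))
  expect_false(any(r$truth$selected))
})
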