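test_that("at k = 1 the intensity model collapses to the shared distribution", {
  trI <- eightTaxonTree("intensity")
  m1 <- relaxModel(2, c(0.2, 0.8, 2.5), c(0.5, 0.3, 0.2), k = 1)
  sim <- simulateAlignment(m1, trI, 60, seed = 301)
  # with k = 1 the test/reference distinction is vacuous: the likelihood
  # equals that of the same model with the partition labels swapped
  swapped <- trI
  lab <- swapped@edgeLabels
  lab[lab == "test"] <- "tmp"; lab[lab == "reference"] <- "test"
  lab[lab == "tmp"] <- "reference"
  swapped@edgeLabels <- lab
  expect_equal(codonLogLik(sim$alignment, trI, m1)$logLik,
               codonLogLik(sim$alignment, swapped, m1)$logLik,
               tolerance = 1e-9)
  # and the alternative fit can never fall below the null
  nullFit <- fitRelax(sim$alignment, trI, null = TRUE)
  altFit <- fitRelax(sim$alignment, trI, null = FALSE, warmStart = nullFit)
  expect_gte(altFit@logLik, nullFit@logLik - 1e-6)
})

test_that("a strong intensification is recovered and classified", {
  trI <- eightTaxonTree("intensity")
  m <- relaxModel(2, c(0.2, 0.8, 2.5), c(0.5, 0.3, 0.2), k = 3)
  sim <- simulateAlignment(m, trI, 400, seed = 302)
  res <- suppressWarnings(relaxTest(sim$alignment, trI))
  expect_true(res@converged)
  expect_gt(res@k, 1)
  expect_equal(res@classification, "intensified")
  expect_equal(res@lrt@df, 1)
})

test_that("k transforms omegas the way the model advertises", {
  m <- relaxModel(2, c(0.2, 1, 2), c(1, 1, 1) / 3, k = 2)
  cls <- phylotroph:::.classStructure(m)
  testOm <- vapply(cls, function(cl) cl$omega[["test"]], numeric(1))
  refOm <- vapply(cls, function(cl) cl$omega[["reference"]], numeric(1))
  expect_equal(testOm, refOm^2)
  # k > 1 pushes categories away from neutrality on the test branches
  expect_true(all(abs(log(testOm)) >= abs(log(refOm))))
  # unclassified branches keep the reference distribution
  expect_equal(vapply(cls, function(cl) cl$omega[["unclassified"]],
                      numeric(1)), refOm)
})

test_that("a designed mixture of exponents is classified per gene", {
  trI <- eightTaxonTree("intensity")
  set.seed(304)
  mk <- function(k, id) simulateAlignment(
    relaxModel(2, c(0.2, 0.8, 2.5), c(0.5, 0.3, 0.2), k = k),
    trI, 350, geneId = id)$alignment
  genes <- list(mk(3, "up"), mk(0.3, "down"))
  res <- suppressWarnings(relaxPanel(genes, trI))
  expect_equal(res[["up"]]@classification, "intensified")
  # relaxation is the harder direction at this length; require the k
  # estimate to point the right way and the classification not to flip
  expect_lt(res[["down"]]@k, 1)
  expect_true(res[["down"]]@classification %in% c("relaxed", "no-change"))
  expect_gt(res[["up"]]@k, res[["down"]]@k)
  # deterministic rerun on identical inputs
  res2 <- suppressWarnings(relaxPanel(genes, trI))
  expect_identical(relaxTable(res), relaxTable(res2))
})

test_that("the relax panel isolates per-gene failures and orders by gene", {
  trI <- eightTaxonTree("intensity")
  set.seed(303)
  good <- simulateAlignment(relaxModel(2, c(0.2, 0.8, 2.5),
                                       c(0.5, 0.3, 0.2), k = 1),
                            trI, 80, geneId = "bbb")$alignment
  bad <- codonAlignment(c(x = "ATGATG"), geneId = "aaa")  # wrong taxa
  res <- suppressWarnings(relaxPanel(list(good, bad), trI))
  expect_equal(names(res), c("aaa", "bbb"))
  expect_false(res[["aaa"]]@converged)
  expect_match(res[["aaa"]]@status, "taxon")
  expect_true(res[["bbb"]]@converged)
  tab <- relaxTable(res)
  expect_equal(nrow(tab), 2L)
  expect_error(relaxPanel(list(), trI), "empty")
})
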