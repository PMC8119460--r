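# Parameter recovery and structural properties of the model fits. These use
# the desk-scale simulation tree (8 taxa, 0.2 substitutions/codon per branch).

test_that("the one-ratio fit recovers a simulated omega", {
  tr <- eightTaxonTree()
  sim <- simulateAlignment(oneRatioModel(2, 0.3), tr, 500, seed = 101)
  fit <- fitOneRatio(sim$alignment, tr)
  expect_true(fit@converged)
  expect_gt(fit@params$omega, 0.2)
  expect_lt(fit@params$omega, 0.4)
  expect_gt(fit@params$kappa, 1.4)
  expect_lt(fit@params$kappa, 2.8)
})

test_that("identical sequences yield a flagged non-informative fit", {
  tr <- toyTree3()
  aln <- codonAlignment(c(A = "ATGAAATTT", B = "ATGAAATTT", C = "ATGAAATTT"))
  fit <- fitOneRatio(aln, tr)
  expect_false(fit@informative)
  expect_true(is.na(fit@params$omega))
})

test_that("model nesting holds: two-ratio dominates one-ratio, alternative dominates null", {
  tr <- eightTaxonTree()
  sim <- simulateAlignment(twoRatioModel(2, 0.2, 2.5), tr, 300, seed = 102)
  one <- fitOneRatio(sim$alignment, tr)
  two <- fitTwoRatio(sim$alignment, tr)
  expect_gte(two@logLik, one@logLik - 1e-6)
  bst <- suppressWarnings(branchSiteTest(sim$alignment, tr))
  expect_gte(bst$alt@logLik, bst$null@logLik - 1e-6)
})

test_that("the two-ratio fit detects strong foreground selection", {
  tr <- eightTaxonTree()
  sim <- simulateAlignment(twoRatioModel(2, 0.2, 3), tr, 500, seed = 103)
  two <- fitTwoRatio(sim$alignment, tr)
  one <- fitOneRatio(sim$alignment, tr)
  expect_gt(two@params$omegaFg, 1)
  expect_lt(two@params$omegaBg, 0.5)
  expect_lt(lrtPvalue(two@logLik, one@logLik)@p, 0.05)
  # constrained variant pins the foreground omega to 1 and is dominated
  con <- fitTwoRatio(sim$alignment, tr, constrainFg1 = TRUE)
  expect_equal(con@params$omegaFg, 1)
  expect_gte(two@logLik, con@logLik - 1e-6)
})

test_that("the branch test is roughly calibrated under a shared omega", {
  # reduced-replicate check of the two-ratio vs one-ratio LRT under the
  # null; the full-size branch-site calibration lives with the acceptance
  # checks
  tr <- eightTaxonTree()
  set.seed(107)
  rej <- vapply(1:20, function(i) {
    sim <- simulateAlignment(oneRatioModel(2, 0.4), tr, 200)
    one <- fitOneRatio(sim$alignment, tr)
    two <- fitTwoRatio(sim$alignment, tr)
    suppressWarnings(lrtPvalue(two@logLik, one@logLik)@p) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.25)
})

test_that("a zero-length foreground branch flags the fit as non-informative", {
  phy <- ape::read.tree(text = "((A:0.2,B:0.2):0,C:0.2,D:0.2);")
  tr <- labeledTree(phy, foreground = c("A", "B"))
  sim <- simulateAlignment(oneRatioModel(2, 0.5), tr, 100, seed = 104)
  two <- fitTwoRatio(sim$alignment, tr)
  expect_false(two@informative)
})

test_that("branch-site fits recover the selection structure and are reproducible", {
  tr <- eightTaxonTree()
  sim <- simulateAlignment(branchSiteModel(2, 0.2, 5, 0.56, 0.24), tr, 500,
                           seed = 105)
  bst <- suppressWarnings(branchSiteTest(sim$alignment, tr))
  expect_true(bst$alt@converged && bst$null@converged)
  expect_gt(bst$alt@params$omega2, 1.5)
  expect_lt(bst$lrt@p, 0.05)
  expect_lt(abs(bst$alt@params$omega0 - 0.2), 0.15)
  # bit-identical rerun on the same inputs
  bst2 <- suppressWarnings(branchSiteTest(sim$alignment, tr))
  expect_identical(bst$alt@logLik, bst2$alt@logLik)
  expect_identical(bst$alt@params, bst2$alt@params)
  expect_identical(bst$lrt@p, bst2$lrt@p)
})

test_that("the branch-site null pins omega2 at 1 and reports boundary flags", {
  tr <- eightTaxonTree()
  sim <- simulateAlignment(branchSiteModel(2, 0.2, 1, 0.49, 0.21), tr, 200,
                           seed = 106)
  nullFit <- fitBranchSite(sim$alignment, tr, null = TRUE)
  expect_equal(nullFit@params$omega2, 1)
  expect_equal(nullFit@model, "branch-site-null")
  expect_true(nullFit@converged)
})
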