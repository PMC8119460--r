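test_that("the panel scan flags selected genes, isolates failures, and orders output", {
  tr <- eightTaxonTree()
  set.seed(401)
  sel <- simulateAlignment(branchSiteModel(2, 0.2, 8, 0.49, 0.21), tr, 300,
                           geneId = "zsel")$alignment
  neu <- simulateAlignment(branchSiteModel(2, 0.2, 1, 0.49, 0.21), tr, 300,
                           geneId = "mneu")$alignment
  broken <- codonAlignment(c(wrong = "ATGATG"), geneId = "abroken")
  recs <- suppressWarnings(
    runGenePanel(list(sel, neu, broken), tr, branchName = "test_branch"))
  expect_equal(names(recs), c("abroken", "mneu", "zsel"))
  expect_match(recs[["abroken"]]@status, "taxon")
  expect_false(recs[["abroken"]]@isPSG)
  expect_equal(recs[["zsel"]]@status, "ok")
  expect_true(recs[["zsel"]]@isPSG)
  expect_gt(recs[["zsel"]]@omegaFg, 1)
  expect_false(recs[["mneu"]]@isPSG)
  # PSG records carry candidate sites with residues from the reference taxon
  expect_true(all(c("site", "residue", "posterior", "highSupport") %in%
                    names(recs[["zsel"]]@sites)))
  tab <- psgTable(recs)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$branch, rep("test_branch", 3))
  expect_equal(sum(tab$is_psg), 1L)
  expect_error(runGenePanel(list(), tr), "empty")
})

test_that("the PSG rule uses the uncorrected p-value and omega > 1", {
  rec <- new("PSGRecord", gene = "g", branch = "b", nTaxa = 8L,
             lrt = lrtPvalue(-100, -102.5, nTests = 2),
             omegaFg = 3, omegaCapped = FALSE, sites = data.frame(),
             isPSG = TRUE, status = "ok")
  # p = 0.025 -> corrected 0.051: still a PSG under the inclusion rule
  expect_lt(rec@lrt@p, 0.05)
  expect_gt(rec@lrt@pAdjusted, 0.05)
  expect_true(rec@isPSG)
})
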