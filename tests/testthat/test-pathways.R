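# Pathway aggregation and the diet-call rules, exercised on the bundled
# fixtures (the published per-branch selection scan) and on synthetic inputs.

birdProfile <- function() {
  fx <- readTable1Fixture()
  aggregateProfile(within(fx[fx$branch == "ancestral_bird", ],
                          is_psg <- p < 0.05 & omega2a > 1),
                   defaultPathwayCatalog(), branch = "ancestral_bird")
}

archosaurProfile <- function() {
  fx <- readTable1Fixture()
  aggregateProfile(within(fx[fx$branch == "ancestral_archosaur", ],
                          is_psg <- p < 0.05 & omega2a > 1),
                   defaultPathwayCatalog(), branch = "ancestral_archosaur")
}

test_that("the fixture panels aggregate to the published per-pathway counts", {
  bp <- birdProfile()
  expect_equal(unname(pathwayCounts(bp)[c("CDA", "FDA")]), c(7L, 8L))
  ap <- archosaurProfile()
  expect_equal(unname(pathwayCounts(ap)[c("PDA", "FDA", "CDA")]),
               c(8L, 6L, 3L))
  # multi-membership: ATP1B3 is counted in both CDA and PDA for the bird
  expect_true("ATP1B3" %in% bp@genes$CDA && "ATP1B3" %in% bp@genes$PDA)
  expect_gte(sum(pathwayCounts(bp)), 17L)
})

test_that("aggregation is permutation invariant and names missing genes", {
  fx <- readTable1Fixture()
  bird <- fx[fx$branch == "ancestral_bird", ]
  bird$is_psg <- TRUE
  cat <- defaultPathwayCatalog()
  p1 <- aggregateProfile(bird, cat, "b")
  p2 <- aggregateProfile(bird[rev(seq_len(nrow(bird))), ], cat, "b")
  expect_equal(pathwayCounts(p1), pathwayCounts(p2))
  expect_equal(p1@minP, p2@minP)
  stray <- rbind(bird, transform(bird[1, ], gene = "NOSUCHGENE"))
  expect_error(aggregateProfile(stray, cat, "b"), "NOSUCHGENE")
})

test_that("diet rules cover the category space deterministically", {
  mkProfile <- function(cda, pda, fda, genes = list()) {
    g <- list(CDA = genes$CDA %||% character(0),
              PDA = genes$PDA %||% character(0),
              FDA = genes$FDA %||% character(0))
    new("PathwayProfile", branch = "x",
        counts = c(CDA = cda, PDA = pda, FDA = fda),
        minP = c(CDA = NA_real_, PDA = NA_real_, FDA = NA_real_),
        genes = g, ranking = character(0))
  }
  `%||%` <- phylotroph:::`%||%`
  expect_equal(dietCategory(callDiet(mkProfile(3L, 8L, 6L))), "carnivore")
  herb <- callDiet(mkProfile(7L, 3L, 8L,
                             list(CDA = "SLC2A5", FDA = "ABCG5")))
  expect_equal(dietCategory(herb), "herbivore")
  expect_equal(herb@subtype, "fruit/seed/nut")
  expect_gt(length(evidenceTrail(herb)), 1L)
  fruitOnly <- callDiet(mkProfile(5L, 1L, 4L, list(CDA = "SLC2A5")))
  expect_equal(fruitOnly@subtype, "fruit")
  expect_equal(dietCategory(callDiet(mkProfile(4L, 4L, 4L))),
               "omnivore-ambiguous")
  ind <- callDiet(mkProfile(0L, 0L, 0L))
  expect_equal(dietCategory(ind), "indeterminate")
  expect_length(evidenceTrail(ind), 0L)
  # determinism
  expect_identical(callDiet(mkProfile(3L, 8L, 6L))@evidence,
                   callDiet(mkProfile(3L, 8L, 6L))@evidence)
})

test_that("the fixture branches yield the published diet calls", {
  bird <- callDiet(birdProfile())
  expect_equal(dietCategory(bird), "herbivore")
  expect_equal(bird@subtype, "fruit/seed/nut")
  arch <- callDiet(archosaurProfile())
  expect_equal(dietCategory(arch), "carnivore")
})

test_that("branch comparison reports shared PSGs and intensity tallies", {
  cmp <- compareBranches(birdProfile(), archosaurProfile())
  expect_setequal(cmp$sharedPSGs, c("APOA4", "APOB", "ATP1B4", "SI"))
  same <- compareBranches(birdProfile(), birdProfile())
  expect_true(all(same$deltas == 0L))
  # synthetic intensity tally
  rx <- list(new("RelaxResult", gene = "CD36", k = 3, logLikAlt = -1,
                 logLikNull = -4,
                 lrt = lrtPvalue(-1, -4), classification = "intensified",
                 converged = TRUE, status = "ok"),
             new("RelaxResult", gene = "SLC5A1", k = 0.2, logLikAlt = -1,
                 logLikNull = -4,
                 lrt = lrtPvalue(-1, -4), classification = "relaxed",
                 converged = TRUE, status = "ok"))
  cmp2 <- compareBranches(birdProfile(), archosaurProfile(), rx,
                          defaultPathwayCatalog())
  tal <- cmp2$intensityTally
  expect_equal(tal$intensified[tal$pathway == "FDA"], 1L)
  expect_equal(tal$relaxed[tal$pathway == "CDA"], 1L)
})

test_that("catalog IO reads multi-membership entries", {
  cat <- defaultPathwayCatalog()
  expect_setequal(cat@mapping$ATP1B3, c("CDA", "PDA"))
  expect_equal(cat@mapping$ATP1B4, "CDA")
  expect_equal(unname(cat@accessions["PDA"]), "map04974")
  mk <- defaultMarkerTable()
  expect_setequal(mk$gene, c("SLC2A5", "ABCG5"))
})
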