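test_that("empirical-Bayes class posteriors normalize and separate selected sites", {
  tr <- eightTaxonTree()
  # sites 1-10 under omega2 = 8 on the foreground, the rest conserved:
  # simulate the two blocks separately and concatenate
  set.seed(201)
  selBlock <- simulateAlignment(branchSiteModel(2, 0.2, 8, 0.001, 0.001),
                                tr, 10)$alignment
  bgBlock <- simulateAlignment(branchSiteModel(2, 0.2, 1, 0.999, 0.0005),
                               tr, 190)$alignment
  mat <- cbind(as.matrix(selBlock), as.matrix(bgBlock)[taxa(selBlock), ])
  aln <- codonAlignment(mat, geneId = "blocked")
  altFit <- fitBranchSite(aln, tr, null = FALSE)
  sp <- sitePosteriors(aln, tr, altFit)
  expect_equal(nrow(sp), 200L)
  expect_true(all(sp$posterior >= 0 & sp$posterior <= 1))
  expect_gt(mean(sp$posterior[1:10]), mean(sp$posterior[11:200]))
  # full class posteriors sum to one at every site
  pp <- altFit@params
  model <- branchSiteModel(pp$kappa, pp$omega0, max(pp$omega2, 1), pp$p0,
                           pp$p1, freqs = altFit@details$freqs)
  ctx <- phylotroph:::.likContext(aln, tr, freqs = model@freqs)
  res <- phylotroph:::.ctxLogLik(ctx, model@kappa,
                                 phylotroph:::.classStructure(model),
                                 perClass = TRUE)
  M <- res$classPatternLogLik + log(pmax(res$props, 1e-300))
  post <- exp(sweep(M, 2, apply(M, 2, max)))
  post <- sweep(post, 2, colSums(post), "/")
  expect_lt(max(abs(colSums(post) - 1)), 1e-8)
})

test_that("null simulations rarely produce high-support selected sites", {
  tr <- eightTaxonTree()
  set.seed(203)
  frac <- vapply(1:6, function(i) {
    sim <- simulateAlignment(branchSiteModel(2, 0.2, 1, 0.49, 0.21), tr, 200)
    alt <- fitBranchSite(sim$alignment, tr, null = FALSE)
    sp <- sitePosteriors(sim$alignment, tr, alt)
    mean(sp$highSupport)
  }, numeric(1))
  expect_lt(mean(frac), 0.1)
})

test_that("posteriors refuse unconverged or non-branch-site fits", {
  tr <- eightTaxonTree()
  sim <- simulateAlignment(branchSiteModel(2, 0.2, 5, 0.5, 0.3), tr, 60,
                           seed = 202)
  nullFit <- fitBranchSite(sim$alignment, tr, null = TRUE)
  expect_error(sitePosteriors(sim$alignment, tr, nullFit), "alternative")
})

test_that("the reference taxon default is the first foreground descendant", {
  tr <- labeledTree("((zeb:0.1,ant:0.1):0.1,cat:0.1,dog:0.1);",
                    foreground = c("zeb", "ant"))
  expect_equal(phylotroph:::.defaultReferenceTaxon(tr), "ant")
})
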