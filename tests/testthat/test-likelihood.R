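test_that("degenerate tree: identical sequences at zero length give stationary log-density", {
  tr <- labeledTree("(A:0,B:0,C:0);")
  seq <- "ATGAAATTTCCC"
  aln <- codonAlignment(c(A = seq, B = seq, C = seq))
  m <- oneRatioModel(2, 0.5)
  ll <- codonLogLik(aln, tr, m)
  expect_equal(ll$logLik, 4 * log(1 / 61), tolerance = 1e-10)
  expect_equal(sum(ll$perSite), ll$logLik)
})

test_that("pruning equals exhaustive enumeration on a 4-taxon tree", {
  set.seed(21)
  for (rep in 1:5) {
    kappa <- runif(1, 1, 4)
    w <- runif(1, 0.05, 2)
    tr <- toyTree4()
    m <- oneRatioModel(kappa, w)
    sim <- simulateAlignment(m, tr, 12)
    aln <- sim$alignment
    ll <- codonLogLik(aln, tr, m)$logLik
    states <- aln@states[match(c("A", "B", "C", "D"), taxa(aln)), ]
    brute <- bruteForce4(states, kappa, rep(w, 5),
                         c(0.15, 0.2, 0.3, 0.25, 0.1),
                         equalCodonFrequencies())
    expect_equal(ll, brute, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rerooting the unrooted tree", {
  set.seed(22)
  phy <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.3):0.12,E:0.4);")
  tr <- labeledTree(phy)
  m <- oneRatioModel(2, 0.4)
  aln <- simulateAlignment(m, tr, 40)$alignment
  base <- codonLogLik(aln, tr, m)$logLik
  for (node in unique(phy$edge[, 1])[-1]) {
    re <- ape::root(phy, node = node, resolve.root = FALSE)
    expect_equal(codonLogLik(aln, labeledTree(re), m)$logLik, base,
                 tolerance = 1e-8)
  }
})

test_that("a duplicate taxon at zero branch length does not change the likelihood", {
  set.seed(23)
  tr <- toyTree3()
  m <- oneRatioModel(2, 0.3)
  aln <- simulateAlignment(m, tr, 30)$alignment
  base <- codonLogLik(aln, tr, m)$logLik
  mat <- as.matrix(aln)
  dup <- codonAlignment(rbind(mat, A2 = mat["A", ]), geneId = "dup")
  tr2 <- labeledTree("((A:0,A2:0):0.3,B:0.2,C:0.4);")
  expect_equal(codonLogLik(dup, tr2, m)$logLik, base, tolerance = 1e-8)
})

test_that("gap and ambiguity codons are marginalized as missing data", {
  tr <- toyTree3()
  m <- oneRatioModel(2, 0.5)
  aln <- codonAlignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGAAT"))
  full <- codonLogLik(aln, tr, m)
  gapped <- codonAlignment(c(A = "ATG---", B = "ATGNNA", C = "ATGAAT"))
  gl <- codonLogLik(gapped, tr, m)
  # site 1 unchanged; site 2 must equal the likelihood with A and B dropped
  expect_equal(gl$perSite[1], full$perSite[1], tolerance = 1e-10)
  # with A and B missing, site 2 reduces to the stationary density of C's codon
  expect_equal(gl$perSite[2], log(1 / 61), tolerance = 1e-10)
})

test_that("mixture site classes combine with their proportions", {
  set.seed(25)
  tr <- toyTree4()
  m <- branchSiteModel(2, 0.2, 4, 0.5, 0.3)
  aln <- simulateAlignment(m, tr, 15)$alignment
  ll <- codonLogLik(aln, tr, m)
  # manual mixture from single-class models sharing the scaling convention
  ctx <- phylotroph:::.likContext(aln, tr, freqs = equalCodonFrequencies())
  cls <- phylotroph:::.classStructure(m)
  cll <- phylotroph:::.ctxCllGenericRef(ctx, 2, cls)
  props <- vapply(cls, function(cl) cl$prop, numeric(1))
  manual <- sum(log(colSums(props * exp(cll)))[ctx$patIndex])
  expect_equal(ll$logLik, manual, tolerance = 1e-8)
  # and the compiled kernels agree with the R reference
  cllC <- phylotroph:::.ctxCllGeneric(ctx, 2, cls)
  expect_lt(max(abs(cll - cllC)), 1e-7)
  cllBS <- phylotroph:::.ctxCllBS(ctx, 2, 0.2, 4)
  cllBSR <- phylotroph:::.ctxCllBSRef(ctx, 2, 0.2, 4)
  expect_lt(max(abs(cllBS - cllBSR)), 1e-7)
})

test_that("taxon mismatches are rejected", {
  tr <- toyTree3()
  aln <- codonAlignment(c(A = "ATG", B = "ATG", X = "ATG"))
  expect_error(codonLogLik(aln, tr, oneRatioModel(2, 1)), "taxon")
})
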