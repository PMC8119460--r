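test_that("the standard code has 61 sense codons with symmetric synonymy", {
  gc <- geneticCode()
  expect_length(gc$codons, 61)
  expect_setequal(gc$stops, c("TAA", "TAG", "TGA"))
  expect_true(all(gc$aa != "*"))
  expect_true(isSynonymous("TTT", "TTC"))
  expect_false(isSynonymous("TTT", "TTA"))
  # symmetry of the pair classification
  syn <- gc$pairType %in% c(1L, 2L)
  dim(syn) <- dim(gc$pairType)
  expect_identical(syn, t(syn))
  expect_identical(gc$pairType > 0L, t(gc$pairType > 0L))
})

test_that("rate matrix entries match an independent pair enumeration", {
  gc <- geneticCode()
  kappa <- 2; omega <- 0.5
  Q <- codonRateMatrix(kappa, omega, equalCodonFrequencies(), scale = FALSE)
  # independent oracle: enumerate all ordered codon pairs from the strings
  bases <- c(A = "G", G = "A", C = "T", T = "C")  # transition partners
  for (i in sample(61, 8)) for (j in sample(61, 8)) {
    if (i == j) next
    a <- strsplit(gc$codons[i], "")[[1]]
    b <- strsplit(gc$codons[j], "")[[1]]
    diff <- which(a != b)
    expected <- if (length(diff) != 1L) 0 else {
      ti <- bases[[a[diff]]] == b[diff]
      syn <- gc$aa[i] == gc$aa[j]
      (1 / 61) * (if (ti) kappa else 1) * (if (syn) 1 else omega)
    }
    expect_equal(unname(Q[i, j]), unname(expected), tolerance = 1e-12)
  }
})

test_that("rate matrices are proper scaled generators", {
  set.seed(1)
  for (rep in 1:5) {
    kappa <- runif(1, 0.5, 8); omega <- runif(1, 0.01, 4)
    f <- runif(61); freqs <- new("CodonFrequencies", freqs = f / sum(f),
                                 scheme = "empirical")
    Q <- codonRateMatrix(kappa, omega, freqs)
    pi <- freqs@freqs
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    expect_lt(max(abs(pi %*% Q)), 1e-10)                  # stationarity
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)        # detailed balance
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-10)
  }
  expect_true(all(codonRateMatrix(2, 0, equalCodonFrequencies(),
                                  scale = FALSE)[geneticCode()$pairType >= 3L] == 0))
  # kappa = omega = 1: all allowed moves share one rate before scaling
  Q1 <- codonRateMatrix(1, 1, equalCodonFrequencies(), scale = FALSE)
  offs <- Q1[geneticCode()$pairType > 0L]
  expect_equal(max(offs), min(offs))
  expect_error(codonRateMatrix(-1, 0.5, equalCodonFrequencies()), "kappa")
})

test_that("transition probabilities behave as a stochastic semigroup", {
  freqs <- equalCodonFrequencies()
  Q <- codonRateMatrix(2.3, 0.4, freqs)
  P0 <- transitionProbabilities(Q, 0, freqs)
  expect_equal(P0, diag(61), tolerance = 1e-10, ignore_attr = TRUE)
  set.seed(3)
  t1 <- runif(1, 0.05, 0.5); t2 <- runif(1, 0.05, 0.5)
  P1 <- transitionProbabilities(Q, t1, freqs)
  P2 <- transitionProbabilities(Q, t2, freqs)
  P12 <- transitionProbabilities(Q, t1 + t2, freqs)
  expect_lt(max(abs(P1 %*% P2 - P12)), 1e-8)
  expect_true(all(P1 >= 0))
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  # ergodic limit: the spectral gap of this Q puts exp(lambda_2 * 50) just
  # above 1e-6, so the residual bound is 1e-5
  Pinf <- transitionProbabilities(Q, 50, freqs)
  expect_lt(max(abs(sweep(Pinf, 2, freqs@freqs))), 1e-5)
  expect_error(transitionProbabilities(Q, -1, freqs), "non-negative")
})

test_that("frequency schemes compute what they promise", {
  expect_equal(estimateCodonFrequencies(codonAlignment(c(a = "ATGAAA")),
                                        "equal")@freqs,
               rep(1 / 61, 61))
  # hand count for F1x4 on ATGATG: A 2/6, T 2/6, G 2/6, C 0 (floored)
  f <- estimateCodonFrequencies(codonAlignment(c(a = "ATGATG")), "F1x4")
  gc <- geneticCode()
  byBase <- do.call(rbind, strsplit(gc$codons, ""))
  hand <- apply(byBase, 1, function(cd)
    prod(ifelse(cd == "C", 1e-9, 1 / 3)))
  hand <- pmax(hand, 1e-9); hand <- hand / sum(hand)
  expect_equal(f@freqs, hand, tolerance = 1e-3)
  # F3x4 recovers its own analytic value on uniform-over-sense-codon data
  set.seed(11)
  codons <- sample(gc$codons, 1e4, replace = TRUE)
  aln <- codonAlignment(c(x = paste0(codons, collapse = "")))
  est <- estimateCodonFrequencies(aln, "F3x4")@freqs
  posFreq <- sapply(1:3, function(p)
    table(factor(substr(gc$codons, p, p), c("T", "C", "A", "G"))) / 61)
  analytic <- posFreq[match(byBase[, 1], rownames(posFreq)), 1] *
    posFreq[match(byBase[, 2], rownames(posFreq)), 2] *
    posFreq[match(byBase[, 3], rownames(posFreq)), 3]
  analytic <- analytic / sum(analytic)
  expect_lt(max(abs(est - analytic)), 0.005)
  expect_error(estimateCodonFrequencies(
    codonAlignment(c(a = "---")), "F3x4"), "gaps")
})
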