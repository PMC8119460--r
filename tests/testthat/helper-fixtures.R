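# Small shared objects for the unit tests; everything is built in code.

toyTree3 <- function() labeledTree("(A:0.3,B:0.2,C:0.4);")

toyTree4 <- function(fg = c("A", "B"))
  labeledTree("((A:0.2,B:0.3):0.15,C:0.25,D:0.1);", foreground = fg)

eightTaxonTree <- function(kind = "selection")
  simulationTree(8, 0.2, kind = kind)

# exhaustive site likelihood for a 4-taxon tree ((A,B)x,C,D) rooted at the
# basal node y, summing over both internal states; transition matrices are
# built directly from the generator with the engine's shared neutral scale
bruteForce4 <- function(states, kappa, omegaByEdge, lens, freqs) {
  Q <- lapply(omegaByEdge, function(w)
    phylotroph:::.neutralScaledQ(kappa, w, freqs))
  P <- Map(function(Qi, t) as.matrix(Matrix::expm(Qi * t)), Q, lens)
  pivec <- freqs@freqs
  tipP <- function(Pm, st) if (st > 0L) Pm[, st] else rep(1, 61)
  # edges: y->x, x->A, x->B, y->C, y->D (rooted at the basal node y)
  tot <- 0
  for (s in seq_len(ncol(states))) {
    obs <- states[, s]
    ab <- tipP(P[[2]], obs[1]) * tipP(P[[3]], obs[2])
    L <- 0
    for (y in 1:61) {
      sumx <- sum(P[[1]][y, ] * ab)
      L <- L + pivec[y] * sumx * tipP(P[[4]], obs[3])[y] *
        tipP(P[[5]], obs[4])[y]
    }
    tot <- tot + log(L)
  }
  as.numeric(tot)
}

# NG86-style counting estimate of omega between two aligned sequences,
# with Jukes-Cantor correction; independent of the likelihood machinery
countingOmega <- function(aln) {
  gc <- geneticCode()
  type <- gc$pairType
  s1 <- aln@states[1, ]; s2 <- aln@states[2, ]
  keep <- s1 > 0L & s2 > 0L
  s1 <- s1[keep]; s2 <- s2[keep]
  # per-codon counts of synonymous/non-synonymous sites (single-step moves)
  synSites <- vapply(1:61, function(i) {
    tt <- type[i, ]
    n <- sum(tt > 0L)
    if (n == 0) 0 else 3 * sum(tt %in% c(1L, 2L)) / n
  }, numeric(1))
  S <- sum((synSites[s1] + synSites[s2]) / 2)
  N <- 3 * length(s1) - S
  diffs <- which(s1 != s2)
  Sd <- Nd <- 0
  for (i in diffs) {
    tt <- type[s1[i], s2[i]]
    if (tt %in% c(1L, 2L)) Sd <- Sd + 1
    else if (tt > 0L) Nd <- Nd + 1
    else {  # multi-step: split evenly (crude, fine for the simulated regime)
      Sd <- Sd + 1; Nd <- Nd + 1
    }
  }
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(Sd / S); dN <- jc(Nd / N)
  dN / dS
}
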