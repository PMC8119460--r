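#' Estimate stationary codon frequencies from an alignment
#'
#' Supported schemes: \code{"equal"} (1/61 per sense codon), \code{"F1x4"}
#' (products of overall nucleotide frequencies), \code{"F3x4"} (products of
#' codon-position-specific nucleotide frequencies; the default convention of
#' the codon-model tools this package mirrors) and \code{"empirical"}
#' (observed sense-codon frequencies). All schemes renormalize over the 61
#' sense codons after excluding stops. Zero frequencies are floored at 1e-9
#' (and renormalized) so the substitution process remains irreducible.
#'
#' @param aln A [CodonAlignment-class].
#' @param scheme Frequency scheme tag.
#' @return A [CodonFrequencies-class].
#' @examples
#' aln <- codonAlignment(c(a = "ATGATG"))
#' estimateCodonFrequencies(aln, "F1x4")
#' @export
estimateCodonFrequencies <- function(aln, scheme = c("F3x4", "F1x4", "equal",
                                                     "empirical")) {
  scheme <- match.arg(scheme)
  gc <- geneticCode()
  if (scheme == "equal")
    return(new("CodonFrequencies", freqs = rep(1 / 61, 61), scheme = "equal"))
  obs <- aln@states[aln@states > 0L]
  if (length(obs) == 0L) stop("alignment contains only gaps/ambiguities")
  codmat <- do.call(rbind, strsplit(gc$codons[obs], ""))
  bases <- c("T", "C", "A", "G")
  f <- switch(scheme,
    F1x4 = {
      nf <- tabulate(match(codmat, bases), 4) / length(codmat)
      nucByCodon <- do.call(rbind, strsplit(gc$codons, ""))
      nf[match(nucByCodon[, 1], bases)] * nf[match(nucByCodon[, 2], bases)] *
        nf[match(nucByCodon[, 3], bases)]
    },
    F3x4 = {
      nf <- sapply(1:3, function(p)
        tabulate(match(codmat[, p], bases), 4) / nrow(codmat))
      nucByCodon <- do.call(rbind, strsplit(gc$codons, ""))
      nf[match(nucByCodon[, 1], bases), 1] *
        nf[match(nucByCodon[, 2], bases), 2] *
        nf[match(nucByCodon[, 3], bases), 3]
    },
    empirical = tabulate(obs, 61) / length(obs))
  f <- pmax(f, 1e-9)
  new("CodonFrequencies", freqs = f / sum(f), scheme = scheme)
}

#' Goldman-Yang instantaneous rate matrix over sense codons
#'
#' Off-diagonal rate from codon i to codon j is 0 when the codons differ at
#' more than one position, and otherwise \code{pi_j * kappa^[transition] *
#' omega^[non-synonymous]}. The diagonal makes rows sum to zero and the matrix
#' is rescaled so the expected number of substitutions per unit time equals 1
#' at stationarity, putting branch lengths on the substitutions-per-codon
#' scale.
#'
#' @param kappa Transition/transversion rate ratio (> 0, finite).
#' @param omega dN/dS ratio (>= 0, finite).
#' @param freqs A [CodonFrequencies-class] (or numeric vector of 61
#'   probabilities).
#' @param scale Rescale to one expected substitution per unit time
#'   (default TRUE).
#' @return A 61 x 61 rate matrix with codon dimnames.
#' @examples
#' Q <- codonRateMatrix(2, 0.5, equalCodonFrequencies())
#' max(abs(rowSums(Q)))  # 0
#' @export
codonRateMatrix <- function(kappa, omega, freqs, scale = TRUE) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive and finite")
  if (!is.finite(omega) || omega < 0) stop("omega must be non-negative and finite")
  pi <- .freqVector(freqs)
  gc <- geneticCode()
  type <- gc$pairType
  fac <- matrix(0, 61, 61)
  fac[type == 1L] <- 1
  fac[type == 2L] <- kappa
  fac[type == 3L] <- omega
  fac[type == 4L] <- kappa * omega
  Q <- fac * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  dimnames(Q) <- dimnames(type)
  Q
}

.freqVector <- function(freqs) {
  pi <- if (is(freqs, "CodonFrequencies")) freqs@freqs else as.numeric(freqs)
  if (length(pi) != 61L) stop("need 61 sense-codon frequencies")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("frequencies must be non-negative and normalized")
  pi
}

#' Equal sense-codon frequencies
#' @return A [CodonFrequencies-class] with 1/61 per sense codon.
#' @export
equalCodonFrequencies <- function()
  new("CodonFrequencies", freqs = rep(1 / 61, 61), scheme = "equal")

# Generator scaled by the neutral (omega = 1) substitution rate. All site
# classes of a mixture share this scale, so branch lengths are expected
# substitutions per codon for a neutral site and omega > 1 classes evolve
# proportionally faster (the rate-elevation signal the selection tests use).
# This is the scaling the likelihood engine and the simulator share.
.neutralScaledQ <- function(kappa, omega, freqs) {
  pi <- .freqVector(freqs)
  Q <- codonRateMatrix(kappa, omega, freqs, scale = FALSE)
  Qn <- if (omega == 1) Q else codonRateMatrix(kappa, 1, freqs, scale = FALSE)
  rate <- -sum(pi * diag(Qn))
  if (rate > 0) Q / rate else Q
}

# Eigendecomposition of a reversible Q via its symmetrization
# B = D^{1/2} Q D^{-1/2}. Deterministic for fixed inputs.
.decomposeQ <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2   # enforce exact symmetry against rounding
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / s,        # D^{-1/2} U, columns
       left = t(e$vectors * s))      # U' D^{1/2}, rows
}

#' Transition probabilities of a codon model
#'
#' Computes \code{P(t) = expm(Q t)} by eigendecomposition of the symmetrized
#' reversible generator.
#'
#' @param Q Rate matrix from [codonRateMatrix()].
#' @param t Branch length (>= 0).
#' @param freqs Stationary frequencies used to build \code{Q}.
#' @return A 61 x 61 stochastic matrix.
#' @examples
#' Q <- codonRateMatrix(2, 0.5, equalCodonFrequencies())
#' P <- transitionProbabilities(Q, 0.1, equalCodonFrequencies())
#' range(rowSums(P))  # both 1
#' @export
transitionProbabilities <- function(Q, t, freqs) {
  if (!is.finite(t) || t < 0) stop("branch length must be non-negative")
  pi <- .freqVector(freqs)
  dec <- .decomposeQ(Q, pi)
  .Pfromdec(dec, t)
}

.Pfromdec <- function(dec, t) {
  P <- (dec$right * rep(exp(dec$values * t), each = 61)) %*% dec$left
  P[P < 0] <- 0
  P
}
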