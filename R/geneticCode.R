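#' Standard genetic code over the sense-codon state space
#'
#' The codon models in this package operate on the 61 sense codons of the
#' standard nuclear genetic code; the three stop codons (TAA, TAG, TGA) are
#' excluded from the state space and rejected in input sequences.
#'
#' @return A list with components \code{codons} (character vector of the 61
#'   sense codons, TCAG order), \code{aa} (amino acid one-letter code per sense
#'   codon), \code{stops} (the three stop codons), and \code{pairType} (61 x 61
#'   integer matrix classifying ordered codon pairs: 0 = not a single-nucleotide
#'   change, 1 = synonymous transversion, 2 = synonymous transition,
#'   3 = non-synonymous transversion, 4 = non-synonymous transition).
#' @examples
#' gc <- geneticCode()
#' length(gc$codons)  # 61
#' @export
geneticCode <- function() {
  .phylotroph_cache$code
}

# Build the code tables once at load time; TCAG base order matches the
# conventional codon-model literature.
.buildGeneticCode <- function() {
  bases <- c("T", "C", "A", "G")
  codons64 <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons64[k] <- paste0(b1, b2, b3)
  }
  aa64 <- vapply(codons64, .translateCodon, character(1))
  stops <- codons64[aa64 == "*"]
  sense <- codons64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  stopifnot(length(sense) == 61L, length(stops) == 3L)

  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  pairType <- matrix(0L, n, n)
  isTransition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  for (i in seq_len(n)) {
    diffs <- sweep(mat, 2, mat[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    single <- which(ndiff == 1L)
    for (j in single) {
      pos <- which(diffs[j, ])
      ti <- isTransition(mat[i, pos], mat[j, pos])
      syn <- aa[i] == aa[j]
      pairType[i, j] <- if (syn) (if (ti) 2L else 1L) else (if (ti) 4L else 3L)
    }
  }
  dimnames(pairType) <- list(sense, sense)
  list(codons = sense, aa = stats::setNames(aa, sense), stops = stops,
       pairType = pairType)
}

.translateCodon <- function(codon) {
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  unname(tab[codon])
}

.phylotroph_cache <- new.env(parent = emptyenv())

#' Test synonymy of two sense codons
#'
#' @param a,b Sense codon strings (e.g. \code{"TTT"}).
#' @return Logical: do the two codons encode the same amino acid?
#' @examples
#' isSynonymous("TTT", "TTC")  # TRUE
#' isSynonymous("TTT", "TTA")  # FALSE
#' @export
isSynonymous <- function(a, b) {
  gc <- geneticCode()
  ia <- match(a, gc$codons); ib <- match(b, gc$codons)
  if (anyNA(ia) || anyNA(ib)) stop("not a sense codon: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  unname(gc$aa[ia] == gc$aa[ib])
}

#' Translate sense codons to amino acids
#' @param codons Character vector of codons.
#' @return One-letter amino acid codes; \code{"X"} for unknown/ambiguous codons,
#'   \code{"-"} for gap codons.
#' @export
translateCodons <- function(codons) {
  out <- .translateCodon(codons)
  out[is.na(out)] <- ifelse(grepl("-", codons[is.na(out)]), "-", "X")
  out
}
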